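#' Build a dynamic PET frame schedule
#'
#' A frame schedule is an ordered, contiguous set of acquisition frames
#' given as `(count, duration)` blocks, e.g. 8 frames of 10 s followed by
#' 5 frames of 20 s. Times are stored in seconds from injection.
#'
#' @param blocks list of two-element numeric vectors `c(count, duration_s)`.
#'   The default is the 37-frame, 93-min HRRT protocol:
#'   8x10 s, 5x20 s, 4x30 s, 4x60 s, 4x180 s, 12x360 s.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `frame` (1-based index), `start_s`, `end_s`, `dur_s`.
#' @examples
#' sched <- frame_schedule()
#' nrow(sched)              # 37
#' sum(sched$dur_s) / 60    # 93 minutes
#' @export
frame_schedule <- function(blocks = list(
                             c(8, 10), c(5, 20), c(4, 30),
                             c(4, 60), c(4, 180), c(12, 360))) {
  if (!is.list(blocks) || !length(blocks)) {
    stop("`blocks` must be a non-empty list of c(count, duration_s) pairs")
  }
  durs <- unlist(lapply(blocks, function(b) {
    if (length(b) != 2 || !is.numeric(b)) {
      stop("each block must be a numeric pair c(count, duration_s)")
    }
    if (b[1] < 1 || b[1] != round(b[1])) stop("frame count must be a positive integer")
    if (b[2] <= 0) stop("frame duration must be positive")
    rep(b[2], b[1])
  }))
  ends <- cumsum(durs)
  out <- data.frame(
    frame = seq_along(durs),
    start_s = c(0, ends[-length(ends)]),
    end_s = ends,
    dur_s = durs
  )
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, %.1f min total>\n",
              nrow(x), max(x$end_s) / 60))
  print(as.data.frame(x), ...)
  invisible(x)
}

assert_schedule <- function(schedule) {
  if (!inherits(schedule, "frame_schedule")) {
    stop("`schedule` must be a frame_schedule object")
  }
  if (any(schedule$dur_s <= 0)) stop("zero-length frames in schedule")
  if (any(abs(schedule$start_s[-1] - schedule$end_s[-nrow(schedule)]) > 1e-9)) {
    stop("schedule frames must be contiguous")
  }
  invisible(schedule)
}

#' Total scan duration of a schedule, in minutes
#' @param schedule a [frame_schedule()] object.
#' @return scalar, minutes.
#' @export
schedule_duration_min <- function(schedule) {
  assert_schedule(schedule)
  max(schedule$end_s) / 60
}

#' Frame midpoint times in minutes
#' @param schedule a [frame_schedule()] object.
#' @return numeric vector of frame midpoints (min), one per frame.
#' @export
frame_mid_min <- function(schedule) {
  assert_schedule(schedule)
  (schedule$start_s + schedule$end_s) / 2 / 60
}

#' Resolve a static acquisition window to frame indices
#'
#' Maps a time window in minutes onto the 1-based inclusive range of frames
#' whose union is exactly `[start_min, end_min]`. Window edges must align
#' with frame boundaries: static images are formed by averaging whole
#' frames, so a window that cuts a frame cannot be represented without
#' silent interpolation and is rejected.
#'
#' @param schedule a [frame_schedule()] object.
#' @param start_min,end_min window bounds in minutes from injection.
#' @param name optional window label carried through to results.
#' @return A `sbr_window` list: `name`, `start_min`, `end_min`, `frames`
#'   (inclusive 1-based integer range).
#' @examples
#' resolve_window(frame_schedule(), 15, 45)$frames  # 24:29
#' @export
resolve_window <- function(schedule, start_min, end_min, name = NULL) {
  assert_schedule(schedule)
  if (!is.numeric(start_min) || !is.numeric(end_min) || end_min <= start_min) {
    stop("window must satisfy end_min > start_min")
  }
  start_s <- start_min * 60
  end_s <- end_min * 60
  tol <- 1e-6
  i1 <- which(abs(schedule$start_s - start_s) < tol)
  i2 <- which(abs(schedule$end_s - end_s) < tol)
  if (!length(i1) || !length(i2)) {
    edges <- sort(unique(c(schedule$start_s, schedule$end_s))) / 60
    near <- function(x) edges[which.min(abs(edges - x))]
    stop(sprintf(
      paste0("window [%g, %g] min does not align with frame boundaries; ",
             "nearest frame edges are %g and %g min"),
      start_min, end_min, near(start_min), near(end_min)
    ))
  }
  structure(
    list(name = if (is.null(name)) sprintf("%g-%g min", start_min, end_min) else name,
         start_min = start_min, end_min = end_min,
         frames = seq.int(i1, i2)),
    class = "sbr_window"
  )
}

#' The four named SBR windows
#'
#' Early peak (15-45 min), short early (27-45 min), late pseudo-equilibrium
#' (51-81 min), and short late (57-75 min) static windows. On the default
#' 37-frame schedule these resolve to frames 24-29, 27-29, 31-35 and 32-34.
#'
#' @param schedule a [frame_schedule()] object.
#' @param which character vector of window names to resolve.
#' @return named list of `sbr_window` objects.
#' @export
sbr_windows <- function(schedule = frame_schedule(),
                        which = c("early", "short_early", "late", "short_late")) {
  defs <- list(
    early = c(15, 45), short_early = c(27, 45),
    late = c(51, 81), short_late = c(57, 75)
  )
  which <- match.arg(which, names(defs), several.ok = TRUE)
  out <- lapply(which, function(nm) {
    resolve_window(schedule, defs[[nm]][1], defs[[nm]][2], name = nm)
  })
  names(out) <- which
  out
}

#' Check that a schedule supports the named SBR windows
#'
#' Resolves the four named windows and verifies the default-protocol frame
#' correspondence (early 24-29, short early 27-29, late 31-35, short late
#' 32-34) whenever the schedule has the default 37-frame layout. Fails
#' loudly on misalignment.
#'
#' @param schedule a [frame_schedule()] object.
#' @return data frame mapping window name to start/end minutes and first/last
#'   frame index, invisibly printed by the analysis drivers.
#' @export
validate_schedule <- function(schedule = frame_schedule()) {
  ws <- sbr_windows(schedule)
  map <- do.call(rbind, lapply(ws, function(w) {
    data.frame(window = w$name, start_min = w$start_min, end_min = w$end_min,
               first_frame = min(w$frames), last_frame = max(w$frames))
  }))
  rownames(map) <- NULL
  expected <- list(early = c(24, 29), short_early = c(27, 29),
                   late = c(31, 35), short_late = c(32, 34))
  if (nrow(schedule) == 37 && abs(max(schedule$end_s) - 5580) < 1e-6) {
    for (nm in names(expected)) {
      got <- c(map$first_frame[map$window == nm], map$last_frame[map$window == nm])
      if (!identical(as.numeric(got), as.numeric(expected[[nm]]))) {
        stop(sprintf("window '%s' resolves to frames %d-%d, expected %d-%d",
                     nm, got[1], got[2], expected[[nm]][1], expected[[nm]][2]))
      }
    }
  }
  map
}

#' Duration-weighted mean of a TAC over a window
#'
#' Static images are formed by averaging frames; with unequal frame
#' durations the physically meaningful average is duration-weighted:
#' `sum(value_i * dur_i) / sum(dur_i)` over the window's frames.
#'
#' @param values numeric vector of frame values, one per schedule frame.
#' @param schedule a [frame_schedule()] object.
#' @param window a `sbr_window` from [resolve_window()].
#' @return scalar mean concentration over the window.
#' @export
window_mean <- function(values, schedule, window) {
  assert_schedule(schedule)
  if (!inherits(window, "sbr_window")) stop("`window` must come from resolve_window()")
  if (length(values) != nrow(schedule)) {
    stop("`values` must have one entry per schedule frame")
  }
  idx <- window$frames
  if (!length(idx)) stop("empty window")
  w <- schedule$dur_s[idx]
  sum(values[idx] * w) / sum(w)
}
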