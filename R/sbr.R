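#' Specific binding ratio from a static window
#'
#' `SBR = SUV_VOI / SUV_CER - 1`, the window mean of the target TAC over the
#' window mean of the cerebellar reference TAC minus one. At equilibrium
#' this ratio approximates `BP_ND`; its bias depends on the window placement
#' relative to the tracer's peak-equilibrium and washout phases.
#'
#' @param voi frame-level target TAC.
#' @param cer frame-level cerebellar reference TAC.
#' @param schedule a [frame_schedule()] object.
#' @param window a `sbr_window` from [resolve_window()] or [sbr_windows()].
#' @return a list: `window`, `suv_voi`, `suv_cer`, `sbr`.
#' @examples
#' sched <- frame_schedule()
#' ref <- simulate_reference_tac(sched)
#' tgt <- srtm_forward(ref, kinetic_params(0.9, 0.35, 3), sched)
#' compute_sbr(tgt, ref, sched, sbr_windows(sched)$early)$sbr
#' @export
compute_sbr <- function(voi, cer, schedule, window) {
  suv_voi <- window_mean(as.numeric(voi), schedule, window)
  suv_cer <- window_mean(as.numeric(cer), schedule, window)
  if (!is.finite(suv_cer) || suv_cer <= 0) {
    stop("reference window mean must be positive")
  }
  list(window = window$name, suv_voi = suv_voi, suv_cer = suv_cer,
       sbr = suv_voi / suv_cer - 1)
}

#' Read / write multi-region TAC tables
#'
#' The on-disk TAC format is a CSV with columns `frame_start_s`,
#' `frame_end_s` and one column per region holding decay-corrected
#' activity concentrations.
#'
#' @param path file path.
#' @return `read_tac_csv`: a list with `schedule` (a [frame_schedule()])
#'   and `values` (named list of numeric vectors, one per region).
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame_start_s", "frame_end_s")
  if (!all(need %in% names(df))) stop("TAC CSV must have frame_start_s,frame_end_s")
  sched <- data.frame(frame = seq_len(nrow(df)),
                      start_s = df$frame_start_s, end_s = df$frame_end_s,
                      dur_s = df$frame_end_s - df$frame_start_s)
  class(sched) <- c("frame_schedule", "data.frame")
  assert_schedule(sched)
  regions <- setdiff(names(df), need)
  list(schedule = sched, values = lapply(stats::setNames(regions, regions),
                                         function(r) df[[r]]))
}

#' @rdname read_tac_csv
#' @param schedule a [frame_schedule()] object.
#' @param values named list of frame-value vectors (one per region).
#' @export
write_tac_csv <- function(schedule, values, path) {
  assert_schedule(schedule)
  df <- data.frame(frame_start_s = schedule$start_s, frame_end_s = schedule$end_s)
  for (r in names(values)) {
    v <- as.numeric(values[[r]])
    if (length(v) != nrow(schedule)) stop("region '", r, "' length mismatch")
    df[[r]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
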