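#' Cohort group specification
#'
#' Defines one diagnostic group by its size and the per-region moments of
#' the ground-truth kinetic parameters. Defaults mirror published group
#' summary statistics for [18F]FE-PE2I DAT binding (see
#' [published_group_moments()]): controls n = 24 with caudate BP_ND
#' 2.98 +/- 0.66 and putamen 4.30 +/- 0.79; PD patients n = 33 with
#' caudate 1.73 +/- 0.58 and putamen 1.28 +/- 0.56.
#'
#' @param name group label, `"controls"` or `"pd"`.
#' @param n number of subjects, >= 2.
#' @param bp named list of `c(mean, sd)` BP_ND moments per region.
#' @param r1,k2 `c(mean, sd)` moments of R1 (unitless) and k2 (1/min),
#'   shared across target regions.
#' @return a `group_spec` list.
#' @export
group_spec <- function(name, n, bp, r1 = c(0.90, 0.06), k2 = c(0.35, 0.06)) {
  if (n < 2) stop("group size must be >= 2")
  chk <- function(m, what) {
    if (length(m) != 2 || !all(is.finite(m)) || m[2] < 0) {
      stop(what, " must be c(mean, sd) with sd >= 0")
    }
  }
  for (r in names(bp)) chk(bp[[r]], paste0("bp$", r))
  chk(r1, "r1"); chk(k2, "k2")
  structure(list(name = name, n = as.integer(n), bp = bp, r1 = r1, k2 = k2),
            class = "group_spec")
}

#' @rdname group_spec
#' @export
default_groups <- function() {
  list(
    controls = group_spec("controls", 24,
                          bp = list(caudate = c(2.98, 0.66), putamen = c(4.30, 0.79))),
    pd = group_spec("pd", 33,
                    bp = list(caudate = c(1.73, 0.58), putamen = c(1.28, 0.56)))
  )
}

#' Session specification for repeated scans
#'
#' @param n_sessions scans per subject (1 = cross-sectional).
#' @param interval_years inter-session interval; ~0 for test-retest
#'   (scans days apart), 2 for the longitudinal design.
#' @param jitter_sd within-subject session-to-session multiplicative SD
#'   (fraction) applied to all kinetic parameters, modelling physiological
#'   and repositioning variability; includes the reference-region clearance.
#' @param apc_true true annual percentage change of BP_ND (%/year, applied
#'   multiplicatively: session at interval T has BP scaled by
#'   `(1 + apc_true/100)^T`).
#' @param jitter_scope `"all"` jitters every kinetic parameter of the scan;
#'   `"reference_clearance"` restricts the jitter to the cerebellar efflux
#'   rate k2ref, isolating the clearance sensitivity of late tissue ratios.
#' @return a `session_spec` list.
#' @export
session_spec <- function(n_sessions = 1, interval_years = 0,
                         jitter_sd = 0.03, apc_true = 0,
                         jitter_scope = c("all", "reference_clearance")) {
  if (interval_years < 0) stop("interval_years must be >= 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(n_sessions = as.integer(n_sessions),
                 interval_years = interval_years,
                 jitter_sd = jitter_sd, apc_true = apc_true,
                 jitter_scope = match.arg(jitter_scope)),
            class = "session_spec")
}

#' Frame-noise model
#'
#' Gaussian frame noise whose variance follows the count-statistics
#' heuristic `var_i = alpha^2 * C_i * C_scan / dt_i`, with `C_i` the
#' noise-free frame value, `C_scan` the duration-weighted scan mean of the
#' same TAC (which makes the relative noise level independent of the
#' arbitrary activity units) and `dt_i` the frame duration in minutes.
#' `alpha = 0` yields noise-free TACs.
#'
#' @param alpha unitless noise scale, >= 0.
#' @return a `noise_model` list.
#' @export
noise_model <- function(alpha = 0.05) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0")
  structure(list(alpha = alpha), class = "noise_model")
}

# Truncated-normal draws by inverse-CDF; sd = 0 degenerates to the mean.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) {
    if (mean < lower) stop("degenerate spec: mean below truncation bound")
    return(rep(mean, n))
  }
  p_lo <- stats::pnorm(lower, mean, sd)
  if (p_lo > 0.999) {
    stop(sprintf("impossible truncation: mean %.3g with sd %.3g almost entirely below %.3g",
                 mean, sd, lower))
  }
  stats::qnorm(stats::runif(n, p_lo, 1), mean, sd)
}

# Deterministic seed splitting: fold a stream of small integers into the
# master seed with an LCG step, keeping everything below 2^31 - 1.
split_seed <- function(master, ...) {
  s <- as.numeric(master) %% 2147483647
  for (k in c(...)) {
    s <- (s * 69069 + as.numeric(k) * 1234567 + 12345) %% 2147483647
  }
  as.integer(s)
}

#' Draw ground-truth kinetic parameters for subjects of a group
#'
#' Truncated-normal draws (lower bound 0.05 for BP_ND and R1, 0.01 for k2)
#' of the target-region parameters; deterministic given `seed`.
#'
#' @param g a [group_spec()].
#' @param region region name present in `g$bp`.
#' @param n number of subjects to draw.
#' @param seed optional integer seed (set before drawing when given).
#' @return data frame with columns `R1`, `k2`, `bp_nd`, one row per draw.
#' @export
sample_subject_params <- function(g, region, n = g$n, seed = NULL) {
  if (!inherits(g, "group_spec")) stop("`g` must be a group_spec")
  if (!region %in% names(g$bp)) stop("unknown region '", region, "'")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    R1 = rtruncnorm_lower(n, g$r1[1], g$r1[2], 0.05),
    k2 = rtruncnorm_lower(n, g$k2[1], g$k2[2], 0.01),
    bp_nd = rtruncnorm_lower(n, g$bp[[region]][1], g$bp[[region]][2], 0.05)
  )
}

#' TAC-level partial-volume mixing
#'
#' Crude stand-in for image-space smoothing to clinical scanner resolution:
#' each target TAC is mixed with the reference TAC,
#' `target' = (1 - m) * target + m * reference`, and the reference receives
#' the complementary spill-in from the mean of the original target TACs.
#' `m = 0` is the identity.
#'
#' @param tacs named list of frame-value vectors including `cerebellum`.
#' @param m mixing coefficient, `0 <= m < 0.5`.
#' @return the mixed TAC list.
#' @export
apply_partial_volume_mixing <- function(tacs, m) {
  if (!is.numeric(m) || m < 0 || m >= 0.5) stop("m must satisfy 0 <= m < 0.5")
  if (m == 0) return(tacs)
  if (!"cerebellum" %in% names(tacs)) stop("tacs must include a 'cerebellum' region")
  cer <- as.numeric(tacs$cerebellum)
  targets <- setdiff(names(tacs), "cerebellum")
  mixed <- tacs
  for (r in targets) mixed[[r]] <- (1 - m) * as.numeric(tacs[[r]]) + m * cer
  tmean <- Reduce(`+`, lapply(tacs[targets], as.numeric)) / length(targets)
  mixed$cerebellum <- (1 - m) * cer + m * tmean
  mixed
}

add_frame_noise <- function(values, schedule, alpha) {
  v <- as.numeric(values)
  if (alpha == 0) return(v)
  dur_min <- schedule$dur_s / 60
  c_scan <- sum(v * dur_min) / sum(dur_min)
  sd_i <- alpha * sqrt(pmax(v, 0) * max(c_scan, 0) / dur_min)
  v + stats::rnorm(length(v), 0, sd_i)
}

#' Simulate a cohort of subject TACs with known ground truth
#'
#' For every subject and session, generates a cerebellar reference TAC from
#' the plasma input via a one-tissue model and caudate/putamen TACs via the
#' forward SRTM, then applies optional partial-volume mixing and frame
#' noise. Longitudinal sessions scale the true BP_ND by
#' `(1 + apc_true/100)^interval`; session jitter perturbs the realised
#' kinetic parameters (including reference delivery and clearance)
#' multiplicatively without changing the recorded truth.
#'
#' Randomness is fully reproducible: the master seed is split
#' deterministically per subject (parameter draws) and per subject-session
#' (jitter and noise), so any subject can be regenerated in isolation.
#'
#' @param groups list of [group_spec()] objects; default [default_groups()].
#' @param sessions a [session_spec()].
#' @param noise a [noise_model()].
#' @param schedule a [frame_schedule()].
#' @param seed master integer seed.
#' @param input an [input_function()].
#' @param ref_kinetics `c(K1ref, k2ref)` population means of the reference
#'   one-tissue parameters (mL/cm^3/min, 1/min).
#' @param ref_cv between-subject coefficient of variation of the reference
#'   parameters (fraction).
#' @param pvc_m partial-volume mixing coefficient (0 disables).
#' @param dt_s fine-grid step (s) for the kinetic simulation.
#' @return a `dat_cohort` list: `manifest` (one row per subject-session with
#'   group, interval and true/realised parameters), `tacs` (named list
#'   `<subject>_s<session>` of region TAC vectors), `schedule`, and the
#'   resolved configuration in `config`.
#' @export
simulate_cohort <- function(groups = default_groups(),
                            sessions = session_spec(),
                            noise = noise_model(),
                            schedule = frame_schedule(),
                            seed = 1,
                            input = input_function(),
                            ref_kinetics = c(K1ref = 0.15, k2ref = 0.05),
                            ref_cv = 0.10,
                            pvc_m = 0,
                            dt_s = 1) {
  assert_schedule(schedule)
  if (!inherits(sessions, "session_spec")) stop("`sessions` must be a session_spec")
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model")
  regions <- unique(unlist(lapply(groups, function(g) names(g$bp))))
  manifest <- list()
  tacs <- list()
  subj_counter <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    prefix <- toupper(substr(g$name, 1, 1))
    for (i in seq_len(g$n)) {
      subj_counter <- subj_counter + 1L
      sid <- sprintf("%s%03d", prefix, i)
      if (sid %in% vapply(manifest, `[[`, character(1), "subject_id")) {
        stop("duplicate subject id: ", sid)
      }
      set.seed(split_seed(seed, gi, i, 0L))
      pars <- lapply(stats::setNames(regions, regions), function(r) {
        as.list(sample_subject_params(g, r, n = 1))
      })
      k1ref <- rtruncnorm_lower(1, ref_kinetics[["K1ref"]],
                                ref_cv * ref_kinetics[["K1ref"]], 1e-3)
      k2ref <- rtruncnorm_lower(1, ref_kinetics[["k2ref"]],
                                ref_cv * ref_kinetics[["k2ref"]], 1e-3)
      for (s in seq_len(sessions$n_sessions)) {
        interval <- (s - 1L) * sessions$interval_years
        decline <- (1 + sessions$apc_true / 100)^interval
        # jitter and frame noise use separate sub-streams so that two
        # configurations differing only in jitter share noise draws
        set.seed(split_seed(seed, gi, i, s, 7L))
        jit <- function(target = "other") {
          if (sessions$jitter_sd == 0) return(1)
          if (sessions$jitter_scope != "all" && target != sessions$jitter_scope) {
            return(1)
          }
          max(1 + stats::rnorm(1, 0, sessions$jitter_sd), 0.5)
        }
        # draw jitters in a fixed order so streams stay aligned across
        # configs; the clearance factor scales the tracer's whole washout
        # (plasma clearance phases and reference-tissue efflux together)
        j_clear <- jit("reference_clearance"); j_k1 <- jit()
        sess_input <- input
        sess_input$l2 <- input$l2 * j_clear
        sess_input$l3 <- input$l3 * j_clear
        sess_ref <- simulate_reference_tac(schedule, k1ref * j_k1,
                                           k2ref * j_clear,
                                           sess_input, dt_s = dt_s)
        sess_tacs <- list()
        row <- list(subject_id = sid, group = g$name, session = s,
                    interval_years = interval,
                    k1ref = k1ref * j_k1, k2ref = k2ref * j_clear)
        for (r in regions) {
          true_bp <- pars[[r]]$bp_nd * decline
          kp <- kinetic_params(pars[[r]]$R1 * jit(), pars[[r]]$k2 * jit(),
                               max(true_bp * jit(), 1e-3))
          sess_tacs[[r]] <- srtm_forward(sess_ref, kp, schedule, dt_s = dt_s)
          row[[paste0("true_bp_", r)]] <- true_bp
          row[[paste0("true_r1_", r)]] <- pars[[r]]$R1
          row[[paste0("true_k2_", r)]] <- pars[[r]]$k2
        }
        sess_tacs$cerebellum <- sess_ref
        if (pvc_m > 0) sess_tacs <- apply_partial_volume_mixing(sess_tacs, pvc_m)
        set.seed(split_seed(seed, gi, i, s, 8L))
        sess_tacs <- lapply(sess_tacs, function(v) {
          add_frame_noise(v, schedule, noise$alpha)
        })
        manifest[[length(manifest) + 1L]] <- row
        tacs[[paste0(sid, "_s", s)]] <- sess_tacs
      }
    }
  }
  manifest <- do.call(rbind, lapply(manifest, function(r) as.data.frame(r)))
  structure(list(
    manifest = manifest, tacs = tacs, schedule = schedule,
    config = list(groups = groups, sessions = sessions, noise = noise,
                  seed = seed, ref_kinetics = as.list(ref_kinetics),
                  ref_cv = ref_cv, pvc_m = pvc_m, dt_s = dt_s,
                  input = unclass(input))
  ), class = "dat_cohort")
}

#' @export
print.dat_cohort <- function(x, ...) {
  cat(sprintf("<dat_cohort: %d subject-sessions, %d frames, groups: %s>\n",
              nrow(x$manifest), nrow(x$schedule),
              paste(unique(x$manifest$group), collapse = ", ")))
  invisible(x)
}

#' Write cohort TACs and manifest to a directory
#'
#' @param cohort a `dat_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed); one TAC CSV per
#'   subject-session plus `manifest.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (nm in names(cohort$tacs)) {
    write_tac_csv(cohort$schedule, cohort$tacs[[nm]],
                  file.path(dir, paste0(nm, "_tac.csv")))
  }
  invisible(dir)
}
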