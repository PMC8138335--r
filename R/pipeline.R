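#' Quantify a simulated or loaded cohort
#'
#' Runs the full quantification for every subject-session: SRTM basis-
#' function fit of BP_ND for each target region against the cerebellar
#' TAC, and SBR over the requested static windows. The SRTM basis is
#' computed once per session and shared across regions.
#'
#' @param cohort a `dat_cohort` from [simulate_cohort()] (or an equivalent
#'   list with `manifest`, `tacs`, `schedule`).
#' @param windows character vector of named windows (see [sbr_windows()]).
#' @param fit_bp logical; fit SRTM BP_ND (set `FALSE` to skip the kinetic
#'   fit and compute SBRs only).
#' @param dt_s fine-grid step (s) used by the fitter.
#' @param verbose print one line per subject-session.
#' @return long-format data frame: `subject_id`, `group`, `session`,
#'   `interval_years`, `region`, `outcome`
#'   (`bp_srtm`, `sbr_early`, ...), `value`, plus `true_bp` for reference.
#' @export
quantify_cohort <- function(cohort,
                            windows = c("early", "short_early", "late", "short_late"),
                            fit_bp = TRUE, dt_s = 1, verbose = FALSE) {
  schedule <- cohort$schedule
  ws <- sbr_windows(schedule, which = windows)
  man <- cohort$manifest
  regions <- setdiff(names(cohort$tacs[[1]]), "cerebellum")
  rows <- vector("list", nrow(man) * length(regions) * (length(ws) + fit_bp))
  ri <- 0L
  for (i in seq_len(nrow(man))) {
    key <- paste0(man$subject_id[i], "_s", man$session[i])
    tacs <- cohort$tacs[[key]]
    if (is.null(tacs)) stop("missing TACs for ", key)
    cer <- tacs$cerebellum
    basis <- if (fit_bp) srtm_basis(cer, schedule, dt_s = dt_s) else NULL
    for (r in regions) {
      tgt <- tacs[[r]]
      true_bp <- man[[paste0("true_bp_", r)]][i]
      if (is.null(true_bp)) true_bp <- NA_real_
      base <- list(subject_id = man$subject_id[i], group = man$group[i],
                   session = man$session[i],
                   interval_years = man$interval_years[i],
                   region = r, true_bp = true_bp)
      if (fit_bp) {
        fit <- fit_srtm(tgt, basis)
        ri <- ri + 1L
        rows[[ri]] <- c(base, list(outcome = "bp_srtm", value = fit$bp_nd))
      }
      for (w in ws) {
        ri <- ri + 1L
        rows[[ri]] <- c(base, list(outcome = paste0("sbr_", w$name),
                                   value = compute_sbr(tgt, cer, schedule, w)$sbr))
      }
    }
    if (verbose) {
      message(sprintf("quantified %s (%d/%d)", key, i, nrow(man)))
    }
  }
  out <- do.call(rbind, lapply(rows[seq_len(ri)], as.data.frame))
  out[, c("subject_id", "group", "session", "interval_years", "region",
          "outcome", "value", "true_bp")]
}

#' Group binding summary and bias (cross-sectional report)
#'
#' Mean +/- SD per group, region and outcome, plus the percentage bias of
#' each SBR measure against the same group's mean SRTM BP_ND.
#'
#' @param outcomes long outcome table from [quantify_cohort()]
#'   (session 1 rows are used).
#' @return data frame: `outcome`, `region`, `group`, `n`, `mean`, `sd`,
#'   `bias_percent`.
#' @export
report_binding <- function(outcomes) {
  oc <- outcomes[outcomes$session == 1, ]
  agg <- stats::aggregate(value ~ outcome + region + group, oc,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v)))
  out <- data.frame(agg[, c("outcome", "region", "group")],
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"])
  bp <- out[out$outcome == "bp_srtm", ]
  out$bias_percent <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (out$outcome[i] == "bp_srtm") next
    ref <- bp$mean[bp$region == out$region[i] & bp$group == out$group[i]]
    if (length(ref) == 1) out$bias_percent[i] <- bias_percent(out$mean[i], ref)
  }
  out[order(out$region, out$outcome, out$group), ]
}

#' Discrimination report: effect size, COV, t test, ROC AUC
#'
#' @param outcomes long outcome table from [quantify_cohort()] with two
#'   groups (controls first by the `controls` label); session 1 rows used.
#' @param controls_label,patients_label group labels.
#' @return data frame per outcome x region: `cohens_d`, `cov_percent`,
#'   `t`, `p_adjusted`, `auc`.
#' @export
report_discrimination <- function(outcomes, controls_label = "controls",
                                  patients_label = "pd") {
  oc <- outcomes[outcomes$session == 1, ]
  key <- unique(oc[, c("outcome", "region")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    sel <- oc$outcome == key$outcome[i] & oc$region == key$region[i]
    x <- oc$value[sel & oc$group == controls_label]
    y <- oc$value[sel & oc$group == patients_label]
    tt <- two_sample_t(x, y)
    data.frame(outcome = key$outcome[i], region = key$region[i],
               cohens_d = cohens_d(x, y), cov_percent = cov_percent(c(x, y)),
               t = tt$t, p_adjusted = tt$p_adjusted, auc = roc_auc(x, y))
  })
  do.call(rbind, out)
}

# Reshape a two-session outcome table into per-subject pairs.
session_pairs <- function(outcomes, outcome, region) {
  sel <- outcomes$outcome == outcome & outcomes$region == region
  oc <- outcomes[sel, ]
  v1 <- oc[oc$session == 1, c("subject_id", "value")]
  v2 <- oc[oc$session == 2, c("subject_id", "value", "interval_years")]
  m <- merge(v1, v2, by = "subject_id", suffixes = c("_1", "_2"))
  if (!nrow(m)) stop("no paired sessions for ", outcome, "/", region)
  m
}

#' Test-retest report: AbsVar, ICC, SEM
#'
#' @param outcomes long outcome table from a two-session cohort with
#'   negligible inter-session interval.
#' @return data frame per outcome x region: `n`, `absvar_mean`,
#'   `absvar_sd`, `icc`, `sem`.
#' @export
report_retest <- function(outcomes) {
  key <- unique(outcomes[, c("outcome", "region")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    p <- session_pairs(outcomes, key$outcome[i], key$region[i])
    av <- abs_var(p$value_1, p$value_2)
    icc <- icc_oneway(p$value_1, p$value_2)
    data.frame(outcome = key$outcome[i], region = key$region[i], n = nrow(p),
               absvar_mean = mean(av), absvar_sd = stats::sd(av),
               icc = icc, sem = sem_measure(c(p$value_1, p$value_2), icc))
  })
  do.call(rbind, out)
}

#' Longitudinal report: APC and paired t test
#'
#' @param outcomes long outcome table from a two-session cohort with a
#'   positive inter-session interval.
#' @return data frame per outcome x region: `n`, `apc_mean`, `apc_sd`,
#'   `paired_t`, `p_adjusted`.
#' @export
report_longitudinal <- function(outcomes) {
  key <- unique(outcomes[, c("outcome", "region")])
  out <- lapply(seq_len(nrow(key)), function(i) {
    p <- session_pairs(outcomes, key$outcome[i], key$region[i])
    a <- apc(p$value_1, p$value_2, p$interval_years)
    tt <- paired_t(p$value_1, p$value_2)
    data.frame(outcome = key$outcome[i], region = key$region[i], n = nrow(p),
               apc_mean = mean(a), apc_sd = stats::sd(a),
               paired_t = tt$t, p_adjusted = tt$p_adjusted)
  })
  do.call(rbind, out)
}

#' Default in-silico study configuration
#'
#' Cross-sectional two-group cohort (24 controls, 33 PD), a 9-patient
#' test-retest arm (two sessions, negligible interval) and a 12-patient
#' longitudinal arm (two sessions two years apart, true decline
#' -8 %/year), all on the default 37-frame schedule.
#'
#' @param seed master seed.
#' @param alpha frame-noise scale (see [noise_model()]).
#' @param jitter_sd within-subject session jitter (see [session_spec()]).
#' @param apc_true true annual percentage change for the longitudinal arm.
#' @param n_retest,n_longitudinal arm sizes.
#' @param dt_s fine-grid step (s).
#' @return a `study_config` list.
#' @export
study_config <- function(seed = 1, alpha = 0.05, jitter_sd = 0.03,
                         apc_true = -8, n_retest = 9, n_longitudinal = 12,
                         dt_s = 1) {
  structure(list(
    seed = seed, schedule = frame_schedule(), groups = default_groups(),
    noise = noise_model(alpha), jitter_sd = jitter_sd, apc_true = apc_true,
    n_retest = as.integer(n_retest), n_longitudinal = as.integer(n_longitudinal),
    dt_s = dt_s
  ), class = "study_config")
}

#' Run the full in-silico study
#'
#' Simulates the three cohorts, quantifies every subject-session (SRTM
#' BP_ND + four SBR windows) and assembles the binding/bias,
#' discrimination, test-retest and longitudinal reports. Deterministic
#' given the config's master seed; each arm derives its own sub-seed.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, all outcome and report
#'   tables plus the resolved configuration (JSON) are written there.
#' @param verbose print stage progress.
#' @return list: `outcomes` (named list of the three long outcome tables),
#'   `binding`, `discrimination`, `retest`, `longitudinal`, `window_map`,
#'   `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  window_map <- validate_schedule(config$schedule)
  stage <- function(msg) if (verbose) message(sprintf("[run_study] %s", msg))
  pd_spec <- config$groups$pd

  stage("simulating cross-sectional cohort")
  cross <- simulate_cohort(
    groups = config$groups,
    sessions = session_spec(1, 0, config$jitter_sd, 0),
    noise = config$noise, schedule = config$schedule,
    seed = split_seed(config$seed, 101L), dt_s = config$dt_s)

  stage("simulating test-retest cohort")
  retest_group <- group_spec("pd", config$n_retest, bp = pd_spec$bp,
                             r1 = pd_spec$r1, k2 = pd_spec$k2)
  retest <- simulate_cohort(
    groups = list(pd = retest_group),
    sessions = session_spec(2, 12 / 365, config$jitter_sd, 0),
    noise = config$noise, schedule = config$schedule,
    seed = split_seed(config$seed, 202L), dt_s = config$dt_s)

  stage("simulating longitudinal cohort")
  long_group <- group_spec("pd", config$n_longitudinal, bp = pd_spec$bp,
                           r1 = pd_spec$r1, k2 = pd_spec$k2)
  longi <- simulate_cohort(
    groups = list(pd = long_group),
    sessions = session_spec(2, 2, config$jitter_sd, config$apc_true),
    noise = config$noise, schedule = config$schedule,
    seed = split_seed(config$seed, 303L), dt_s = config$dt_s)

  stage("quantifying (SRTM fits + SBR windows)")
  oc_cross <- quantify_cohort(cross, dt_s = config$dt_s)
  oc_retest <- quantify_cohort(retest, dt_s = config$dt_s)
  oc_long <- quantify_cohort(longi, dt_s = config$dt_s)

  stage("building reports")
  res <- list(
    outcomes = list(cross = oc_cross, retest = oc_retest, longitudinal = oc_long),
    binding = report_binding(oc_cross),
    discrimination = report_discrimination(oc_cross),
    retest = report_retest(oc_retest),
    longitudinal = report_longitudinal(oc_long),
    window_map = window_map,
    config = config
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res$outcomes)) {
      utils::write.csv(res$outcomes[[nm]],
                       file.path(out_dir, paste0("outcomes_", nm, ".csv")),
                       row.names = FALSE)
    }
    for (nm in c("binding", "discrimination", "retest", "longitudinal",
                 "window_map")) {
      utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    cfg <- config
    cfg$schedule <- as.data.frame(cfg$schedule)
    jsonlite::write_json(cfg, file.path(out_dir, "study_config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stage(paste("artifacts written to", out_dir))
  }
  res
}
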