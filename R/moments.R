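#' Published group summary statistics for [18F]FE-PE2I DAT binding
#'
#' Group means and SDs of the five outcome measures (SRTM BP_ND and the
#' four SBR windows) in caudate and putamen, for healthy controls (n = 24)
#' and PD patients (n = 33), as reported for the reference HRRT cohort.
#' These moments serve two purposes: they parameterise the default
#' synthetic cohort, and they are the inputs from which between-group
#' effect sizes and combined-sample COVs can be recomputed exactly
#' (see [cohens_d_moments()] and [cov_percent_moments()]).
#'
#' @return data frame with columns `outcome`, `region`, `group`, `n`,
#'   `mean`, `sd`.
#' @export
published_group_moments <- function() {
  rows <- rbind(
    c("bp_srtm",         "caudate", "controls", 24, 2.98, 0.66),
    c("bp_srtm",         "putamen", "controls", 24, 4.30, 0.79),
    c("bp_srtm",         "caudate", "pd",       33, 1.73, 0.58),
    c("bp_srtm",         "putamen", "pd",       33, 1.28, 0.56),
    c("sbr_early",       "caudate", "controls", 24, 2.99, 0.70),
    c("sbr_early",       "putamen", "controls", 24, 4.15, 0.88),
    c("sbr_early",       "caudate", "pd",       33, 1.90, 0.63),
    c("sbr_early",       "putamen", "pd",       33, 1.51, 0.61),
    c("sbr_short_early", "caudate", "controls", 24, 4.00, 1.04),
    c("sbr_short_early", "putamen", "controls", 24, 5.45, 1.36),
    c("sbr_short_early", "caudate", "pd",       33, 2.47, 0.81),
    c("sbr_short_early", "putamen", "pd",       33, 1.85, 0.81),
    c("sbr_late",        "caudate", "controls", 24, 4.97, 1.82),
    c("sbr_late",        "putamen", "controls", 24, 6.96, 2.39),
    c("sbr_late",        "caudate", "pd",       33, 2.84, 0.94),
    c("sbr_late",        "putamen", "pd",       33, 1.89, 0.96),
    c("sbr_short_late",  "caudate", "controls", 24, 4.95, 1.82),
    c("sbr_short_late",  "putamen", "controls", 24, 6.96, 2.39),
    c("sbr_short_late",  "caudate", "pd",       33, 2.86, 0.94),
    c("sbr_short_late",  "putamen", "pd",       33, 1.89, 0.97)
  )
  out <- data.frame(outcome = rows[, 1], region = rows[, 2], group = rows[, 3],
                    n = as.integer(rows[, 4]), mean = as.numeric(rows[, 5]),
                    sd = as.numeric(rows[, 6]))
  out
}

#' Recompute group-discrimination statistics from published moments
#'
#' For each outcome and region, reconstructs the combined-sample SD from
#' the two groups' moments and derives Cohen's d (controls minus patients
#' over the combined SD), the combined-sample COV, and the percentage bias
#' of each SBR measure against the group-mean BP_ND.
#'
#' @param moments a moments table in the layout of
#'   [published_group_moments()].
#' @return data frame: `outcome`, `region`, `cohens_d`, `cov_percent`,
#'   `bias_controls`, `bias_pd` (bias NA for the BP_ND row itself).
#' @export
moment_discrimination <- function(moments = published_group_moments()) {
  key <- unique(moments[, c("outcome", "region")])
  get <- function(o, r, g, f) {
    moments[[f]][moments$outcome == o & moments$region == r & moments$group == g]
  }
  out <- lapply(seq_len(nrow(key)), function(i) {
    o <- key$outcome[i]; r <- key$region[i]
    m1 <- get(o, r, "controls", "mean"); s1 <- get(o, r, "controls", "sd")
    n1 <- get(o, r, "controls", "n")
    m2 <- get(o, r, "pd", "mean"); s2 <- get(o, r, "pd", "sd")
    n2 <- get(o, r, "pd", "n")
    bias_c <- bias_pd <- NA_real_
    if (o != "bp_srtm") {
      bias_c <- bias_percent(m1, get("bp_srtm", r, "controls", "mean"))
      bias_pd <- bias_percent(m2, get("bp_srtm", r, "pd", "mean"))
    }
    data.frame(outcome = o, region = r,
               cohens_d = cohens_d_moments(m1, s1, n1, m2, s2, n2),
               cov_percent = cov_percent_moments(m1, s1, n1, m2, s2, n2),
               bias_controls = bias_c, bias_pd = bias_pd)
  })
  do.call(rbind, out)
}
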