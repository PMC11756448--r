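#' Scoring configuration
#'
#' Collects the decision constants of the pipeline: the percent cell death
#' defining the margin of safety (20% by default, giving MOS20), the MOS cut
#' point below which a donor is DILI positive (100 xCmax by default, the
#' ROC-calibrated operating point), the cohort fraction above which a drug is
#' called at clinical DILI risk (10%), and the toxicity-score bin edges that
#' grade severity.
#'
#' @param death_pct Percent cell death defining the margin, in (0, 100).
#' @param cut_point MOS cut point in xCmax units (> 0); donors with
#'   `MOS <= cut_point` are DILI positive (boundary inclusive).
#' @param cohort_fraction_threshold Fraction of positive donors at or above
#'   which a drug is called at risk, in (0, 1).
#' @param severity_bin_edges Increasing edges on the toxicity-score scale
#'   splitting positive donors into low / moderate / high / severe.
#' @return A list of class `score_config`.
#' @export
score_config <- function(death_pct = 20, cut_point = 100,
                         cohort_fraction_threshold = 0.10,
                         severity_bin_edges = c(1, 2, 3)) {
  if (death_pct <= 0 || death_pct >= 100) {
    abort_invalid_argument("`death_pct` must lie strictly between 0 and 100")
  }
  if (cut_point <= 0) abort_invalid_argument("`cut_point` must be positive")
  if (cohort_fraction_threshold <= 0 || cohort_fraction_threshold >= 1) {
    abort_invalid_argument("`cohort_fraction_threshold` must lie in (0, 1)")
  }
  if (length(severity_bin_edges) != 3L || is.unsorted(severity_bin_edges, strictly = TRUE)) {
    abort_invalid_argument("`severity_bin_edges` must be 3 increasing values")
  }
  structure(
    list(death_pct = death_pct, cut_point = cut_point,
         cohort_fraction_threshold = cohort_fraction_threshold,
         severity_bin_edges = severity_bin_edges),
    class = "score_config"
  )
}

severity_levels <- c("none", "low", "moderate", "high", "severe")

#' Margin of safety at the configured percent cell death
#'
#' MOS20 is the concentration (in xCmax multiples) at which the fitted curve
#' predicts 20% loss of viability, i.e. IC20 / Cmax. Because doses are
#' expressed as Cmax multiples throughout, the inhibitory concentration is
#' already the margin relative to the therapeutic exposure. Censored
#' (non-toxic within range) or non-converged curves give `Inf`.
#'
#' @param fit A [fit_hill()] object.
#' @param config A [score_config()].
#' @return Positive margin, or `Inf`.
#' @export
mos20 <- function(fit, config = score_config()) {
  inhibitory_concentration(fit, config$death_pct)
}

#' Classify one donor as DILI positive or negative
#'
#' A donor is DILI positive when the margin of safety does not exceed the cut
#' point (boundary inclusive): the curve reaches the death threshold at or
#' below `cut_point` x Cmax.
#'
#' @param mos Margin of safety (positive, possibly `Inf`).
#' @param config A [score_config()].
#' @return Logical.
#' @export
classify_donor <- function(mos, config = score_config()) {
  if (any(!is.na(mos) & mos <= 0)) abort_invalid_argument("`mos` must be positive")
  mos <= config$cut_point
}

#' Toxicity score of one donor x drug
#'
#' The toxicity score used here is the log-distance of the margin of safety
#' below the cut point, clipped at zero:
#' `TS = max(0, log10(cut_point / MOS20))`. It is exactly zero for DILI
#' negative donors (MOS at or beyond the cut point, including `Inf`) and
#' grows as toxicity appears at concentrations ever further below the cut
#' point. This definition is this package's own reconstruction of a
#' curve-derived toxicity score: it is computed from LogIC50/HillSlope via
#' IC20, is positive exactly for DILI-positive donors, and orders severity.
#'
#' @param fit A [fit_hill()] object.
#' @param config A [score_config()].
#' @return Nonnegative score (log10 units).
#' @examples
#' d <- data.frame(dose_xcmax = c(0.01, 0.1, 1, 10, 100))
#' d$viability_pct <- 100 / (1 + d$dose_xcmax)
#' toxicity_score(fit_hill(d)) # log10(100 / 0.25) ~ 2.602
#' @export
toxicity_score <- function(fit, config = score_config()) {
  m <- mos20(fit, config)
  if (is.infinite(m)) return(0)
  max(0, log10(config$cut_point / m))
}

#' Severity grade from a toxicity score
#'
#' Zero maps to `none`; positive scores are binned by the configured edges
#' (defaults 1, 2, 3 on the log10 score scale) into `low`, `moderate`,
#' `high`, `severe`. The grade is monotone in the score.
#'
#' @param ts Nonnegative toxicity score(s).
#' @param config A [score_config()].
#' @return Ordered factor with levels none < low < moderate < high < severe.
#' @export
severity_grade <- function(ts, config = score_config()) {
  if (any(is.na(ts)) || any(ts < 0)) {
    abort_invalid_argument("`ts` must be nonnegative")
  }
  e <- config$severity_bin_edges
  idx <- ifelse(ts == 0, 1L,
         ifelse(ts <= e[1], 2L,
         ifelse(ts <= e[2], 3L,
         ifelse(ts <= e[3], 4L, 5L))))
  factor(severity_levels[idx], levels = severity_levels, ordered = TRUE)
}

#' Score every donor x drug curve in a viability table
#'
#' Fits all curves with [fit_cohort()] and derives, per donor x drug, the
#' margin of safety, toxicity score, DILI flag and severity grade.
#'
#' @param records Viability records (`donor_id`, `drug`, `dose_xcmax`,
#'   `replicate`, `viability_pct`).
#' @param config A [score_config()].
#' @return Data.frame of donor x drug scores: `donor_id`, `drug`, `log_ic50`,
#'   `hill_slope`, `converged`, `mos20`, `ts`, `dili_positive`, `severity`.
#' @export
score_cohort <- function(records, config = score_config()) {
  fits_tab <- fit_cohort(records)
  fits <- attr(fits_tab, "fits")
  m <- vapply(fits, mos20, numeric(1), config = config)
  ts <- vapply(fits, toxicity_score, numeric(1), config = config)
  out <- data.frame(
    donor_id = fits_tab$donor_id,
    drug = fits_tab$drug,
    log_ic50 = fits_tab$log_ic50,
    hill_slope = fits_tab$hill_slope,
    converged = fits_tab$converged,
    mos20 = m,
    ts = ts,
    dili_positive = classify_donor(m, config),
    severity = severity_grade(ts, config),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}
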