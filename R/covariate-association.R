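#' Partial eta-squared from one-way ANOVA
#'
#' Effect size of a categorical factor on a numeric outcome:
#' `eta_p^2 = SS_between / (SS_between + SS_within)`, with the p-value from
#' the one-way ANOVA F test. With a single factor this equals classical
#' eta-squared. Degenerate inputs are handled explicitly: identical group
#' means give effect 0 (p = 1 when there is also no residual variance);
#' distinct means with zero within-group variance give effect 1, p = 0.
#'
#' @param outcome Numeric outcome vector.
#' @param group Factor (or coercible) with at least 2 levels, each observed
#'   at least twice.
#' @return List with `effect_size` and `p_value`.
#' @examples
#' eta_squared_partial(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' @export
eta_squared_partial <- function(outcome, group) {
  group <- factor(group)
  if (length(outcome) != length(group)) {
    abort_invalid_argument("`outcome` and `group` must have equal length")
  }
  if (any(!is.finite(outcome))) abort_invalid_argument("`outcome` must be finite")
  counts <- table(group)
  if (length(counts) < 2L) {
    abort_insufficient_data("need at least 2 groups")
  }
  if (any(counts < 2L)) {
    abort_insufficient_data(sprintf(
      "every group needs >= 2 observations (smallest: %s with %d)",
      names(counts)[which.min(counts)], min(counts)
    ))
  }
  if (stats::var(outcome) == 0) {
    return(list(effect_size = 0, p_value = 1))
  }
  fit <- stats::lm(outcome ~ group)
  # degenerate decompositions (ssb = 0 or ssw = 0) are interpreted explicitly
  # below; anova's "essentially perfect fit" warning adds nothing there
  an <- suppressWarnings(stats::anova(fit))
  ssb <- an$`Sum Sq`[1]
  ssw <- an$`Sum Sq`[2]
  if (ssb <= 0 || (ssb + ssw) == 0) {
    return(list(effect_size = 0, p_value = 1))
  }
  if (ssw == 0) {
    return(list(effect_size = 1, p_value = 0))
  }
  list(effect_size = ssb / (ssb + ssw), p_value = an$`Pr(>F)`[1])
}

#' R-squared of a simple linear regression
#'
#' Ordinary least squares of a numeric outcome on a continuous covariate,
#' returning the coefficient of determination and the slope's F-test
#' p-value.
#'
#' @param outcome Numeric outcome vector (>= 3 observations).
#' @param covariate Numeric covariate, not constant.
#' @return List with `effect_size` (R-squared) and `p_value`.
#' @export
regression_r2 <- function(outcome, covariate) {
  if (length(outcome) != length(covariate)) {
    abort_invalid_argument("`outcome` and `covariate` must have equal length")
  }
  if (length(outcome) < 3L) {
    abort_insufficient_data("need at least 3 paired observations")
  }
  if (any(!is.finite(outcome)) || any(!is.finite(covariate))) {
    abort_invalid_argument("inputs must be finite")
  }
  if (stats::var(covariate) == 0) {
    abort_invalid_argument("`covariate` is constant; slope is not estimable")
  }
  if (stats::var(outcome) == 0) {
    return(list(effect_size = 0, p_value = 1))
  }
  fit <- stats::lm(outcome ~ covariate)
  # an exactly linear outcome (R^2 = 1) is interpreted explicitly below
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  p <- if (r2 >= 1) 0 else stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                                     sm$fstatistic[3L], lower.tail = FALSE)
  list(effect_size = r2, p_value = unname(p))
}

#' Cohen effect-size label
#'
#' Conventional guideline bins for eta-p-squared-scale effects: negligible
#' below 0.01, small to 0.06, medium to 0.13, large above 0.13.
#'
#' @param effect_size Effect size(s) in \[0, 1\].
#' @return Factor negligible < small < medium < large.
#' @export
cohen_label <- function(effect_size) {
  lv <- c("negligible", "small", "medium", "large")
  idx <- ifelse(effect_size > 0.13, 4L,
         ifelse(effect_size > 0.06, 3L,
         ifelse(effect_size >= 0.01, 2L, 1L)))
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Sex- and age-association table for DILI risk and severity
#'
#' For every drug, quantifies how donor sex and age relate to the DILI
#' outcome and its severity:
#' * sex vs risk — one-way ANOVA of the 0/1 DILI flag on sex (eta-p-squared);
#' * sex vs severity — ANOVA of the toxicity score on sex;
#' * age vs risk — ANOVA of the 0/1 flag on age dichotomized at `age_cut`
#'   (default 52 years, the adverse-drug-reaction age threshold);
#' * age vs severity — OLS R-squared of the toxicity score on continuous age.
#'
#' Risk enters the ANOVA as a 0/1 indicator (a linear-probability
#' simplification). Raw p-values are reported by default; `adjust = "BH"`
#' applies Benjamini-Hochberg across the table.
#'
#' @param scores [score_cohort()] output (needs `donor_id`, `drug`,
#'   `dili_positive`, `ts`).
#' @param donors Donor metadata with `donor_id`, `sex`, `age`.
#' @param age_cut Age dichotomization point in years for the risk ANOVA.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame: `drug`, `factor`, `outcome`, `effect_size`, `p_value`,
#'   `effect_label`. Cells whose ANOVA/regression is not estimable for a
#'   cohort (e.g. a single donor in one sex) are returned as `NA` with a
#'   warning.
#' @export
association_table <- function(scores, donors, age_cut = 52, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- c("donor_id", "drug", "dili_positive", "ts")
  if (!all(need %in% names(scores))) {
    abort_invalid_argument("`scores` needs donor_id, drug, dili_positive, ts")
  }
  if (!all(c("donor_id", "sex", "age") %in% names(donors))) {
    abort_invalid_argument("`donors` needs donor_id, sex, age")
  }
  missing <- setdiff(unique(scores$donor_id), donors$donor_id)
  if (length(missing)) {
    abort_join(sprintf("no metadata for donor(s): %s", paste(missing, collapse = ", ")))
  }
  dat <- merge(scores, donors[, c("donor_id", "sex", "age")], by = "donor_id")

  one_cell <- function(drug, fac, outc, fun) {
    res <- tryCatch(fun(), dili_error = function(e) {
      warning(sprintf("%s %s~%s not estimable: %s", drug, fac, outc,
                      conditionMessage(e)), call. = FALSE)
      list(effect_size = NA_real_, p_value = NA_real_)
    })
    data.frame(drug = drug, factor = fac, outcome = outc,
               effect_size = res$effect_size, p_value = res$p_value,
               stringsAsFactors = FALSE)
  }

  rows <- lapply(split(dat, dat$drug), function(d) {
    drug <- d$drug[1]
    risk <- as.numeric(d$dili_positive)
    age_grp <- factor(ifelse(d$age >= age_cut, "older", "younger"),
                      levels = c("younger", "older"))
    rbind(
      one_cell(drug, "sex", "risk",
               function() eta_squared_partial(risk, d$sex)),
      one_cell(drug, "sex", "severity",
               function() eta_squared_partial(d$ts, d$sex)),
      one_cell(drug, "age", "risk",
               function() eta_squared_partial(risk, age_grp)),
      one_cell(drug, "age", "severity",
               function() regression_r2(d$ts, d$age))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  out$effect_label <- cohen_label(out$effect_size)
  out
}
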