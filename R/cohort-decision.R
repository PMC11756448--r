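#' Drug-level DILI risk call from donor classifications
#'
#' Aggregates one drug's donor DILI flags into a cohort decision: the drug is
#' called at clinical DILI risk when at least the configured fraction of
#' donors (10% by default) is DILI positive, boundary inclusive.
#'
#' @param scores Donor x drug score rows for a single drug (needs `drug` and
#'   `dili_positive` columns), e.g. a subset of [score_cohort()] output.
#' @param config A [score_config()].
#' @param clinical_dili Optional known clinical label for the drug.
#' @return One-row data.frame: `drug`, `n_donors`, `n_positive`,
#'   `positive_fraction`, `positive_pct` (percent rounded half away from zero
#'   to one decimal, the convention for text outputs), `predicted_risk`,
#'   `clinical_dili`.
#' @examples
#' s <- data.frame(drug = "x", dili_positive = c(rep(TRUE, 2), rep(FALSE, 22)))
#' call_drug_risk(s) # 8.3%, no risk
#' @export
call_drug_risk <- function(scores, config = score_config(), clinical_dili = NA) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    abort_invalid_argument("`scores` must be a non-empty data.frame")
  }
  if (!all(c("drug", "dili_positive") %in% names(scores))) {
    abort_invalid_argument("`scores` needs columns `drug` and `dili_positive`")
  }
  drugs <- unique(scores$drug)
  if (length(drugs) != 1L) {
    abort_invalid_argument(sprintf(
      "`scores` must contain a single drug, found: %s",
      paste(drugs, collapse = ", ")
    ))
  }
  n <- nrow(scores)
  npos <- sum(scores$dili_positive)
  frac <- npos / n
  data.frame(
    drug = drugs,
    n_donors = n,
    n_positive = npos,
    positive_fraction = frac,
    positive_pct = round_percent1(100 * frac),
    predicted_risk = frac >= config$cohort_fraction_threshold,
    clinical_dili = clinical_dili,
    stringsAsFactors = FALSE
  )
}

#' Cohort risk calls for every drug in a score table
#'
#' @param scores Output of [score_cohort()] (any number of drugs).
#' @param drug_meta Optional data.frame with `drug` and `clinical_dili`
#'   columns supplying clinical labels.
#' @param config A [score_config()].
#' @return Data.frame with one [call_drug_risk()] row per drug.
#' @export
cohort_results <- function(scores, drug_meta = NULL, config = score_config()) {
  labels <- NULL
  if (!is.null(drug_meta)) {
    if (!all(c("drug", "clinical_dili") %in% names(drug_meta))) {
      abort_invalid_argument("`drug_meta` needs columns `drug` and `clinical_dili`")
    }
    labels <- stats::setNames(drug_meta$clinical_dili, drug_meta$drug)
  }
  rows <- lapply(split(scores, scores$drug), function(s) {
    lab <- if (!is.null(labels) && s$drug[1] %in% names(labels)) {
      labels[[s$drug[1]]]
    } else {
      NA
    }
    call_drug_risk(s, config, clinical_dili = lab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$drug), , drop = FALSE]
}

#' Confusion-matrix performance of drug risk calls
#'
#' Compares predicted drug-level risk with clinical DILI labels and reports
#' the confusion matrix with sensitivity and specificity in percent.
#'
#' @param results Data.frame of cohort results with `predicted_risk` and a
#'   known (non-NA) logical `clinical_dili` per drug.
#' @return List of class `dili_performance`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity` (percent).
#' @export
performance <- function(results) {
  need <- c("predicted_risk", "clinical_dili")
  if (!is.data.frame(results) || !all(need %in% names(results))) {
    abort_invalid_argument("`results` needs columns predicted_risk and clinical_dili")
  }
  if (any(is.na(results$clinical_dili))) {
    abort_invalid_argument("every result needs a known clinical label")
  }
  lab <- as.logical(results$clinical_dili)
  if (!any(lab)) abort_undefined_metric("no clinical-positive drugs: sensitivity undefined")
  if (all(lab)) abort_undefined_metric("no clinical-negative drugs: specificity undefined")
  pred <- as.logical(results$predicted_risk)
  tp <- sum(pred & lab); fn <- sum(!pred & lab)
  tn <- sum(!pred & !lab); fp <- sum(pred & !lab)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp)),
    class = "dili_performance"
  )
}

#' @export
print.dili_performance <- function(x, ...) {
  cat(sprintf(
    "<dili_performance> TP %d FP %d TN %d FN %d | sensitivity %.1f%%, specificity %.1f%%\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' ROC analysis of the margin of safety as a DILI predictor
#'
#' Each donor x drug pair is one observation, labeled by the drug's clinical
#' DILI status, and scored by `-MOS20` (a lower margin of safety means
#' toxicity closer to the therapeutic exposure, hence a more positive
#' prediction). The ROC is traced by sweeping the decision rule
#' `MOS20 <= cut` over all unique finite margins plus the two degenerate
#' cuts; infinite margins (non-toxic curves) take part as the least-positive
#' score rather than being dropped, since dropping them would bias
#' specificity. AUC is computed by the trapezoidal rule (equal to the
#' Mann-Whitney pairwise concordance), and the optimal cut point maximizes
#' Youden's J = sensitivity + specificity - 1, ties resolved toward the
#' smaller margin.
#'
#' @param scores Data.frame with `drug` and `mos20` columns (donor-level).
#' @param drug_meta Data.frame with `drug` and logical `clinical_dili`.
#' @return List of class `dili_roc`: `auc`, `optimal_cut_point`, `youden_j`,
#'   `n_pos`, `n_neg`, and `points` (data.frame `cut`, `tpr`, `fpr`).
#' @export
roc_analysis <- function(scores, drug_meta) {
  if (!all(c("drug", "mos20") %in% names(scores))) {
    abort_invalid_argument("`scores` needs columns `drug` and `mos20`")
  }
  if (!all(c("drug", "clinical_dili") %in% names(drug_meta))) {
    abort_invalid_argument("`drug_meta` needs columns `drug` and `clinical_dili`")
  }
  labels <- stats::setNames(as.logical(drug_meta$clinical_dili), drug_meta$drug)
  missing <- setdiff(unique(scores$drug), names(labels))
  if (length(missing)) {
    abort_join(sprintf("no clinical label for drug(s): %s",
                       paste(missing, collapse = ", ")))
  }
  y <- labels[scores$drug]
  mos <- scores$mos20
  if (any(is.na(mos)) || any(mos <= 0)) {
    abort_invalid_argument("`mos20` values must be positive (Inf allowed)")
  }
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    abort_undefined_metric("ROC needs both clinical-positive and clinical-negative drugs")
  }

  cuts <- c(-Inf, sort(unique(mos[is.finite(mos)])), Inf)
  tpr <- vapply(cuts, function(cc) sum(mos <= cc & y) / n_pos, numeric(1))
  fpr <- vapply(cuts, function(cc) sum(mos <= cc & !y) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  j <- tpr - fpr
  finite <- is.finite(cuts)
  best_j <- max(j[finite])
  opt <- min(cuts[finite & j == best_j])

  structure(
    list(auc = auc, optimal_cut_point = opt, youden_j = best_j,
         n_pos = n_pos, n_neg = n_neg,
         points = data.frame(cut = cuts, tpr = tpr, fpr = fpr)),
    class = "dili_roc"
  )
}

#' @export
print.dili_roc <- function(x, ...) {
  cat(sprintf(
    "<dili_roc> AUC %.4f over %d positive / %d negative pairs; optimal cut %.4g xCmax (Youden J %.3f)\n",
    x$auc, x$n_pos, x$n_neg, x$optimal_cut_point, x$youden_j
  ))
  invisible(x)
}

#' Probability of detecting at least one event in a cohort
#'
#' The chance that a cohort of `n` donors contains at least one donor showing
#' an event of the given population incidence: `1 - (1 - incidence)^n`. With
#' n = 24 and 10% incidence this is 0.9202, the rationale behind 24-donor
#' cohorts.
#'
#' @param n Cohort size(s), >= 1.
#' @param incidence Event incidence in (0, 1).
#' @return Detection probability in (0, 1).
#' @examples
#' detection_power(24, 0.10) # 0.9202
#' @export
detection_power <- function(n, incidence) {
  if (any(!is.finite(n)) || any(n < 1)) abort_invalid_argument("`n` must be >= 1")
  if (!is.numeric(incidence) || any(incidence <= 0) || any(incidence >= 1)) {
    abort_invalid_argument("`incidence` must lie strictly between 0 and 1")
  }
  1 - (1 - incidence)^n
}

#' Smallest cohort detecting an event with target probability
#'
#' @param target_power Required detection probability in (0, 1).
#' @param incidence Event incidence in (0, 1).
#' @return Smallest integer `n` with `detection_power(n, incidence) >=
#'   target_power`.
#' @examples
#' min_cohort_size(0.92, 0.10) # 24
#' @export
min_cohort_size <- function(target_power, incidence) {
  if (target_power <= 0 || target_power >= 1) {
    abort_invalid_argument("`target_power` must lie strictly between 0 and 1")
  }
  if (incidence <= 0 || incidence >= 1) {
    abort_invalid_argument("`incidence` must lie strictly between 0 and 1")
  }
  n <- max(1L, ceiling(log(1 - target_power) / log(1 - incidence)) - 2L)
  while (detection_power(n, incidence) < target_power) n <- n + 1L
  as.integer(n)
}
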