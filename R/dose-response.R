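#' Fit the constrained inhibitory Hill model to one donor x drug
#'
#' Least-squares fit of the "log(inhibitor) vs. normalized response --
#' variable slope" model with the top and bottom plateaus fixed at 100 and 0:
#' `V(c) = 100 / (1 + 10^((log10(c) - log_ic50) * h))` with internal slope
#' `h > 0`. Following the reporting convention for inhibitory curves the
#' returned `hill_slope` is `-h`. Replicate wells enter the loss individually
#' (unweighted), and viability values above 100 are kept: clipping them would
#' bias the top plateau.
#'
#' Optimization is Levenberg-Marquardt ([minpack.lm::nlsLM()]) under box
#' bounds `log_ic50` in `[log10(min dose) - 2, log10(max dose) + 2]` and `h`
#' in `[0.1, 10]`, multi-started from 5 log-spaced `log_ic50` guesses across
#' the dose range; the best converged start (lowest RSS) wins. Failure of
#' every start yields `converged = FALSE`, never an error.
#'
#' A curve is flagged `censored_low_toxicity` when it cannot demonstrate the
#' 20%-death criterion within the tested range: the fitted curve predicts
#' viability above 80% at the maximum tested dose (or no fit converged).
#'
#' @param records Data.frame with columns `dose_xcmax` and `viability_pct`
#'   (rows for one donor x drug; `donor_id`/`drug`/`replicate` columns are
#'   carried along if present).
#' @param slope_bounds Length-2 bounds for the internal (positive) slope.
#' @param n_starts Number of log-spaced multi-start guesses.
#'
#' @return An object of class `hill_fit`: `log_ic50`, `hill_slope` (negative),
#'   `top` (100), `bottom` (0), `converged`, `rss`, `r_squared`, `n_points`,
#'   `censored_low_toxicity`, `max_dose`, plus `donor_id`/`drug` if supplied.
#' @examples
#' d <- data.frame(dose_xcmax = c(0.01, 0.1, 1, 10, 50, 100))
#' d$viability_pct <- 100 / (1 + d$dose_xcmax) # IC50 = 1 xCmax, slope 1
#' fit <- fit_hill(d)
#' c(fit$log_ic50, fit$hill_slope)
#' @export
fit_hill <- function(records, slope_bounds = c(0.1, 10), n_starts = 5L) {
  need <- c("dose_xcmax", "viability_pct")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort_invalid_argument(
      "`records` must be a data.frame with columns dose_xcmax and viability_pct"
    )
  }
  dose <- records$dose_xcmax
  viab <- records$viability_pct
  if (any(!is.finite(viab))) abort_invalid_argument("viability values must be finite")
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    abort_invalid_argument("doses must be positive and finite")
  }
  if (length(unique(dose)) < 3L) {
    abort_insufficient_data("need at least 3 distinct doses to fit a Hill curve")
  }

  x <- log10(dose)
  lo <- min(x) - 2
  hi <- max(x) + 2
  starts <- seq(min(x), max(x), length.out = n_starts)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        viab ~ 100 / (1 + 10^((x - L) * h)),
        start = list(L = s, h = 1),
        lower = c(lo, slope_bounds[1]),
        upper = c(hi, slope_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(coef = stats::coef(fit), rss = rss)
      }
    }
  }

  out <- list(
    log_ic50 = NA_real_, hill_slope = NA_real_, top = 100, bottom = 0,
    converged = FALSE, rss = NA_real_, r_squared = NA_real_,
    n_points = length(viab), censored_low_toxicity = TRUE,
    max_dose = max(dose),
    donor_id = if ("donor_id" %in% names(records)) records$donor_id[1] else NA_character_,
    drug = if ("drug" %in% names(records)) records$drug[1] else NA_character_
  )
  if (!is.null(best)) {
    L <- unname(best$coef["L"])
    h <- unname(best$coef["h"])
    tss <- sum((viab - mean(viab))^2)
    out$log_ic50 <- L
    out$hill_slope <- -h
    out$converged <- TRUE
    out$rss <- best$rss
    out$r_squared <- if (tss > 0) 1 - best$rss / tss else NA_real_
    pred_max <- 100 / (1 + 10^((log10(max(dose)) - L) * h))
    out$censored_low_toxicity <- pred_max > 80
  }
  structure(out, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<hill_fit> log10 IC50 = %.4g xCmax, HillSlope = %.4g (Top 100 / Bottom 0)\n  RSS %.4g, R^2 %s, n = %d%s\n",
      x$log_ic50, x$hill_slope, x$rss,
      ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
      x$n_points,
      ifelse(x$censored_low_toxicity, ", censored (low toxicity in range)", "")
    ))
  } else {
    cat("<hill_fit> not converged\n")
  }
  invisible(x)
}

#' Predicted viability from a fitted Hill curve
#'
#' @param fit A converged [fit_hill()] object.
#' @param dose Positive dose(s) in xCmax units.
#' @return Viability percent; continuous and strictly decreasing in dose.
#' @export
predict_viability <- function(fit, dose) {
  if (!inherits(fit, "hill_fit")) abort_invalid_argument("`fit` must be a hill_fit")
  if (!fit$converged) abort_invalid_state("cannot predict from a non-converged fit")
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    abort_invalid_argument("`dose` must be positive and finite")
  }
  h <- abs(fit$hill_slope)
  100 / (1 + 10^((log10(dose) - fit$log_ic50) * h))
}

#' Inhibitory concentration at a given percent cell death
#'
#' Closed-form inverse of the constrained Hill curve:
#' `IC_p = 10^log_ic50 * (p / (100 - p))^(1 / h)`, the concentration at which
#' the fitted curve predicts `p` percent loss of viability. Returns `Inf`
#' when the fit is censored for low toxicity or did not converge — no toxic
#' concentration is observable within the tested range.
#'
#' @param fit A [fit_hill()] object.
#' @param death_pct Percent cell death in (0, 100); 50 gives the IC50.
#' @return Positive concentration in xCmax units, or `Inf`.
#' @examples
#' d <- data.frame(dose_xcmax = c(0.01, 0.1, 1, 10, 100))
#' d$viability_pct <- 100 / (1 + d$dose_xcmax)
#' inhibitory_concentration(fit_hill(d), 20) # 0.25 xCmax
#' @export
inhibitory_concentration <- function(fit, death_pct) {
  if (!inherits(fit, "hill_fit")) abort_invalid_argument("`fit` must be a hill_fit")
  if (!is.numeric(death_pct) || length(death_pct) != 1L ||
      death_pct <= 0 || death_pct >= 100) {
    abort_invalid_argument("`death_pct` must lie strictly between 0 and 100")
  }
  if (!fit$converged || fit$censored_low_toxicity) {
    return(Inf)
  }
  h <- abs(fit$hill_slope)
  10^fit$log_ic50 * (death_pct / (100 - death_pct))^(1 / h)
}

#' Fit all donor x drug curves in a viability table
#'
#' @param records Viability records for one or more donors and drugs.
#' @param ... Passed to [fit_hill()].
#' @return Data.frame with one row per donor x drug and the `hill_fit`
#'   fields as columns, plus a `fits` attribute holding the fit objects.
#' @export
fit_cohort <- function(records, ...) {
  need <- c("donor_id", "drug", "dose_xcmax", "viability_pct")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort_invalid_argument(
      "`records` must contain donor_id, drug, dose_xcmax, viability_pct"
    )
  }
  key <- interaction(records$donor_id, records$drug, drop = TRUE, sep = "\r")
  groups <- split(records, key)
  fits <- lapply(groups, fit_hill, ...)
  tab <- data.frame(
    donor_id = vapply(fits, `[[`, character(1), "donor_id"),
    drug = vapply(fits, `[[`, character(1), "drug"),
    log_ic50 = vapply(fits, `[[`, numeric(1), "log_ic50"),
    hill_slope = vapply(fits, `[[`, numeric(1), "hill_slope"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    censored_low_toxicity = vapply(fits, `[[`, logical(1), "censored_low_toxicity"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    n_points = vapply(fits, `[[`, integer(1), "n_points"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ord <- order(tab$drug, tab$donor_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
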