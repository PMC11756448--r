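#' Generate a synthetic donor cohort
#'
#' Draws donor demographics and a latent per-donor drug sensitivity emulating
#' the inter-individual variability a donor-dependent hepatotoxicity screen
#' assumes: sex from a Bernoulli draw, age uniform over a range, ABO blood
#' group from population-like frequencies, and a multiplicative sensitivity
#' (lognormal on the log10-IC50 scale) shared across drugs for a donor, so
#' that susceptibility to liver injury is a donor trait.
#'
#' @param n Number of donors (positive integer).
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @param age_range Length-2 numeric, inclusive age bounds in years.
#' @param sex_balance Probability that a donor is female, in \[0, 1\].
#' @param sensitivity_sd Standard deviation of the donor latent sensitivity on
#'   the log10 IC50 scale; 0 switches the shared latent off.
#' @param abo_freq Named numeric vector of ABO group sampling weights.
#'
#' @return A data.frame with columns `donor_id`, `sex` (factor M/F), `age`,
#'   `abo`, and `sensitivity` (positive; multiplies IC50).
#' @examples
#' donors <- generate_donors(24, seed = 1)
#' table(donors$sex)
#' @export
generate_donors <- function(n, seed = 1L, age_range = c(18, 80),
                            sex_balance = 0.5, sensitivity_sd = 0.25,
                            abo_freq = c(A = 0.40, B = 0.11, AB = 0.04, O = 0.45)) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort_invalid_argument("`n` must be a positive integer")
  }
  n <- as.integer(n)
  if (!is.numeric(sex_balance) || sex_balance < 0 || sex_balance > 1) {
    abort_invalid_argument("`sex_balance` must lie in [0, 1]")
  }
  if (length(age_range) != 2L || age_range[1] > age_range[2]) {
    abort_invalid_argument("`age_range` must be an increasing length-2 interval")
  }
  if (sensitivity_sd < 0) {
    abort_invalid_argument("`sensitivity_sd` must be nonnegative")
  }
  with_seed(seed, {
    data.frame(
      donor_id = sprintf("D%03d", seq_len(n)),
      sex = factor(ifelse(stats::runif(n) < sex_balance, "F", "M"),
                   levels = c("M", "F")),
      age = as.integer(round(stats::runif(n, age_range[1], age_range[2]))),
      abo = factor(sample(names(abo_freq), n, replace = TRUE, prob = abo_freq),
                   levels = c("A", "B", "AB", "O")),
      sensitivity = 10^stats::rnorm(n, 0, sensitivity_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Define a drug toxicity archetype
#'
#' An archetype is the generative truth for one drug: the cohort-median
#' potency, its lognormal spread across donors, the Hill steepness, an
#' optional viability floor encoding idiosyncratic (incomplete-kill) toxicity,
#' and optional sex/age covariate effects on potency. All doses are expressed
#' as multiples of Cmax, the therapeutic maximal plasma concentration.
#'
#' @param name Drug name.
#' @param clinical_dili Logical; the drug's clinical DILI label.
#' @param median_log_ic50 Cohort-median log10 IC50 in xCmax units.
#' @param donor_sd Across-donor SD of log10 IC50 (per drug), > 0.
#' @param hill Hill steepness, > 0.
#' @param plateau_floor Minimum viability percent in \[0, 100); values > 0
#'   give a plateauing, dose-independent ("idiosyncratic") response in which
#'   viability drops to the floor and then stays there.
#' @param sex_effect Additive shift of log10 IC50 for female donors.
#' @param age_slope Shift of log10 IC50 per year of age (centered at the
#'   cohort mean age).
#'
#' @return A list of class `drug_archetype`.
#' @examples
#' drug_archetype("examplinib", TRUE, median_log_ic50 = 0.5, donor_sd = 0.4)
#' @export
drug_archetype <- function(name, clinical_dili, median_log_ic50,
                           donor_sd = 0.4, hill = 1,
                           plateau_floor = 0, sex_effect = 0, age_slope = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_invalid_argument("`name` must be a non-empty string")
  }
  if (!is.logical(clinical_dili) || length(clinical_dili) != 1L) {
    abort_invalid_argument("`clinical_dili` must be TRUE or FALSE")
  }
  stopifnot_scalar_number(median_log_ic50, "median_log_ic50")
  if (donor_sd <= 0) abort_invalid_argument("`donor_sd` must be positive")
  if (hill <= 0) abort_invalid_argument("`hill` must be positive")
  if (plateau_floor < 0 || plateau_floor >= 100) {
    abort_invalid_argument("`plateau_floor` must lie in [0, 100)")
  }
  structure(
    list(name = name, clinical_dili = clinical_dili,
         median_log_ic50 = median_log_ic50, donor_sd = donor_sd,
         hill = hill, plateau_floor = plateau_floor,
         sex_effect = sex_effect, age_slope = age_slope),
    class = "drug_archetype"
  )
}

#' @export
print.drug_archetype <- function(x, ...) {
  cat(sprintf(
    "<drug_archetype> %s (clinical DILI: %s)\n  median log10 IC50 %.3g xCmax, donor SD %.3g, hill %.3g, floor %.3g%%\n",
    x$name, ifelse(x$clinical_dili, "yes", "no"),
    x$median_log_ic50, x$donor_sd, x$hill, x$plateau_floor
  ))
  invisible(x)
}

#' Define a viability plate design
#'
#' @param doses Strictly increasing positive concentrations in xCmax units;
#'   default log-spaced 0.01x to 100x Cmax.
#' @param replicates Replicate wells per dose (>= 1); default triplicate.
#' @param noise_sd SD of Gaussian plate noise on the percent-viability scale.
#' @param viability_cap Upper truncation for readouts (plate readers can
#'   report above 100% of vehicle control); lower truncation is 0.
#'
#' @return A list of class `plate_design`.
#' @export
plate_design <- function(doses = c(0.01, 0.1, 1, 10, 50, 100),
                         replicates = 3L, noise_sd = 5, viability_cap = 120) {
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    abort_invalid_argument("`doses` must be positive and finite")
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    abort_invalid_argument("`doses` must be strictly increasing")
  }
  if (min(doses) < 0.001) abort_invalid_argument("minimum dose must be >= 0.001 xCmax")
  if (replicates < 1) abort_invalid_argument("`replicates` must be >= 1")
  if (noise_sd < 0) abort_invalid_argument("`noise_sd` must be nonnegative")
  structure(
    list(doses = as.numeric(doses), replicates = as.integer(replicates),
         noise_sd = noise_sd, viability_cap = viability_cap),
    class = "plate_design"
  )
}

#' True viability of an archetype curve
#'
#' Evaluates the generative dose-response
#' `V(c) = floor + (100 - floor) / (1 + (c / IC50)^hill)`.
#'
#' @param dose Dose(s) in xCmax units.
#' @param ic50 IC50 in xCmax units.
#' @param hill Steepness > 0.
#' @param plateau_floor Minimum viability percent.
#' @return Viability percent, same length as `dose`.
#' @export
hill_viability <- function(dose, ic50, hill = 1, plateau_floor = 0) {
  plateau_floor + (100 - plateau_floor) / (1 + (dose / ic50)^hill)
}

#' Simulate plate-reader viability records for one drug
#'
#' For each donor the true log10 IC50 is
#' `median_log_ic50 + log10(sensitivity) + sex_effect * I(F) +
#' age_slope * (age - mean age) + Normal(0, donor_sd)`; each well reading is
#' the true curve value plus Gaussian noise, truncated to
#' `[0, viability_cap]`.
#'
#' @param donors Data.frame from [generate_donors()].
#' @param drug A [drug_archetype()].
#' @param design A [plate_design()].
#' @param seed Integer seed.
#' @param shared_sensitivity If `FALSE`, the shared donor latent is ignored
#'   (donor susceptibility is then independent across drugs, carried only by
#'   the per-drug `donor_sd` draw).
#'
#' @return Data.frame of viability records with columns
#'   `donor_id`, `drug`, `dose_xcmax`, `replicate`, `viability_pct`, one row
#'   per donor x dose x replicate.
#' @examples
#' donors <- generate_donors(4, seed = 1)
#' drug <- drug_archetype("examplinib", TRUE, 0.5)
#' head(simulate_viability(donors, drug, plate_design(), seed = 2))
#' @export
simulate_viability <- function(donors, drug, design = plate_design(),
                               seed = 1L, shared_sensitivity = TRUE) {
  if (!is.data.frame(donors) || nrow(donors) == 0L) {
    abort_invalid_argument("`donors` must be a non-empty donor data.frame")
  }
  if (!inherits(drug, "drug_archetype")) {
    abort_invalid_argument("`drug` must be a drug_archetype")
  }
  if (!inherits(design, "plate_design")) {
    abort_invalid_argument("`design` must be a plate_design")
  }
  n <- nrow(donors)
  with_seed(seed, {
    latent <- if (shared_sensitivity) log10(donors$sensitivity) else 0
    log_ic50 <- drug$median_log_ic50 + latent +
      drug$sex_effect * as.numeric(donors$sex == "F") +
      drug$age_slope * (donors$age - mean(donors$age)) +
      stats::rnorm(n, 0, drug$donor_sd)
    ic50 <- 10^log_ic50

    grid <- expand.grid(
      replicate = seq_len(design$replicates),
      dose_xcmax = design$doses,
      donor_idx = seq_len(n),
      KEEP.OUT.ATTRS = FALSE
    )
    truth <- hill_viability(grid$dose_xcmax, ic50[grid$donor_idx],
                            drug$hill, drug$plateau_floor)
    noisy <- if (design$noise_sd > 0) {
      truth + stats::rnorm(nrow(grid), 0, design$noise_sd)
    } else {
      truth
    }
    data.frame(
      donor_id = donors$donor_id[grid$donor_idx],
      drug = drug$name,
      dose_xcmax = grid$dose_xcmax,
      replicate = grid$replicate,
      viability_pct = pmin(pmax(noisy, 0), design$viability_cap),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a full cohort x drug-panel screen
#'
#' Convenience wrapper running [simulate_viability()] for every archetype in a
#' panel, with per-drug seeds derived deterministically from `seed`.
#'
#' @param donors Donor data.frame.
#' @param panel List of [drug_archetype()] objects.
#' @param design A [plate_design()].
#' @param seed Integer seed.
#' @inheritParams simulate_viability
#' @return Row-bound viability records for all drugs.
#' @export
simulate_panel <- function(donors, panel, design = plate_design(), seed = 1L,
                           shared_sensitivity = TRUE) {
  if (!length(panel)) abort_invalid_argument("`panel` must be non-empty")
  recs <- lapply(seq_along(panel), function(i) {
    simulate_viability(donors, panel[[i]], design,
                       seed = as.integer(seed) + 1000L * i,
                       shared_sensitivity = shared_sensitivity)
  })
  do.call(rbind, recs)
}

#' Demonstration 12-drug archetype panel
#'
#' A synthetic panel of 12 archetypes named after a well-known
#' hepatotoxicity screening set: 3 drugs without clinical DILI concern and 9
#' with, including an idiosyncratic plateauing archetype (incomplete kill,
#' viability floor ~65%) and archetypes with sex- and age-linked potency
#' shifts. Potencies are engineered so that a 24-donor cohort reproduces the
#' expected risk calls; it is openly synthetic, not a reconstruction of any
#' measured dataset.
#'
#' @return Named list of [drug_archetype()] objects.
#' @export
demo_drug_panel <- function() {
  p <- list(
    drug_archetype("albuterol",    FALSE, 3.40, donor_sd = 0.40),
    drug_archetype("flavoxate",    FALSE, 3.50, donor_sd = 0.40),
    drug_archetype("lenvatinib",   FALSE, 3.80, donor_sd = 0.35),
    drug_archetype("beta-estradiol", TRUE, 2.45, donor_sd = 0.45,
                   sex_effect = -0.45, age_slope = -0.010),
    drug_archetype("etoposide",    TRUE, 2.25, donor_sd = 0.50),
    drug_archetype("nizatidine",   TRUE, 2.55, donor_sd = 0.45,
                   age_slope = -0.022),
    drug_archetype("azathioprine", TRUE, 0.70, donor_sd = 0.50, hill = 2,
                   plateau_floor = 65),
    drug_archetype("oxaliplatin",  TRUE, 0.50, donor_sd = 0.30,
                   age_slope = -0.008),
    drug_archetype("bosentan",     TRUE, 0.60, donor_sd = 0.30),
    drug_archetype("stavudine",    TRUE, 2.60, donor_sd = 0.50),
    drug_archetype("cabozantinib", TRUE, 0.40, donor_sd = 0.30),
    drug_archetype("sorafenib",    TRUE, 0.55, donor_sd = 0.35)
  )
  names(p) <- vapply(p, `[[`, character(1), "name")
  p
}

#' Drug metadata table for a panel
#'
#' @param panel List of archetypes.
#' @return Data.frame with `drug` and `clinical_dili` columns.
#' @export
panel_metadata <- function(panel) {
  data.frame(
    drug = vapply(panel, `[[`, character(1), "name"),
    clinical_dili = vapply(panel, `[[`, logical(1), "clinical_dili"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
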