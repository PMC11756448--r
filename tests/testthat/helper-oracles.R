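# Fixtures and independent oracles used across the suite.

# Noiseless constrained-Hill viability table.
hill_curve_df <- function(ic50, h = 1, doses = c(0.01, 0.1, 1, 10, 50, 100),
                          floor = 0, replicates = 1L) {
  d <- expand.grid(replicate = seq_len(replicates), dose_xcmax = doses)
  d$viability_pct <- floor + (100 - floor) / (1 + (d$dose_xcmax / ic50)^h)
  d[, c("dose_xcmax", "replicate", "viability_pct")]
}

# Mann-Whitney pairwise-concordance AUC: positives should have SMALLER mos.
concordance_auc <- function(mos, positive) {
  pos <- mos[positive]
  neg <- mos[!positive]
  pairs <- outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b))
  # Inf vs Inf compares NA under Inf == Inf? no, Inf == Inf is TRUE in R.
  mean(pairs)
}

# Bisection root-finder for predicted viability == 100 - death_pct.
bisect_icp <- function(fit, death_pct, lo = 1e-12, hi = 1e12, tol = 1e-12) {
  target <- 100 - death_pct
  f <- function(x) predict_viability(fit, x) - target
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in 1:200) {
    mid <- sqrt(lo * hi) # bisect on log scale
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

# Build a minimal donor-score data.frame for cohort-rule tests.
fake_scores <- function(drug, n_pos, n_total) {
  data.frame(
    donor_id = sprintf("D%03d", seq_len(n_total)),
    drug = drug,
    dili_positive = c(rep(TRUE, n_pos), rep(FALSE, n_total - n_pos)),
    stringsAsFactors = FALSE
  )
}

# Cohort results mirroring a 12-drug screening table: 9 clinically positive
# drugs all predicted at risk, 3 negatives all clear.
twelve_drug_results <- function() {
  data.frame(
    drug = c("albuterol", "flavoxate", "lenvatinib", "beta-estradiol",
             "etoposide", "nizatidine", "azathioprine", "oxaliplatin",
             "bosentan", "stavudine", "cabozantinib", "sorafenib"),
    n_positive = c(2, 1, 0, 13, 18, 13, 22, 24, 24, 11, 24, 24),
    n_donors = 24L,
    clinical_dili = c(FALSE, FALSE, FALSE, rep(TRUE, 9)),
    stringsAsFactors = FALSE
  )
}
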