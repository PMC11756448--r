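test_that("generated donors respect cardinality, bounds and degenerate probabilities", {
  donors <- generate_donors(24, seed = 1)
  expect_equal(nrow(donors), 24L)
  expect_equal(anyDuplicated(donors$donor_id), 0L)
  expect_true(all(donors$age >= 18 & donors$age <= 80))
  expect_true(all(donors$sensitivity > 0))

  all_f <- generate_donors(24, seed = 2, sex_balance = 1)
  expect_true(all(all_f$sex == "F"))
  all_m <- generate_donors(24, seed = 2, sex_balance = 0)
  expect_true(all(all_m$sex == "M"))

  expect_error(generate_donors(0), class = "dili_invalid_argument")
  expect_error(generate_donors(10, sex_balance = 1.5),
               class = "dili_invalid_argument")
})

test_that("sex draw matches its Bernoulli rate at large n", {
  donors <- generate_donors(1000, seed = 7, sex_balance = 0.5)
  f_frac <- mean(donors$sex == "F")
  expect_lt(abs(f_frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("noiseless records lie exactly on the Hill curve and respect limits", {
  donors <- generate_donors(6, seed = 3, sensitivity_sd = 0)
  drug <- drug_archetype("x", TRUE, median_log_ic50 = 0, donor_sd = 1e-12)
  design <- plate_design(noise_sd = 0)
  recs <- simulate_viability(donors, drug, design, seed = 4)

  expect_equal(nrow(recs), 6 * length(design$doses) * design$replicates)
  # IC50 = 1 xCmax for every donor: dose at IC50 gives 50, dose -> 0 gives ~100
  expect_equal(recs$viability_pct[recs$dose_xcmax == 1], rep(50, 18))
  expect_true(all(recs$viability_pct[recs$dose_xcmax == 0.01] > 98))
  expect_equal(recs$viability_pct,
               100 / (1 + recs$dose_xcmax), tolerance = 1e-12)
})

test_that("plateau archetypes approach their viability floor at high dose", {
  donors <- generate_donors(5, seed = 5, sensitivity_sd = 0)
  drug <- drug_archetype("plat", TRUE, median_log_ic50 = 0, donor_sd = 1e-12,
                         hill = 2, plateau_floor = 65)
  recs <- simulate_viability(donors, drug, plate_design(noise_sd = 0), seed = 6)
  at100 <- recs$viability_pct[recs$dose_xcmax == 100]
  expect_true(all(abs(at100 - 65) < 0.1))
  # and never drops below the floor
  expect_true(all(recs$viability_pct >= 65))
})

test_that("simulation is reproducible per seed and varies across seeds", {
  donors <- generate_donors(8, seed = 11)
  drug <- drug_archetype("x", TRUE, 0.5)
  a <- simulate_viability(donors, drug, plate_design(), seed = 42)
  b <- simulate_viability(donors, drug, plate_design(), seed = 42)
  c <- simulate_viability(donors, drug, plate_design(), seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_identical(generate_donors(24, seed = 9), generate_donors(24, seed = 9))
})

test_that("expected viability is monotone non-increasing in dose for all archetypes", {
  donors <- generate_donors(3, seed = 12, sensitivity_sd = 0)
  for (drug in demo_drug_panel()) {
    recs <- simulate_viability(donors, drug, plate_design(noise_sd = 0), seed = 1)
    for (id in unique(recs$donor_id)) {
      v <- recs[recs$donor_id == id, ]
      v <- v[order(v$dose_xcmax, v$replicate), ]
      means <- tapply(v$viability_pct, v$dose_xcmax, mean)
      expect_true(all(diff(means[order(as.numeric(names(means)))]) <= 1e-9),
                  label = sprintf("monotone for %s", drug$name))
    }
  }
})

test_that("noise is truncated to [0, viability_cap]", {
  donors <- generate_donors(10, seed = 13)
  drug <- drug_archetype("noisy", TRUE, 0, donor_sd = 0.3)
  recs <- simulate_viability(donors, drug,
                             plate_design(noise_sd = 40, viability_cap = 120),
                             seed = 14)
  expect_true(all(recs$viability_pct >= 0))
  expect_true(all(recs$viability_pct <= 120))
})

test_that("covariate effects shift potency in the stated direction", {
  donors <- generate_donors(400, seed = 15, sensitivity_sd = 0)
  drug <- drug_archetype("sexed", TRUE, 1, donor_sd = 0.05, sex_effect = -0.6)
  recs <- simulate_viability(donors, drug, plate_design(noise_sd = 0), seed = 16)
  at1 <- recs[recs$dose_xcmax == 1 & recs$replicate == 1, ]
  at1 <- merge(at1, donors[, c("donor_id", "sex")], by = "donor_id")
  # lower IC50 for F => lower viability at a fixed dose
  expect_lt(mean(at1$viability_pct[at1$sex == "F"]),
            mean(at1$viability_pct[at1$sex == "M"]))
})

test_that("fitted log10 IC50 spread recovers the generative donor SD", {
  donors <- generate_donors(200, seed = 21, sensitivity_sd = 0)
  drug <- drug_archetype("x", TRUE, median_log_ic50 = 0.5, donor_sd = 0.5)
  recs <- simulate_viability(donors, drug, plate_design(noise_sd = 0), seed = 22)
  fits <- fit_cohort(recs)
  sd_hat <- stats::sd(fits$log_ic50[fits$converged])
  expect_lt(abs(sd_hat - 0.5) / 0.5, 0.20)
})

test_that("invalid simulator inputs are rejected", {
  drug <- drug_archetype("x", TRUE, 0)
  expect_error(simulate_viability(data.frame(), drug, plate_design(), 1),
               class = "dili_invalid_argument")
  expect_error(plate_design(doses = c(1, 1, 2)), class = "dili_invalid_argument")
  expect_error(plate_design(doses = c(-1, 1)), class = "dili_invalid_argument")
  expect_error(drug_archetype("x", TRUE, 0, donor_sd = 0),
               class = "dili_invalid_argument")
  expect_error(drug_archetype("x", TRUE, 0, plateau_floor = 100),
               class = "dili_invalid_argument")
})
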