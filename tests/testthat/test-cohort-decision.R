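test_that("cohort rule reproduces the printed worked fractions and calls", {
  cases <- list(
    list(pos = 2, pct = 8.3, risk = FALSE),
    list(pos = 1, pct = 4.2, risk = FALSE),
    list(pos = 18, pct = 75.0, risk = TRUE),
    list(pos = 22, pct = 91.7, risk = TRUE),
    list(pos = 11, pct = 45.8, risk = TRUE),
    list(pos = 24, pct = 100.0, risk = TRUE),
    list(pos = 0, pct = 0.0, risk = FALSE)
  )
  for (cs in cases) {
    res <- call_drug_risk(fake_scores("drugX", cs$pos, 24))
    expect_equal(res$n_positive, cs$pos)
    expect_equal(res$positive_pct, cs$pct)
    expect_identical(res$predicted_risk, cs$risk)
    expect_equal(res$positive_fraction, cs$pos / 24)
  }
})

test_that("cohort rule is order invariant, boundary inclusive, and rejects mixed drugs", {
  s <- fake_scores("d", 5, 24)
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(call_drug_risk(s)$positive_fraction,
               call_drug_risk(shuffled)$positive_fraction)

  # exactly 10% of donors positive => at risk
  s10 <- fake_scores("d", 2, 20)
  expect_true(call_drug_risk(s10)$predicted_risk)
  s_under <- fake_scores("d", 1, 20)
  expect_false(call_drug_risk(s_under)$predicted_risk)

  mixed <- rbind(fake_scores("a", 1, 2), fake_scores("b", 1, 2))
  expect_error(call_drug_risk(mixed), class = "dili_invalid_argument")
  expect_error(call_drug_risk(s[0, ]), class = "dili_invalid_argument")
})

test_that("confusion-matrix performance handles the 12-drug screen and its inversions", {
  tab <- twelve_drug_results()
  tab$predicted_risk <- tab$n_positive / tab$n_donors >= 0.10
  perf <- performance(tab)
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
  expect_equal(perf$tp, 9)
  expect_equal(perf$tn, 3)

  inverted <- tab
  inverted$predicted_risk <- !tab$predicted_risk
  perf_inv <- performance(inverted)
  expect_equal(perf_inv$sensitivity, 0)
  expect_equal(perf_inv$specificity, 0)

  # one missed positive out of nine
  miss1 <- tab
  miss1$predicted_risk[which(miss1$clinical_dili)[1]] <- FALSE
  perf_m <- performance(miss1)
  expect_equal(perf_m$sensitivity, 100 * 8 / 9, tolerance = 1e-12)
  expect_equal(perf_m$specificity, 100)

  one_class <- tab[tab$clinical_dili, ]
  expect_error(performance(one_class), class = "dili_undefined_metric")
  expect_match(tryCatch(performance(one_class), error = conditionMessage),
               "negative")
})

test_that("ROC analysis separates, matches the concordance oracle, and places the cut", {
  # perfectly separated cohorts: AUC 1, optimal cut between the groups
  sep <- data.frame(
    drug = rep(c("toxic", "safe"), each = 10),
    mos20 = c(stats::runif(10, 0.1, 5), stats::runif(10, 200, 1e4))
  )
  meta <- data.frame(drug = c("toxic", "safe"), clinical_dili = c(TRUE, FALSE))
  roc <- roc_analysis(sep, meta)
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden_j, 1)
  expect_lte(roc$optimal_cut_point, min(sep$mos20[sep$drug == "safe"]))
  expect_gte(roc$optimal_cut_point, max(sep$mos20[sep$drug == "toxic"]))

  # hand-built 4-point set with one inversion
  hand <- data.frame(drug = c("p1", "p2", "n1", "n2"),
                     mos20 = c(1, 50, 10, 100))
  hand_meta <- data.frame(drug = c("p1", "p2", "n1", "n2"),
                          clinical_dili = c(TRUE, TRUE, FALSE, FALSE))
  roc_hand <- roc_analysis(hand, hand_meta)
  expect_equal(roc_hand$auc,
               concordance_auc(hand$mos20, hand_meta$clinical_dili))
  expect_equal(roc_hand$auc, 0.75)

  # oracle equivalence on random instances, with ties and infinities
  set.seed(202)
  for (i in 1:20) {
    n <- 60
    df <- data.frame(
      drug = sample(c("a", "b", "c", "d"), n, replace = TRUE),
      mos20 = sample(c(10^stats::runif(n - 10, -2, 3), rep(Inf, 5),
                       rep(2.5, 5)))
    )
    m <- data.frame(drug = c("a", "b", "c", "d"),
                    clinical_dili = c(TRUE, TRUE, FALSE, FALSE))
    y <- m$clinical_dili[match(df$drug, m$drug)]
    if (length(unique(y)) < 2) next
    expect_equal(roc_analysis(df, m)$auc, concordance_auc(df$mos20, y),
                 tolerance = 1e-12)
  }

  expect_error(roc_analysis(sep, data.frame(drug = c("toxic", "safe"),
                                            clinical_dili = c(TRUE, TRUE))),
               class = "dili_undefined_metric")
})

test_that("ROC of label-permuted margins hovers at chance level", {
  set.seed(303)
  n <- 2000
  df <- data.frame(drug = sample(c("a", "b"), n, replace = TRUE),
                   mos20 = 10^stats::rnorm(n, 1, 1))
  m <- data.frame(drug = c("a", "b"), clinical_dili = c(TRUE, FALSE))
  roc <- roc_analysis(df, m)
  expect_lt(abs(roc$auc - 0.5), 0.05)
})

test_that("ROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(404)
  df <- data.frame(drug = sample(c("a", "b", "c"), 80, replace = TRUE),
                   mos20 = 10^stats::runif(80, -2, 3))
  m <- data.frame(drug = c("a", "b", "c"),
                  clinical_dili = c(TRUE, FALSE, TRUE))
  y <- m$clinical_dili[match(df$drug, m$drug)]
  ours <- roc_analysis(df, m)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(y, -df$mos20, direction = "<",
                                              quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("binomial detection power matches the closed form and a Monte Carlo oracle", {
  expect_equal(detection_power(24, 0.10), 1 - 0.9^24)
  expect_equal(round(detection_power(24, 0.10), 4), 0.9202)
  expect_equal(detection_power(1, 0.10), 0.10)

  set.seed(505)
  mc <- mean(stats::rbinom(1e6, 24, 0.10) > 0)
  expect_lt(abs(detection_power(24, 0.10) - mc), 0.001)

  expect_error(detection_power(24, 0), class = "dili_invalid_argument")
  expect_error(detection_power(24, 1), class = "dili_invalid_argument")
  expect_error(detection_power(0, 0.1), class = "dili_invalid_argument")
})

test_that("detection power is monotone and round-trips with the cohort planner", {
  ns <- 1:60
  expect_true(all(diff(detection_power(ns, 0.1)) > 0))
  # strictly increasing in incidence (below float saturation at power ~ 1)
  incs <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(detection_power(24, incs)) > 0))

  expect_equal(min_cohort_size(0.92, 0.10), 24L)
  expect_equal(min_cohort_size(0.5, 0.5), 1L)
  expect_equal(min_cohort_size(0.99, 0.10), 44L)

  set.seed(606)
  for (i in 1:25) {
    target <- stats::runif(1, 0.05, 0.995)
    inc <- stats::runif(1, 0.02, 0.9)
    n <- min_cohort_size(target, inc)
    expect_gte(detection_power(n, inc), target)
    if (n > 1) expect_lt(detection_power(n - 1, inc), target)
  }
})

test_that("safe and toxic archetypes are discriminated across seeds end to end", {
  safe <- drug_archetype("safe", FALSE, median_log_ic50 = 3.4, donor_sd = 0.4)
  toxic <- drug_archetype("toxic", TRUE, median_log_ic50 = 1.0, donor_sd = 0.4)
  design <- plate_design(noise_sd = 5)
  ok <- 0L
  for (seed in 1:20) {
    donors <- generate_donors(24, seed = seed)
    recs <- rbind(
      simulate_viability(donors, safe, design, seed = 7000 + seed),
      simulate_viability(donors, toxic, design, seed = 8000 + seed)
    )
    res <- cohort_results(score_cohort(recs))
    safe_ok <- !res$predicted_risk[res$drug == "safe"]
    toxic_ok <- res$predicted_risk[res$drug == "toxic"]
    if (safe_ok && toxic_ok) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})
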