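#' Run the full DILI risk pipeline on a scenario or on measured tables
#'
#' Orchestrates the analysis end to end: obtain viability records (simulated
#' from a [cohort_scenario()] or read from CSV), fit every donor x drug Hill
#' curve, derive margins of safety / toxicity scores / severity grades,
#' aggregate to drug-level risk calls, evaluate confusion-matrix performance
#' and the MOS ROC where clinical labels permit, and compute the sex/age
#' association table. Writes a machine-readable report bundle and returns
#' the pieces invisibly.
#'
#' Output files in `out_dir`:
#' * `donor_scores.tsv` — per donor x drug fit and score table;
#' * `cohort_results.tsv` — per-drug positive fractions and risk calls;
#' * `performance.json` — confusion matrix, sensitivity/specificity, AUC,
#'   optimal cut point and ROC points (full precision);
#' * `associations.tsv` — sex/age effect sizes per drug;
#' * `severity_matrix.tsv` — donors x drugs severity ordinals;
#' * `run_log.txt` — config echo and package version.
#'
#' Given the same inputs and seed the bundle is byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the simulation branch.
#' @param scenario A [cohort_scenario()]; ignored when `viability_csv` is
#'   given.
#' @param viability_csv,donors_csv,drugs_csv Optional measured inputs; all
#'   three must be given together.
#' @param config A [score_config()].
#' @param age_cut Age dichotomization for the association table (years).
#' @return Invisibly, a list with `scores`, `results`, `performance`, `roc`,
#'   `associations`, `severity_matrix`, `paths`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, scenario = cohort_scenario(),
                         viability_csv = NULL, donors_csv = NULL,
                         drugs_csv = NULL, config = score_config(),
                         age_cut = 52) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  from_files <- !is.null(viability_csv)
  if (from_files && (is.null(donors_csv) || is.null(drugs_csv))) {
    abort_invalid_argument(
      "measured-data runs need viability_csv, donors_csv and drugs_csv together"
    )
  }

  if (from_files) {
    records <- read_viability_csv(viability_csv)
    donors <- read_donors_csv(donors_csv)
    drug_meta <- read_drugs_csv(drugs_csv)
  } else {
    if (!inherits(scenario, "cohort_scenario")) {
      abort_invalid_argument("`scenario` must be a cohort_scenario")
    }
    donors <- generate_donors(
      scenario$n_donors, seed = seed, age_range = scenario$age_range,
      sex_balance = scenario$sex_balance,
      sensitivity_sd = scenario$sensitivity_sd
    )
    records <- simulate_panel(donors, scenario$panel, scenario$design,
                              seed = as.integer(seed) + 1L,
                              shared_sensitivity = scenario$shared_sensitivity)
    drug_meta <- panel_metadata(scenario$panel)
  }

  scores <- score_cohort(records, config)
  results <- cohort_results(scores, drug_meta, config)

  labeled <- results[!is.na(results$clinical_dili), , drop = FALSE]
  perf <- NULL
  roc <- NULL
  if (nrow(labeled) > 0 && length(unique(labeled$clinical_dili)) == 2L) {
    perf <- performance(labeled)
    roc <- roc_analysis(
      scores[scores$drug %in% labeled$drug, , drop = FALSE],
      drug_meta[!is.na(drug_meta$clinical_dili), , drop = FALSE]
    )
  }

  assoc <- association_table(scores, donors, age_cut = age_cut)

  sev <- severity_matrix(scores)

  paths <- list(
    donor_scores = file.path(out_dir, "donor_scores.tsv"),
    cohort_results = file.path(out_dir, "cohort_results.tsv"),
    performance = file.path(out_dir, "performance.json"),
    associations = file.path(out_dir, "associations.tsv"),
    severity_matrix = file.path(out_dir, "severity_matrix.tsv"),
    run_log = file.path(out_dir, "run_log.txt")
  )

  write_tsv <- function(df, path) {
    df <- as.data.frame(lapply(df, function(col) {
      if (is.factor(col)) as.character(col) else col
    }), stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_tsv(scores, paths$donor_scores)
  write_tsv(results, paths$cohort_results)
  write_tsv(assoc, paths$associations)
  sev_out <- data.frame(donor_id = rownames(sev), sev,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(sev_out, paths$severity_matrix)

  perf_obj <- list(
    n_drugs = nrow(results),
    performance = if (is.null(perf)) NULL else unclass(perf),
    roc = if (is.null(roc)) NULL else list(
      auc = roc$auc, optimal_cut_point = roc$optimal_cut_point,
      youden_j = roc$youden_j, n_pos = roc$n_pos, n_neg = roc$n_neg,
      points = roc$points
    )
  )
  jsonlite::write_json(perf_obj, paths$performance, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  log_lines <- c(
    sprintf("dilirisk %s", as.character(utils::packageVersion("dilirisk"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("input: %s", if (from_files) viability_csv else
      sprintf("simulated scenario (%d donors, %d drugs)",
              nrow(donors), length(unique(records$drug)))),
    sprintf("death_pct: %g", config$death_pct),
    sprintf("cut_point: %g xCmax", config$cut_point),
    sprintf("cohort_fraction_threshold: %g", config$cohort_fraction_threshold),
    sprintf("severity_bin_edges: %s", paste(config$severity_bin_edges, collapse = ", ")),
    sprintf("age_cut: %g", age_cut)
  )
  writeLines(log_lines, paths$run_log)

  invisible(list(scores = scores, results = results, performance = perf,
                 roc = roc, associations = assoc, severity_matrix = sev,
                 donors = donors, drug_meta = drug_meta, paths = paths))
}

#' Donors x drugs severity matrix
#'
#' Reshapes per donor x drug severity grades into the wide matrix used for
#' heatmap-style reporting.
#'
#' @param scores [score_cohort()] output.
#' @return Character matrix (donors x drugs) of severity ordinals.
#' @export
severity_matrix <- function(scores) {
  need <- c("donor_id", "drug", "severity")
  if (!all(need %in% names(scores))) {
    abort_invalid_argument("`scores` needs donor_id, drug, severity")
  }
  donors <- sort(unique(scores$donor_id))
  drugs <- sort(unique(scores$drug))
  m <- matrix(NA_character_, length(donors), length(drugs),
              dimnames = list(donors, drugs))
  m[cbind(match(scores$donor_id, donors), match(scores$drug, drugs))] <-
    as.character(scores$severity)
  m
}
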