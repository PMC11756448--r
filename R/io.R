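# File formats: CSV in (viability, donors, drugs), TSV/JSON out, YAML
# scenario configs. Validation errors cite the offending column and row.

check_header <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort_format(sprintf("%s: missing required column(s): %s",
                         path, paste(miss, collapse = ", ")))
  }
}

# data rows start at line 2 (after the header)
row_label <- function(i) sprintf("row %d (line %d)", i, i + 1L)

#' Read a plate-reader viability table
#'
#' Expected CSV schema: `donor_id,drug,dose_xcmax,replicate,viability_pct`
#' with doses as positive Cmax multiples and viability as nonnegative percent
#' of vehicle control.
#'
#' @param path CSV path.
#' @return Validated data.frame of viability records.
#' @export
read_viability_csv <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, c("donor_id", "drug", "dose_xcmax", "replicate", "viability_pct"), path)
  for (col in c("dose_xcmax", "replicate", "viability_pct")) {
    if (!is.numeric(df[[col]])) {
      abort_format(sprintf("%s: column `%s` must be numeric", path, col))
    }
  }
  bad <- which(!is.finite(df$dose_xcmax) | df$dose_xcmax <= 0)
  if (length(bad)) {
    abort_validation(sprintf("%s: non-positive dose_xcmax at %s",
                             path, row_label(bad[1])))
  }
  bad <- which(!is.finite(df$viability_pct) | df$viability_pct < 0)
  if (length(bad)) {
    abort_validation(sprintf("%s: negative or non-finite viability_pct at %s",
                             path, row_label(bad[1])))
  }
  df
}

#' Read donor metadata
#'
#' Expected CSV schema: `donor_id,sex,age,abo` with sex in {M, F}, age in
#' years, abo in {A, B, AB, O}.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_donors_csv <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, c("donor_id", "sex", "age", "abo"), path)
  if (anyDuplicated(df$donor_id)) {
    abort_validation(sprintf("%s: duplicated donor_id at %s", path,
                             row_label(which(duplicated(df$donor_id))[1])))
  }
  bad <- which(!df$sex %in% c("M", "F"))
  if (length(bad)) {
    abort_validation(sprintf("%s: sex must be M or F at %s", path, row_label(bad[1])))
  }
  if (!is.numeric(df$age)) abort_format(sprintf("%s: column `age` must be numeric", path))
  bad <- which(!is.finite(df$age) | df$age < 0 | df$age > 130)
  if (length(bad)) {
    abort_validation(sprintf("%s: implausible age at %s", path, row_label(bad[1])))
  }
  bad <- which(!df$abo %in% c("A", "B", "AB", "O"))
  if (length(bad)) {
    abort_validation(sprintf("%s: abo must be one of A/B/AB/O at %s",
                             path, row_label(bad[1])))
  }
  df$sex <- factor(df$sex, levels = c("M", "F"))
  df$abo <- factor(df$abo, levels = c("A", "B", "AB", "O"))
  df
}

#' Read drug metadata
#'
#' Expected CSV schema: `drug,clinical_dili[,cmax_ref]`; `clinical_dili` is
#' parsed as logical (TRUE/FALSE, yes/no, 1/0) and may be empty for unknown.
#'
#' @param path CSV path.
#' @return Data.frame with logical `clinical_dili`.
#' @export
read_drugs_csv <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, c("drug", "clinical_dili"), path)
  raw <- tolower(trimws(as.character(df$clinical_dili)))
  parsed <- ifelse(raw %in% c("true", "yes", "1"), TRUE,
            ifelse(raw %in% c("false", "no", "0"), FALSE, NA))
  bad <- which(is.na(parsed) & nzchar(raw) & raw != "na")
  if (length(bad)) {
    abort_validation(sprintf("%s: unparseable clinical_dili value '%s' at %s",
                             path, raw[bad[1]], row_label(bad[1])))
  }
  df$clinical_dili <- parsed
  df
}

#' Write viability records / donor metadata as CSV
#'
#' Inverse of the readers; column order and names match the documented
#' schemas so a write-then-read round-trip reproduces the records.
#'
#' @param records Viability data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_viability_csv <- function(records, path) {
  cols <- c("donor_id", "drug", "dose_xcmax", "replicate", "viability_pct")
  check_header(records, cols, "records")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_viability_csv
#' @param donors Donor data.frame.
#' @export
write_donors_csv <- function(donors, path) {
  cols <- c("donor_id", "sex", "age", "abo")
  check_header(donors, cols, "donors")
  utils::write.csv(donors[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_viability_csv
#' @param drug_meta Drug metadata data.frame (`drug`, `clinical_dili`).
#' @export
write_drugs_csv <- function(drug_meta, path) {
  check_header(drug_meta, c("drug", "clinical_dili"), "drug_meta")
  utils::write.csv(drug_meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulation scenario: cohort, panel and plate design in one object
#'
#' A scenario bundles everything the simulator needs: the donor-cohort
#' parameters, the drug archetype panel, and the plate design. Scenarios
#' serialize to YAML so simulated studies are fully reproducible from a
#' config file plus a seed.
#'
#' @param n_donors Cohort size.
#' @param age_range Donor age interval (years).
#' @param sex_balance Probability of a female donor.
#' @param sensitivity_sd SD of the shared donor latent (log10 IC50 scale).
#' @param panel List of [drug_archetype()]s.
#' @param design A [plate_design()].
#' @param shared_sensitivity Share the donor latent across drugs?
#' @return List of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_donors = 24L, age_range = c(18, 80),
                            sex_balance = 0.5, sensitivity_sd = 0.25,
                            panel = demo_drug_panel(), design = plate_design(),
                            shared_sensitivity = TRUE) {
  if (n_donors < 1) abort_invalid_argument("`n_donors` must be >= 1")
  structure(
    list(n_donors = as.integer(n_donors), age_range = as.numeric(age_range),
         sex_balance = sex_balance, sensitivity_sd = sensitivity_sd,
         panel = panel, design = design,
         shared_sensitivity = isTRUE(shared_sensitivity)),
    class = "cohort_scenario"
  )
}

#' Read / write a scenario as YAML
#'
#' @param scenario A [cohort_scenario()].
#' @param path YAML path.
#' @return `write_scenario_yaml` the path invisibly; `read_scenario_yaml` a
#'   `cohort_scenario`.
#' @export
write_scenario_yaml <- function(scenario, path) {
  if (!inherits(scenario, "cohort_scenario")) {
    abort_invalid_argument("`scenario` must be a cohort_scenario")
  }
  obj <- list(
    n_donors = scenario$n_donors,
    age_range = scenario$age_range,
    sex_balance = scenario$sex_balance,
    sensitivity_sd = scenario$sensitivity_sd,
    shared_sensitivity = scenario$shared_sensitivity,
    design = unclass(scenario$design),
    drugs = lapply(unname(scenario$panel), unclass)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  obj <- yaml::read_yaml(path)
  need <- c("n_donors", "design", "drugs")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    abort_format(sprintf("%s: scenario missing field(s): %s",
                         path, paste(miss, collapse = ", ")))
  }
  design <- do.call(plate_design, obj$design[c("doses", "replicates",
                                               "noise_sd", "viability_cap")])
  panel <- lapply(obj$drugs, function(d) {
    do.call(drug_archetype, d[c("name", "clinical_dili", "median_log_ic50",
                                "donor_sd", "hill", "plateau_floor",
                                "sex_effect", "age_slope")])
  })
  names(panel) <- vapply(panel, `[[`, character(1), "name")
  cohort_scenario(
    n_donors = obj$n_donors,
    age_range = if (!is.null(obj$age_range)) obj$age_range else c(18, 80),
    sex_balance = if (!is.null(obj$sex_balance)) obj$sex_balance else 0.5,
    sensitivity_sd = if (!is.null(obj$sensitivity_sd)) obj$sensitivity_sd else 0.25,
    panel = panel, design = design,
    shared_sensitivity = if (!is.null(obj$shared_sensitivity)) obj$shared_sensitivity else TRUE
  )
}
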