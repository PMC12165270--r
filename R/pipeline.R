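#' Run a claims table through the full evaluation pipeline
#'
#' Applies cohort exclusions, builds FTD-containing outpatient
#' reimbursements, standardizes doses (MME/day and eMME/day), evaluates
#' every patient-year against the applicable criteria, and computes
#' annual usage.
#'
#' @param claims A claims tibble (see [read_claims()]).
#' @param factors An [mme_factor_table()].
#' @param thresholds A [criteria_thresholds()].
#' @return List with `evaluations`, `reimbursements` (dose summaries with
#'   eMME), `usage` (annual MME per patient-year), and `exclusions`.
#' @export
evaluate_cohort <- function(claims,
                            factors = mme_factor_table(),
                            thresholds = criteria_thresholds()) {
  validate_claims(claims)
  split <- apply_exclusions(claims)
  items <- build_patient_years(split$eligible)
  if (nrow(items) == 0) {
    stop("no eligible patient-years in the claims table", call. = FALSE)
  }
  rx <- add_emme(summarize_reimbursements(items, factors))
  evaluations <- evaluate_patient_years(rx, thresholds)
  usage <- annual_usage(items, factors)
  list(evaluations = evaluations, reimbursements = rx, usage = usage,
       exclusions = split$exclusions)
}

#' Compare pipeline output against ground-truth labels
#'
#' Checks per-criterion flags and verdicts of evaluated patient-years
#' against the labels emitted by [generate_cohort()] (NA flags must match
#' NA), and that every decoy labelled `excluded` was indeed removed with
#' the expected reason.
#'
#' @param evaluations From [evaluate_patient_years()].
#' @param labels From [generate_cohort()] or [read_labels()].
#' @param exclusions Exclusion log from [apply_exclusions()] (optional;
#'   decoy checks are skipped when absent).
#' @return List with `agreement` (fraction of eligible labels fully
#'   recovered), `n_labels`, `mismatches` (tibble of disagreeing
#'   patient-years), and `decoys_ok`.
#' @export
compare_to_labels <- function(evaluations, labels, exclusions = NULL) {
  flag_cols <- c("flag_period", "flag_dose", "flag_overlap_rx",
                 "flag_overlap_annual", "flag_multi_institution")
  eligible <- dplyr::filter(labels, !.data$excluded)
  merged <- dplyr::inner_join(
    eligible,
    evaluations[, c("patient_id", "year", "group", flag_cols, "verdict")],
    by = c("patient_id", "year"), suffix = c("_expected", "")
  )
  same <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  ok <- same(merged$expected_group, merged$group) &
    same(merged$expected_verdict, merged$verdict)
  for (col in flag_cols) {
    ok <- ok & same(merged[[paste0(col, "_expected")]], merged[[col]])
  }
  # labels with no matching evaluation row count as failures
  agreement <- if (nrow(eligible) == 0) NA_real_ else
    sum(ok) / nrow(eligible)
  decoys_ok <- NA
  if (!is.null(exclusions)) {
    decoys <- dplyr::filter(labels, .data$excluded)
    hit <- dplyr::inner_join(
      decoys, exclusions, by = c("patient_id", "year")
    )
    decoys_ok <- nrow(hit) == nrow(decoys) &&
      all(hit$exclusion_reason == hit$reason) &&
      nrow(dplyr::semi_join(evaluations, decoys,
                            by = c("patient_id", "year"))) == 0
  }
  list(agreement = agreement, n_labels = nrow(eligible),
       mismatches = merged[!ok, c("patient_id", "year", "archetype")],
       decoys_ok = decoys_ok)
}

#' Patient-level usage table for inequality analysis
#'
#' Joins evaluations with annual FTD usage into the layout
#' [modified_lorenz()] and [gini_by_stratum()] expect: one row per
#' patient-year with its age stratum ("W"/"O") and evaluation subgroup
#' (e.g. "WM-I"), pooled across years.
#'
#' @inheritParams compare_to_labels
#' @param usage From [annual_usage()].
#' @return Tibble: `patient_id`, `year`, `stratum`, `group`, `usage`.
#' @export
usage_by_group <- function(evaluations, usage) {
  merged <- dplyr::inner_join(evaluations, usage,
                              by = c("patient_id", "year"))
  tibble::tibble(
    patient_id = paste(merged$patient_id, merged$year, sep = "/"),
    year = merged$year,
    stratum = substr(merged$group, 1, 1),
    group = paste(merged$group, merged$verdict, sep = "-"),
    usage = merged$ftd_mme
  )
}

#' Read a pipeline run configuration
#'
#' Reads a YAML run configuration with optional blocks `thresholds`
#' (overrides for [criteria_thresholds()]), `simulation` (arguments of
#' [simulation_config()]), `ftd_factor`/`ftd_days_per_patch`, and
#' `paths`. Unknown keys fail validation.
#'
#' @param path YAML file path.
#' @return List with `thresholds`, `simulation`, `factors`, `paths`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("thresholds", "simulation", "ftd_factor", "ftd_days_per_patch",
             "factors_file", "paths")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  thresholds <- do.call(criteria_thresholds,
                        as.list(raw$thresholds %||% list()))
  simulation <- do.call(simulation_config,
                        as.list(raw$simulation %||% list()))
  factors <- if (!is.null(raw$factors_file)) {
    read_mme_factors(raw$factors_file,
                     ftd_factor = raw$ftd_factor %||% 2.4,
                     ftd_days_per_patch = raw$ftd_days_per_patch %||% 3)
  } else {
    mme_factor_table(ftd_factor = raw$ftd_factor %||% 2.4,
                     ftd_days_per_patch = raw$ftd_days_per_patch %||% 3)
  }
  list(thresholds = thresholds, simulation = simulation, factors = factors,
       paths = raw$paths %||% list())
}

log_stage <- function(stage, ...) {
  message(sprintf("[ftduse] %s: %s", stage,
                  paste(sprintf("%s=%s", names(list(...)), list(...)),
                        collapse = " ")))
}

#' Pipeline subcommands
#'
#' File-to-file entry points mirroring an end-to-end run:
#'
#' * `ftd_simulate()` writes `claims.csv` and `labels.csv` for a seeded
#'   synthetic cohort.
#' * `ftd_evaluate()` writes `evaluations.csv`, `exclusions.csv` and a
#'   JSON summary of counts per group; with labels present it also writes
#'   `recovery.json`.
#' * `ftd_trends()` writes `trends.csv` plus the log-linear APC of the
#'   reimbursement rate.
#' * `ftd_inequality()` writes `lorenz.csv` (modified Lorenz points) and
#'   `gini.json` (per-stratum Gini).
#' * `ftd_report()` runs all of the above into one output directory.
#'
#' Progress is logged to standard error; every artifact is reproducible
#' byte-for-byte under a fixed seed.
#'
#' @param config A run configuration from [read_run_config()], or the
#'   default.
#' @param out_dir Output directory (created if missing).
#' @param claims_path Claims CSV; defaults to `claims.csv` in `out_dir`.
#' @param labels_path Optional labels CSV for recovery reporting.
#' @param seed Optional integer overriding the configured simulation
#'   seed.
#' @return Paths of the written artifacts, invisibly.
#' @name pipeline-subcommands
NULL

default_run_config <- function() {
  list(thresholds = criteria_thresholds(),
       simulation = simulation_config(),
       factors = mme_factor_table(), paths = list())
}

#' @rdname pipeline-subcommands
#' @export
ftd_simulate <- function(config = default_run_config(), out_dir = ".",
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulation
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cohort <- generate_cohort(sim)
  paths <- c(claims = file.path(out_dir, "claims.csv"),
             labels = file.path(out_dir, "labels.csv"))
  write_claims(cohort$claims, paths["claims"])
  write_labels(cohort$labels, paths["labels"])
  log_stage("simulate", seed = sim$seed, rows = nrow(cohort$claims),
            patient_years = nrow(cohort$labels))
  invisible(paths)
}

#' @rdname pipeline-subcommands
#' @export
ftd_evaluate <- function(config = default_run_config(), out_dir = ".",
                         claims_path = file.path(out_dir, "claims.csv"),
                         labels_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  claims <- read_claims(claims_path)
  res <- evaluate_cohort(claims, config$factors, config$thresholds)
  paths <- c(evaluations = file.path(out_dir, "evaluations.csv"),
             exclusions = file.path(out_dir, "exclusions.csv"),
             groups = file.path(out_dir, "group_counts.json"))
  readr::write_csv(res$evaluations, paths["evaluations"], na = "")
  readr::write_csv(res$exclusions, paths["exclusions"], na = "")
  counts <- dplyr::count(res$evaluations, .data$group, .data$verdict)
  jsonlite::write_json(counts, paths["groups"], digits = NA)
  if (is.null(labels_path) &&
      file.exists(file.path(dirname(claims_path), "labels.csv"))) {
    labels_path <- file.path(dirname(claims_path), "labels.csv")
  }
  if (!is.null(labels_path)) {
    recovery <- compare_to_labels(res$evaluations, read_labels(labels_path),
                                  res$exclusions)
    paths["recovery"] <- file.path(out_dir, "recovery.json")
    jsonlite::write_json(
      recovery[c("agreement", "n_labels", "decoys_ok")],
      paths["recovery"], auto_unbox = TRUE, digits = NA
    )
    log_stage("recovery", agreement = recovery$agreement,
              n_labels = recovery$n_labels)
  }
  log_stage("evaluate", patient_years = nrow(res$evaluations),
            excluded = nrow(res$exclusions))
  invisible(paths)
}

#' @rdname pipeline-subcommands
#' @export
ftd_trends <- function(config = default_run_config(), out_dir = ".",
                       claims_path = file.path(out_dir, "claims.csv")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  claims <- read_claims(claims_path)
  res <- evaluate_cohort(claims, config$factors, config$thresholds)
  registrants <- tibble::tibble(
    year = sort(unique(res$evaluations$year)),
    n_registrants = config$simulation$n_registrants
  )
  trends <- summarize_trends(res$evaluations, res$usage, registrants,
                             config$thresholds)
  path <- file.path(out_dir, "trends.csv")
  readr::write_csv(trends, path, na = "")
  if (nrow(trends) >= 3) {
    apc <- apc_loglinear(trends$year, trends$reimbursements_per_100k)
    log_stage("trends", years = nrow(trends),
              apc_reimbursements = round_half_up(apc, 1))
  }
  invisible(c(trends = path))
}

#' @rdname pipeline-subcommands
#' @export
ftd_inequality <- function(config = default_run_config(), out_dir = ".",
                           claims_path = file.path(out_dir, "claims.csv")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  claims <- read_claims(claims_path)
  res <- evaluate_cohort(claims, config$factors, config$thresholds)
  usage <- usage_by_group(res$evaluations, res$usage)
  lorenz <- modified_lorenz(usage)
  ginis <- gini_by_stratum(usage)
  paths <- c(lorenz = file.path(out_dir, "lorenz.csv"),
             gini = file.path(out_dir, "gini.json"))
  readr::write_csv(lorenz, paths["lorenz"])
  jsonlite::write_json(ginis, paths["gini"], digits = NA)
  log_stage("inequality", strata = nrow(ginis))
  invisible(paths)
}

#' @rdname pipeline-subcommands
#' @export
ftd_report <- function(config = default_run_config(), out_dir = ".",
                       seed = NULL) {
  p1 <- ftd_simulate(config, out_dir, seed = seed)
  p2 <- ftd_evaluate(config, out_dir, claims_path = p1[["claims"]],
                     labels_path = p1[["labels"]])
  p3 <- ftd_trends(config, out_dir, claims_path = p1[["claims"]])
  p4 <- ftd_inequality(config, out_dir, claims_path = p1[["claims"]])
  invisible(c(p1, p2, p3, p4))
}
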