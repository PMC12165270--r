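#' Default archetype mix of the synthetic cohort
#'
#' Counts of patient-years per archetype. Each violation archetype plants
#' exactly one criterion violation (plus one deliberately mixed
#' archetype); the three `excluded_*` archetypes are decoys that must be
#' removed by the cohort filters.
#'
#' @return Named integer vector.
#' @export
default_archetype_mix <- function() {
  c(
    compliant_single = 220L,
    compliant_multiple = 340L,
    long_period = 60L,
    high_dose_single = 60L,
    high_dose_multiple = 80L,
    early_revisit_overlap = 100L,
    chronic_annual_overlap = 60L,
    doctor_shopping = 60L,
    mixed_violations = 40L,
    excluded_cancer = 40L,
    excluded_pediatric = 20L,
    excluded_inpatient = 20L
  )
}

#' Synthetic cohort configuration
#'
#' @param seed Integer seed; the single source of randomness.
#' @param years Calendar years to spread patient-years over.
#' @param archetype_mix Named counts per archetype; see
#'   [default_archetype_mix()].
#' @param strength_levels Marketed patch strengths, mcg/h.
#' @param co_opioid_probability Probability that a compliant visit also
#'   dispenses a co-prescribed oral opioid.
#' @param male_probability Probability a patient is male.
#' @param older_probability Probability a patient is an older adult
#'   (>= 65).
#' @param institution_pool Number of distinct institutions to draw from.
#' @param n_registrants Registrants per year in the sampling frame (rate
#'   denominator for trend summaries).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              years = 2014:2020,
                              archetype_mix = default_archetype_mix(),
                              strength_levels = c(12, 25, 50, 75, 100),
                              co_opioid_probability = 0.3,
                              male_probability = 0.4,
                              older_probability = 0.55,
                              institution_pool = 50L,
                              n_registrants = 100000L) {
  known <- names(default_archetype_mix())
  bad <- setdiff(names(archetype_mix), known)
  if (length(bad) > 0) {
    stop("unknown archetype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(archetype_mix) == 0 || sum(archetype_mix) == 0) {
    stop("archetype_mix must request at least one patient-year", call. = FALSE)
  }
  stopifnot(
    all(archetype_mix >= 0),
    co_opioid_probability >= 0, co_opioid_probability <= 1,
    male_probability >= 0, male_probability <= 1,
    older_probability >= 0, older_probability <= 1,
    institution_pool >= 5, n_registrants > 0
  )
  structure(
    list(seed = as.integer(seed), years = years,
         archetype_mix = archetype_mix,
         strength_levels = strength_levels,
         co_opioid_probability = co_opioid_probability,
         male_probability = male_probability,
         older_probability = older_probability,
         institution_pool = as.integer(institution_pool),
         n_registrants = as.integer(n_registrants)),
    class = "simulation_config"
  )
}

# Diagnosis pools by ICD-10 chapter, weighted toward musculoskeletal
# disease as in non-cancer chronic-pain claims.
diagnosis_pool <- function() {
  list(
    codes = c("M54", "M16", "M17", "M25", "S72", "T14", "G62", "G54",
              "K57", "K80", "I73", "I70", "R52", "F45"),
    weights = c(0.20, 0.15, 0.12, 0.08, 0.07, 0.05, 0.05, 0.03,
                0.02, 0.02, 0.02, 0.02, 0.10, 0.07)
  )
}

sample_diagnoses <- function(n_secondary = sample(0:2, 1)) {
  pool <- diagnosis_pool()
  codes <- sample(pool$codes, 1 + n_secondary, prob = pool$weights)
  paste(codes, collapse = ";")
}

# One claim row; days_supplied is NA for FTD (derived downstream).
claim_row <- function(patient, visit_date, institution, drug_code,
                      drug_class, strength, quantity, days_supplied,
                      diagnoses, setting = "outpatient") {
  tibble::tibble(
    patient_id = patient$patient_id, sex = patient$sex,
    age = patient$age, visit_date = visit_date,
    year = patient$year, institution_id = institution,
    setting = setting, drug_code = drug_code, drug_class = drug_class,
    strength = strength, quantity = as.integer(quantity),
    days_supplied = as.integer(days_supplied),
    diagnosis_codes = diagnoses
  )
}

# Emit the rows of one visit: an FTD item plus, with the configured
# probability, an oxycodone co-prescription covering the same days at
# 10 mg/day (15 MME/day), small enough to preserve every dose margin.
visit_rows <- function(patient, visit_date, institution, strength, quantity,
                       config, with_co_opioid = NA, setting = "outpatient",
                       extra_diagnosis = NULL) {
  diagnoses <- sample_diagnoses()
  if (!is.null(extra_diagnosis)) {
    diagnoses <- paste(diagnoses, extra_diagnosis, sep = ";")
  }
  rows <- claim_row(patient, visit_date, institution,
                    paste0("FTD", strength), "FTD", strength, quantity,
                    NA_integer_, diagnoses, setting)
  if (is.na(with_co_opioid)) {
    with_co_opioid <- stats::runif(1) < config$co_opioid_probability
  }
  if (with_co_opioid) {
    days <- quantity * 3L
    rows <- dplyr::bind_rows(
      rows,
      claim_row(patient, visit_date, institution, "OXYCODONE",
                "other_opioid", 5, days * 2L, days, diagnoses, setting)
    )
  }
  rows
}

# Start day leaving room for `span` further days within the year.
sample_start_date <- function(year, span) {
  start <- sample(seq_len(365 - span - 1), 1)
  as.Date(sprintf("%d-01-01", year)) + start - 1
}

sample_patient <- function(config, id, pediatric = FALSE) {
  older <- !pediatric && stats::runif(1) < config$older_probability
  age <- if (pediatric) sample(10:19, 1)
         else if (older) sample(65:94, 1) else sample(20:64, 1)
  list(
    patient_id = id,
    sex = if (stats::runif(1) < config$male_probability) "male" else "female",
    age = age,
    year = sample(config$years, 1),
    older = older
  )
}

label_for <- function(patient, archetype, single, flags, excluded_reason = NA) {
  excluded <- !is.na(excluded_reason)
  group <- if (excluded) NA_character_ else {
    paste0(if (patient$older) "O" else "W", if (single) "S" else "M")
  }
  full <- c(period = NA, dose = NA, overlap_rx = NA, overlap_annual = NA,
            multi_institution = NA)
  if (!excluded) {
    full[c("period", "dose")] <- flags[c("period", "dose")]
    if (!single) {
      full[c("overlap_rx", "overlap_annual", "multi_institution")] <-
        flags[c("overlap_rx", "overlap_annual", "multi_institution")]
    }
  }
  tibble::tibble(
    patient_id = patient$patient_id, year = patient$year,
    archetype = archetype,
    excluded = excluded, exclusion_reason = excluded_reason,
    expected_group = group,
    flag_period = full[["period"]], flag_dose = full[["dose"]],
    flag_overlap_rx = full[["overlap_rx"]],
    flag_overlap_annual = full[["overlap_annual"]],
    flag_multi_institution = full[["multi_institution"]],
    expected_verdict = if (excluded) NA_character_
                       else if (any(full, na.rm = TRUE)) "I" else "A"
  )
}

# Multi-visit emitter: walks a fixed interval schedule from a random
# start date, one row set per visit.
schedule_rows <- function(patient, intervals, institutions, strength,
                          quantity, config, with_co_opioid = NA) {
  dates <- sample_start_date(patient$year, sum(intervals)) +
    cumsum(c(0, intervals))
  dplyr::bind_rows(lapply(seq_along(dates), function(i) {
    visit_rows(patient, dates[i], institutions[i], strength, quantity,
               config, with_co_opioid)
  }))
}

low_strength <- function(config) {
  sample(config$strength_levels[config$strength_levels * 2.4 <= 85], 1)
}

high_strength <- function(config) {
  sample(config$strength_levels[config$strength_levels * 2.4 >= 95], 1)
}

#' Generate one archetype patient-year
#'
#' Emits the claim rows and ground-truth label of a single synthetic
#' patient-year. Every archetype is constructed so its defining
#' (in)equality holds with a guard margin of at least 1 day or 5 MME/day,
#' so integer rounding can never flip the planted label:
#'
#' * `compliant_single` / `compliant_multiple` — every criterion met with
#'   margin (doses <= 75 MME/day, no overlaps, <= 2 institutions).
#' * `long_period` — one prescription of 31-35 patches (93-105 days).
#' * `high_dose_single` / `high_dose_multiple` — patch strengths of 50+
#'   mcg/h (120+ MME/day or eMME/day) on otherwise compliant schedules.
#' * `early_revisit_overlap` — one 25-day revisit within 30-day supplies
#'   (overlap 5 > 3), annual allowance untouched.
#' * `chronic_annual_overlap` — twelve 27-day revisits of 30-day supplies
#'   (each overlap 3, total 33 > the 30-day annual allowance).
#' * `doctor_shopping` — 4-5 distinct prescribing institutions.
#' * `mixed_violations` — dose, both overlaps and multi-institution
#'   violated simultaneously.
#' * `excluded_cancer`, `excluded_pediatric`, `excluded_inpatient` —
#'   decoys the cohort filters must remove.
#'
#' @param archetype Archetype name; see [default_archetype_mix()].
#' @param config A [simulation_config()].
#' @param patient_id Identifier for the emitted patient.
#' @return List with `claims` (tibble of rows) and `label` (one-row
#'   tibble).
#' @export
sample_archetype <- function(archetype, config, patient_id = "P000001") {
  pediatric <- identical(archetype, "excluded_pediatric")
  patient <- sample_patient(config, patient_id, pediatric)
  inst <- function(n = 1, distinct = FALSE) {
    pool <- sprintf("H%03d", seq_len(config$institution_pool))
    if (distinct) sample(pool, n) else sample(pool, n, replace = TRUE)
  }
  no_flags <- c(period = FALSE, dose = FALSE, overlap_rx = FALSE,
                overlap_annual = FALSE, multi_institution = FALSE)
  switch(
    archetype,
    compliant_single = {
      claims <- visit_rows(patient, sample_start_date(patient$year, 40),
                           inst(), low_strength(config), sample(5:10, 1),
                           config)
      list(claims = claims,
           label = label_for(patient, archetype, TRUE, no_flags))
    },
    compliant_multiple = {
      n <- sample(3:8, 1)
      # draw all visits from 1-2 institutions: margin of 1 under the limit
      claims <- schedule_rows(patient, sample(30:33, n - 1, replace = TRUE),
                              sample(inst(2, distinct = TRUE), n, replace = TRUE),
                              low_strength(config), 10, config)
      list(claims = claims,
           label = label_for(patient, archetype, FALSE, no_flags))
    },
    long_period = {
      q <- sample(31:35, 1)
      claims <- visit_rows(patient, sample_start_date(patient$year, 3 * q),
                           inst(), low_strength(config), q, config,
                           with_co_opioid = FALSE)
      flags <- no_flags; flags["period"] <- TRUE
      list(claims = claims,
           label = label_for(patient, archetype, TRUE, flags))
    },
    high_dose_single = {
      claims <- visit_rows(patient, sample_start_date(patient$year, 40),
                           inst(), high_strength(config), sample(5:10, 1),
                           config, with_co_opioid = FALSE)
      flags <- no_flags; flags["dose"] <- TRUE
      list(claims = claims,
           label = label_for(patient, archetype, TRUE, flags))
    },
    high_dose_multiple = {
      n <- sample(2:4, 1)
      claims <- schedule_rows(patient, rep(30L, n - 1), rep(inst(), n),
                              high_strength(config), 10, config,
                              with_co_opioid = FALSE)
      flags <- no_flags; flags["dose"] <- TRUE
      list(claims = claims,
           label = label_for(patient, archetype, FALSE, flags))
    },
    early_revisit_overlap = {
      claims <- schedule_rows(patient, c(30L, 30L, 25L, 30L), rep(inst(), 5),
                              low_strength(config), 10, config,
                              with_co_opioid = FALSE)
      flags <- no_flags; flags["overlap_rx"] <- TRUE
      list(claims = claims,
           label = label_for(patient, archetype, FALSE, flags))
    },
    chronic_annual_overlap = {
      claims <- schedule_rows(patient, rep(27L, 11), rep(inst(), 12),
                              low_strength(config), 10, config,
                              with_co_opioid = FALSE)
      flags <- no_flags; flags["overlap_annual"] <- TRUE
      list(claims = claims,
           label = label_for(patient, archetype, FALSE, flags))
    },
    doctor_shopping = {
      n <- sample(4:5, 1)
      claims <- schedule_rows(patient, sample(30:33, n - 1, replace = TRUE),
                              inst(n, distinct = TRUE), low_strength(config),
                              10, config)
      flags <- no_flags; flags["multi_institution"] <- TRUE
      list(claims = claims,
           label = label_for(patient, archetype, FALSE, flags))
    },
    mixed_violations = {
      claims <- schedule_rows(patient, rep(25L, 3), inst(4, distinct = TRUE),
                              50, 10, config, with_co_opioid = FALSE)
      flags <- c(period = FALSE, dose = TRUE, overlap_rx = TRUE,
                 overlap_annual = TRUE, multi_institution = TRUE)
      list(claims = claims,
           label = label_for(patient, archetype, FALSE, flags))
    },
    excluded_cancer = {
      claims <- visit_rows(patient, sample_start_date(patient$year, 40),
                           inst(), low_strength(config), 10, config,
                           extra_diagnosis = "C50")
      list(claims = claims,
           label = label_for(patient, archetype, TRUE, no_flags,
                             excluded_reason = "cancer"))
    },
    excluded_pediatric = {
      claims <- visit_rows(patient, sample_start_date(patient$year, 40),
                           inst(), low_strength(config), 10, config)
      list(claims = claims,
           label = label_for(patient, archetype, TRUE, no_flags,
                             excluded_reason = "pediatric"))
    },
    excluded_inpatient = {
      claims <- visit_rows(patient, sample_start_date(patient$year, 40),
                           inst(), low_strength(config), 10, config,
                           setting = "inpatient")
      list(claims = claims,
           label = label_for(patient, archetype, TRUE, no_flags,
                             excluded_reason = "no_outpatient_ftd"))
    },
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
}

#' Generate a synthetic claims cohort with ground-truth labels
#'
#' Emits a claims table in the [claims_schema()] layout together with one
#' ground-truth label per generated patient-year. Labels of eligible
#' patient-years carry the expected group (WS/WM/OS/OM), per-criterion
#' flags (NA where a criterion does not apply) and the expected
#' appropriate/potentially-inappropriate verdict; decoy patient-years are
#' labelled with their expected exclusion reason. Output is deterministic
#' given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `claims` and `labels` tibbles.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  mix <- config$archetype_mix[config$archetype_mix > 0]
  counter <- 0L
  out <- lapply(names(mix), function(arch) {
    lapply(seq_len(mix[[arch]]), function(i) {
      counter <<- counter + 1L
      sample_archetype(arch, config, sprintf("P%06d", counter))
    })
  })
  out <- unlist(out, recursive = FALSE)
  claims <- dplyr::bind_rows(lapply(out, `[[`, "claims"))
  labels <- dplyr::bind_rows(lapply(out, `[[`, "label"))
  list(claims = claims, labels = labels)
}

#' Read / write ground-truth label tables
#'
#' @param labels Labels tibble from [generate_cohort()].
#' @param path CSV path.
#' @return `write_labels()`: `path`, invisibly. `read_labels()`: labels
#'   tibble.
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels, path, na = "")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      year = readr::col_integer(),
      archetype = readr::col_character(),
      excluded = readr::col_logical(),
      exclusion_reason = readr::col_character(),
      expected_group = readr::col_character(),
      flag_period = readr::col_logical(),
      flag_dose = readr::col_logical(),
      flag_overlap_rx = readr::col_logical(),
      flag_overlap_annual = readr::col_logical(),
      flag_multi_institution = readr::col_logical(),
      expected_verdict = readr::col_character()
    ),
    progress = FALSE
  )
}
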