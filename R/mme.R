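#' Morphine-milligram-equivalent conversion factors
#'
#' A conversion table for co-prescribed oral opioids (MME per mg) plus the
#' fentanyl-patch constants: 2.4 MME per mcg/h per day, and an approved use
#' period of 3 days per patch. The per-mg factors follow the CDC oral
#' conversion factors.
#'
#' @param factors Tibble with columns `drug_code` and `factor_mme_per_mg`
#'   (all factors > 0). Defaults to [default_mme_factors()].
#' @param ftd_factor MME per mcg/h per day for transdermal fentanyl.
#' @param ftd_days_per_patch Approved days of use per patch.
#' @return An object of class `mme_factor_table`.
#' @export
mme_factor_table <- function(factors = default_mme_factors(),
                             ftd_factor = 2.4,
                             ftd_days_per_patch = 3) {
  stopifnot(
    is.data.frame(factors),
    all(c("drug_code", "factor_mme_per_mg") %in% names(factors)),
    all(factors$factor_mme_per_mg > 0),
    ftd_factor > 0, ftd_days_per_patch >= 1
  )
  structure(
    list(
      factors = tibble::as_tibble(factors),
      ftd_factor = ftd_factor,
      ftd_days_per_patch = as.integer(ftd_days_per_patch)
    ),
    class = "mme_factor_table"
  )
}

#' @export
print.mme_factor_table <- function(x, ...) {
  cat("MME conversion factors (", nrow(x$factors), " oral opioids)\n", sep = "")
  cat("FTD: ", x$ftd_factor, " MME per mcg/h per day, ",
      x$ftd_days_per_patch, " days per patch\n", sep = "")
  print(x$factors, ...)
  invisible(x)
}

#' Default oral-opioid conversion factors (CDC)
#'
#' @return Tibble with `drug_code` and `factor_mme_per_mg`.
#' @export
default_mme_factors <- function() {
  tibble::tibble(
    drug_code = c("MORPHINE", "OXYCODONE", "HYDROCODONE",
                  "HYDROMORPHONE", "TRAMADOL", "CODEINE"),
    factor_mme_per_mg = c(1, 1.5, 1, 4, 0.1, 0.15)
  )
}

#' Read a conversion-factor table
#'
#' Reads a delimited text file `drug_code,factor_mme_per_mg` and wraps it
#' with the FTD constants.
#'
#' @param path CSV path.
#' @inheritParams mme_factor_table
#' @return An `mme_factor_table`.
#' @export
read_mme_factors <- function(path, ftd_factor = 2.4, ftd_days_per_patch = 3) {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(drug_code = readr::col_character(),
                            factor_mme_per_mg = readr::col_double()),
    progress = FALSE
  )
  mme_factor_table(tab, ftd_factor, ftd_days_per_patch)
}

#' MME delivered by one fentanyl patch
#'
#' One patch of strength s mcg/h delivers s x 2.4 x 3 MME over its
#' approved 3-day use period (e.g. a 25 mcg/h patch is 180 MME).
#'
#' @param strength Patch strength in mcg/h (> 0); vectorized.
#' @param factors An `mme_factor_table`.
#' @return MME per patch.
#' @export
patch_mme <- function(strength, factors = mme_factor_table()) {
  if (any(is.na(strength)) || any(strength <= 0)) {
    stop("patch strength must be a positive mcg/h value", call. = FALSE)
  }
  strength * factors$ftd_factor * factors$ftd_days_per_patch
}

#' Standardize claim items to MME and covered days
#'
#' For FTD items the total dose is patches x patch MME and the covered
#' duration is patches x 3 days (derived, never taken from the table); for
#' other opioids it is strength (mg) x quantity x the drug's per-mg factor
#' over the dispensed `days_supplied`.
#'
#' @param items Opioid claim items (rows with `drug_class` in
#'   `{"FTD", "other_opioid"}`), e.g. from [group_reimbursements()].
#' @param factors An `mme_factor_table`.
#' @return `items` with added `mme_total` and `duration_days`.
#' @export
item_mme <- function(items, factors = mme_factor_table()) {
  if (any(!items$drug_class %in% c("FTD", "other_opioid"))) {
    stop("item_mme() expects opioid items only", call. = FALSE)
  }
  other <- items$drug_class == "other_opioid"
  fac <- factors$factors$factor_mme_per_mg[
    match(items$drug_code, factors$factors$drug_code)]
  unknown <- other & is.na(fac)
  if (any(unknown)) {
    stop("no MME conversion factor for drug code(s): ",
         paste(unique(items$drug_code[unknown]), collapse = ", "),
         call. = FALSE)
  }
  items$mme_total <- ifelse(
    other,
    items$strength * items$quantity * fac,
    items$quantity * patch_mme(items$strength, factors)
  )
  items$duration_days <- ifelse(
    other,
    items$days_supplied,
    items$quantity * factors$ftd_days_per_patch
  )
  items
}

#' Per-reimbursement dose summaries (MME/day)
#'
#' Collapses opioid items to one row per reimbursement. The MME/day of a
#' reimbursement is its total MME (all co-prescribed opioids included)
#' divided by the longest covered duration among its items; the FTD's own
#' implied duration (patches x 3) counts toward that maximum.
#'
#' @param items Opioid items with `rx_id`, e.g. from
#'   [build_patient_years()].
#' @param factors An `mme_factor_table`.
#' @return One row per reimbursement: keys, `primary_diagnosis`,
#'   `mme_total`, `longest_days`, `mme_per_day`, `ftd_patches`,
#'   `ftd_duration_days`, `contains_ftd`.
#' @export
summarize_reimbursements <- function(items, factors = mme_factor_table()) {
  items <- item_mme(items, factors)
  out <- dplyr::summarise(
    dplyr::group_by(items, .data$rx_id),
    patient_id = .data$patient_id[1],
    year = .data$year[1],
    sex = .data$sex[1],
    age = .data$age[1],
    visit_date = .data$visit_date[1],
    institution_id = .data$institution_id[1],
    primary_diagnosis = sub(";.*$", "", .data$diagnosis_codes[1]),
    mme_total = sum(.data$mme_total),
    longest_days = max(.data$duration_days),
    ftd_patches = sum(.data$quantity[.data$drug_class == "FTD"]),
    contains_ftd = any(.data$drug_class == "FTD"),
    n_items = dplyr::n(),
    .groups = "drop"
  )
  out$ftd_duration_days <- out$ftd_patches * factors$ftd_days_per_patch
  out$mme_per_day <- out$mme_total / out$longest_days
  dplyr::arrange(out, .data$patient_id, .data$year, .data$visit_date,
                 .data$institution_id)
}

#' Interval-based estimated MME/day (eMME/day)
#'
#' For each reimbursement of a patient-year except the last, the effective
#' interval is the number of days until the next visit, under the
#' assumption that all dispensed opioids are consumed before returning;
#' the final reimbursement has no next visit and uses its own longest
#' covered duration, so a fully adherent patient has eMME/day equal to
#' MME/day at every visit. A zero interval (same-day visits at different
#' institutions) is clamped to 1 day; the number of clamped intervals is
#' attached as the `n_clamped` attribute.
#'
#' @param rx Reimbursement summaries from [summarize_reimbursements()].
#' @return `rx` with added `interval_to_next` (NA for the last visit of a
#'   patient-year), `effective_interval`, and `emme_per_day`.
#' @export
add_emme <- function(rx) {
  rx <- dplyr::arrange(rx, .data$patient_id, .data$year, .data$visit_date,
                       .data$institution_id)
  rx <- dplyr::mutate(
    dplyr::group_by(rx, .data$patient_id, .data$year),
    interval_to_next = as.integer(dplyr::lead(.data$visit_date) - .data$visit_date)
  )
  rx <- dplyr::ungroup(rx)
  eff <- ifelse(is.na(rx$interval_to_next), rx$longest_days, rx$interval_to_next)
  n_clamped <- sum(eff < 1)
  rx$effective_interval <- pmax(eff, 1L)
  rx$emme_per_day <- rx$mme_total / rx$effective_interval
  attr(rx, "n_clamped") <- n_clamped
  rx
}

#' Annual opioid usage per patient-year
#'
#' Sums standardized MME over the FTD items and over all opioid items of
#' each patient-year's included reimbursements.
#'
#' @inheritParams summarize_reimbursements
#' @return One row per patient-year: `patient_id`, `year`, `ftd_mme`,
#'   `opioid_mme` (with `ftd_mme <= opioid_mme`).
#' @export
annual_usage <- function(items, factors = mme_factor_table()) {
  items <- item_mme(items, factors)
  dplyr::summarise(
    dplyr::group_by(items, .data$patient_id, .data$year),
    ftd_mme = sum(.data$mme_total[.data$drug_class == "FTD"]),
    opioid_mme = sum(.data$mme_total),
    .groups = "drop"
  )
}
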