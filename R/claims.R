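#' Claims table column schema
#'
#' The canonical column layout of a claims table: one row per dispensed drug
#' item. Dates are ISO-8601 (`YYYY-MM-DD`); `diagnosis_codes` is a
#' semicolon-joined list of ICD-10 codes, first code primary.
#'
#' @return Named character vector mapping column name to type
#'   (`"character"`, `"integer"`, `"double"`, `"date"`).
#' @export
claims_schema <- function() {
  c(
    patient_id      = "character",
    sex             = "character",
    age             = "integer",
    visit_date      = "date",
    year            = "integer",
    institution_id  = "character",
    setting         = "character",
    drug_code       = "character",
    drug_class      = "character",
    strength        = "double",
    quantity        = "integer",
    days_supplied   = "integer",
    diagnosis_codes = "character"
  )
}

#' Read a claims table
#'
#' Reads a UTF-8 comma-delimited claims table with a header row matching
#' [claims_schema()]. Every row is either parsed or rejected with a
#' row-level diagnostic; a malformed file fails as a whole.
#'
#' For fentanyl patch rows (`drug_class == "FTD"`) `days_supplied` may be
#' empty: the covered duration is derived downstream as patches x 3 days
#' and is never stored.
#'
#' @param path Path to a claims CSV file.
#' @return A tibble of claims, one row per dispensed item.
#' @export
read_claims <- function(path) {
  if (!file.exists(path)) {
    stop("claims file not found: ", path, call. = FALSE)
  }
  spec <- readr::cols(
    patient_id      = readr::col_character(),
    sex             = readr::col_character(),
    age             = readr::col_integer(),
    visit_date      = readr::col_date(format = "%Y-%m-%d"),
    year            = readr::col_integer(),
    institution_id  = readr::col_character(),
    setting         = readr::col_character(),
    drug_code       = readr::col_character(),
    drug_class      = readr::col_character(),
    strength        = readr::col_double(),
    quantity        = readr::col_integer(),
    days_supplied   = readr::col_integer(),
    diagnosis_codes = readr::col_character()
  )
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  missing <- setdiff(names(claims_schema()), hdr)
  if (length(missing) > 0) {
    stop("claims file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # parse problems are re-reported below with row indices
  claims <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                             progress = FALSE))
  probs <- readr::problems(claims)
  if (nrow(probs) > 0) {
    stop("unparseable claims row(s): ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  validate_claims(claims)
  claims
}

#' Write a claims table
#'
#' @param claims A claims tibble as returned by [read_claims()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_claims <- function(claims, path) {
  readr::write_csv(claims, path, na = "")
  invisible(path)
}

#' Validate a claims table
#'
#' Checks the structural invariants of a claims table and fails with
#' row-indexed diagnostics: non-positive quantities, negative strengths,
#' FTD rows without a positive strength, visit dates outside their
#' stated calendar year, unknown sex/setting/drug-class levels.
#'
#' @param claims A claims tibble.
#' @return `claims`, invisibly, if valid.
#' @export
validate_claims <- function(claims) {
  missing <- setdiff(names(claims_schema()), names(claims))
  if (length(missing) > 0) {
    stop("claims table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- c(
    if (length(i <- bad(claims$quantity <= 0)) > 0)
      paste0("non-positive quantity in row(s) ", paste(i, collapse = ", ")),
    if (length(i <- which(claims$drug_class != "non_opioid" &
                          (is.na(claims$strength) | claims$strength <= 0))) > 0)
      paste0("opioid row(s) without positive strength: ", paste(i, collapse = ", ")),
    if (length(i <- bad(as.integer(format(claims$visit_date, "%Y")) != claims$year)) > 0)
      paste0("visit_date outside calendar year in row(s) ", paste(i, collapse = ", ")),
    if (length(i <- bad(!claims$sex %in% c("male", "female"))) > 0)
      paste0("unknown sex in row(s) ", paste(i, collapse = ", ")),
    if (length(i <- bad(!claims$setting %in% c("outpatient", "inpatient"))) > 0)
      paste0("unknown setting in row(s) ", paste(i, collapse = ", ")),
    if (length(i <- bad(!claims$drug_class %in% c("FTD", "other_opioid", "non_opioid"))) > 0)
      paste0("unknown drug_class in row(s) ", paste(i, collapse = ", ")),
    if (length(i <- which(claims$drug_class != "FTD" &
                          claims$drug_class != "non_opioid" &
                          (is.na(claims$days_supplied) | claims$days_supplied <= 0))) > 0)
      paste0("non-FTD opioid row(s) without positive days_supplied: ",
             paste(i, collapse = ", "))
  )
  if (length(problems) > 0) {
    stop(paste(problems, collapse = "; "), call. = FALSE)
  }
  invisible(claims)
}

#' Group claim lines into reimbursements
#'
#' A reimbursement is one claimed outpatient visit: all opioid items a
#' patient received on the same date at the same institution. Claim lines
#' sharing `(patient_id, visit_date, institution_id)` are assigned one
#' reimbursement id; non-opioid items are dropped. Output is one row per
#' opioid item, ordered by patient, year and visit date.
#'
#' @param claims A claims tibble (any mix of patients and years).
#' @return The opioid items with an added `rx_id` reimbursement key.
#' @export
group_reimbursements <- function(claims) {
  items <- dplyr::filter(claims, .data$drug_class %in% c("FTD", "other_opioid"))
  items <- dplyr::arrange(items, .data$patient_id, .data$year,
                          .data$visit_date, .data$institution_id)
  keys <- paste(items$patient_id, items$year, items$visit_date,
                items$institution_id, sep = "\r")
  items$rx_id <- match(keys, unique(keys))
  items
}

#' Apply cohort inclusion and exclusion rules
#'
#' Splits claims into eligible patient-years and an exclusion log. A
#' patient-calendar-year is eligible iff it has at least one outpatient
#' FTD-containing reimbursement, the recorded age is 20 or more, and no
#' diagnosis code that year (any position, any setting) starts with "C"
#' (ICD-10 malignant-neoplasm chapter). Patient-years are independent
#' analysis units: a patient excluded in one year may be eligible in
#' another.
#'
#' Reasons are logged in precedence order `no_outpatient_ftd`, `cancer`,
#' `pediatric` (one reason per excluded patient-year).
#'
#' @param claims A claims tibble.
#' @return A list with `eligible` (claims restricted to eligible
#'   patient-years) and `exclusions` (tibble: `patient_id`, `year`,
#'   `reason`).
#' @export
apply_exclusions <- function(claims) {
  py <- dplyr::summarise(
    dplyr::group_by(claims, .data$patient_id, .data$year),
    age = max(.data$age),
    has_outpatient_ftd = any(.data$drug_class == "FTD" &
                             .data$setting == "outpatient"),
    has_cancer = any(grepl("(^|;)C", .data$diagnosis_codes)),
    .groups = "drop"
  )
  py$reason <- dplyr::case_when(
    !py$has_outpatient_ftd ~ "no_outpatient_ftd",
    py$has_cancer          ~ "cancer",
    py$age < 20            ~ "pediatric",
    TRUE                   ~ NA_character_
  )
  exclusions <- dplyr::select(
    dplyr::filter(py, !is.na(.data$reason)),
    "patient_id", "year", "reason"
  )
  eligible_keys <- dplyr::filter(py, is.na(.data$reason))
  eligible <- dplyr::semi_join(claims, eligible_keys,
                               by = c("patient_id", "year"))
  list(eligible = eligible, exclusions = exclusions)
}

#' Build patient-year reimbursement histories
#'
#' Restricts eligible claims to outpatient visits, groups them into
#' reimbursements, and keeps only FTD-containing reimbursements — the
#' analysis unit of the rule engine. Co-prescribed opioids dispensed at
#' the same visit stay inside the reimbursement; opioid-only visits
#' without an FTD are dropped.
#'
#' @param eligible Eligible claims, as returned by [apply_exclusions()].
#' @return One row per opioid item of an FTD-containing outpatient
#'   reimbursement, with `rx_id` keys, date-ordered within patient-year.
#' @export
build_patient_years <- function(eligible) {
  outpt <- dplyr::filter(eligible, .data$setting == "outpatient")
  items <- group_reimbursements(outpt)
  ftd_rx <- unique(items$rx_id[items$drug_class == "FTD"])
  items <- dplyr::filter(items, .data$rx_id %in% ftd_rx)
  items$rx_id <- match(items$rx_id, unique(items$rx_id))
  items
}
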