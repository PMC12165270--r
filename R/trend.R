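#' Rate per 100,000 registrants
#'
#' @param count Event or patient count.
#' @param registrants Registrants in the sampling frame (> 0).
#' @return `100000 * count / registrants`; vectorized.
#' @export
rate_per_100k <- function(count, registrants) {
  if (any(registrants <= 0)) stop("registrants must be positive", call. = FALSE)
  1e5 * count / registrants
}

#' Percent change between two values
#'
#' @param a Baseline value (> 0).
#' @param b Comparison value.
#' @return `100 * (b - a) / a`.
#' @export
percent_change <- function(a, b) {
  if (any(a <= 0)) stop("baseline must be positive", call. = FALSE)
  100 * (b - a) / a
}

#' Annual percent change from a log-linear trend
#'
#' Fits ordinary least squares of `log(rate)` on calendar year and returns
#' `100 * (exp(slope) - 1)`, the constant yearly growth rate implied by
#' the fitted exponential trend. On an exact geometric series with ratio r
#' this returns exactly `100 * (r - 1)`.
#'
#' @param years Calendar years (length >= 3).
#' @param rates Positive yearly rates, same length.
#' @return APC in percent.
#' @export
apc_loglinear <- function(years, rates) {
  if (length(years) != length(rates) || length(rates) < 3) {
    stop("need rates for at least 3 years", call. = FALSE)
  }
  if (any(rates <= 0)) stop("rates must be positive for a log-linear fit",
                            call. = FALSE)
  fit <- stats::lm(log(rates) ~ years)
  100 * (exp(unname(stats::coef(fit)[2])) - 1)
}

# mean (SD) of a numeric vector as a two-element list; SD of a single
# value is reported as 0 to mirror the report-table convention.
mean_sd <- function(x) {
  s <- stats::sd(x)
  list(mean = mean(x), sd = if (is.na(s)) 0 else s)
}

#' Yearly utilization trends
#'
#' Builds the yearly trend table: patients and reimbursements per 100,000
#' registrants, sex- and age-stratified patient rates, reimbursements per
#' patient, and annual FTD usage per patient (means with SDs).
#'
#' @param evaluations Patient-year evaluations from
#'   [evaluate_patient_years()].
#' @param usage Annual usage per patient-year from [annual_usage()].
#' @param registrants Tibble with columns `year` and `n_registrants`.
#' @param thresholds A [criteria_thresholds()] object (for the working-age
#'   boundary).
#' @return One row per year with the rate and usage columns.
#' @export
summarize_trends <- function(evaluations, usage, registrants,
                             thresholds = criteria_thresholds()) {
  ev <- dplyr::left_join(evaluations, usage, by = c("patient_id", "year"))
  tab <- dplyr::summarise(
    dplyr::group_by(ev, .data$year),
    n_patients = dplyr::n(),
    n_reimbursements = sum(.data$n_reimbursements),
    n_male = sum(.data$sex == "male"),
    n_female = sum(.data$sex == "female"),
    n_working_age = sum(.data$age <= thresholds$working_age_upper),
    n_older_adult = sum(.data$age > thresholds$working_age_upper),
    mean_rx_per_patient = mean(.data$n_reimbursements),
    sd_rx_per_patient = stats::sd(.data$n_reimbursements),
    mean_annual_ftd_mme = mean(.data$ftd_mme),
    sd_annual_ftd_mme = stats::sd(.data$ftd_mme),
    .groups = "drop"
  )
  tab <- dplyr::inner_join(tab, registrants, by = "year")
  for (col in c("patients", "reimbursements", "male", "female",
                "working_age", "older_adult")) {
    tab[[paste0(col, "_per_100k")]] <-
      rate_per_100k(tab[[paste0("n_", col)]], tab$n_registrants)
  }
  dplyr::arrange(tab, .data$year)
}

# ICD-10 chapter bucket of a primary diagnosis code, matching the
# morbidity categories of the group report table.
diagnosis_chapter <- function(code) {
  first <- substr(code, 1, 1)
  dplyr::case_when(
    first == "M" ~ "musculoskeletal",
    first %in% c("S", "T") ~ "injury_poisoning",
    first == "G" ~ "nervous",
    first == "K" ~ "digestive",
    first == "I" ~ "circulatory",
    TRUE ~ "others"
  )
}

#' Group-level clinical characteristics
#'
#' Summarizes the four age-by-frequency groups (WS, WM, OS, OM) and the
#' two age-stratum totals: patient and reimbursement counts, sex split,
#' reimbursements per patient, annual FTD and all-opioid usage (MME),
#' dose per reimbursement (MME/day), and primary-diagnosis chapter
#' tallies over reimbursements.
#'
#' @inheritParams summarize_trends
#' @param rx Reimbursement summaries with eMME columns (from
#'   [add_emme()]).
#' @return A list with `groups` (one row per group and stratum total) and
#'   `diagnoses` (chapter tallies per group, long form).
#' @export
summarize_groups <- function(evaluations, usage, rx) {
  ev <- dplyr::left_join(evaluations, usage, by = c("patient_id", "year"))
  rx <- dplyr::left_join(
    rx,
    dplyr::select(evaluations, "patient_id", "year", "group"),
    by = c("patient_id", "year")
  )
  summarize_block <- function(ev_sub, rx_sub, label) {
    tibble::tibble(
      group = label,
      n_patients = nrow(ev_sub),
      n_male = sum(ev_sub$sex == "male"),
      n_female = sum(ev_sub$sex == "female"),
      n_reimbursements = sum(ev_sub$n_reimbursements),
      mean_rx_per_patient = mean(ev_sub$n_reimbursements),
      sd_rx_per_patient = mean_sd(ev_sub$n_reimbursements)$sd,
      mean_annual_ftd_mme = mean(ev_sub$ftd_mme),
      sd_annual_ftd_mme = mean_sd(ev_sub$ftd_mme)$sd,
      mean_annual_opioid_mme = mean(ev_sub$opioid_mme),
      sd_annual_opioid_mme = mean_sd(ev_sub$opioid_mme)$sd,
      mean_mme_per_day = mean(rx_sub$mme_per_day),
      sd_mme_per_day = mean_sd(rx_sub$mme_per_day)$sd
    )
  }
  labels <- list(
    WS = "WS", WM = "WM", W_total = c("WS", "WM"),
    OS = "OS", OM = "OM", O_total = c("OS", "OM")
  )
  groups <- dplyr::bind_rows(lapply(names(labels), function(lab) {
    members <- labels[[lab]]
    summarize_block(ev[ev$group %in% members, ], rx[rx$group %in% members, ],
                    lab)
  }))
  diagnoses <- dplyr::count(
    dplyr::mutate(rx, chapter = diagnosis_chapter(.data$primary_diagnosis)),
    .data$group, .data$chapter, name = "n_reimbursements"
  )
  list(groups = groups, diagnoses = diagnoses)
}

#' Round half away from zero
#'
#' Report-table rounding: ties go away from zero (round(0.5) up, round
#' (-0.5) down), unlike base R's round-half-even. Internal computation is
#' never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
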