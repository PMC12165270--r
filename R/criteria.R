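#' Rule-engine thresholds
#'
#' The evaluation thresholds for potentially inappropriate FTD use. All
#' comparisons are boundary-inclusive: a value at the threshold is
#' compliant, a value beyond it is flagged.
#'
#' @param max_period_days Longest compliant single-prescription FTD
#'   duration (days); 90 days, i.e. 30 patches.
#' @param max_mme_per_day Dose ceiling, MME/day (single prescription) or
#'   eMME/day (multiple prescriptions).
#' @param max_overlap_per_rx_days Allowed early-revisit overlap between two
#'   consecutive prescriptions, days.
#' @param annual_overlap_fraction Allowed fraction of the annual
#'   prescription period (first to last visit) covered by overlaps, when
#'   that period is shorter than `annual_period_breakpoint_days`.
#' @param annual_overlap_cap_days Fixed allowance (days) for annual
#'   prescription periods at or beyond the breakpoint, and the cap on the
#'   fractional allowance below it.
#' @param annual_period_breakpoint_days Period length (days) at which the
#'   allowance switches from fractional to fixed.
#' @param max_institutions Most distinct prescribing institutions allowed
#'   per year.
#' @param working_age_upper Last age (years) counted as working age.
#' @return A named list of class `criteria_thresholds`.
#' @export
criteria_thresholds <- function(max_period_days = 90,
                                max_mme_per_day = 90,
                                max_overlap_per_rx_days = 3,
                                annual_overlap_fraction = 0.16,
                                annual_overlap_cap_days = 30,
                                annual_period_breakpoint_days = 182,
                                max_institutions = 3,
                                working_age_upper = 64) {
  th <- list(
    max_period_days = max_period_days,
    max_mme_per_day = max_mme_per_day,
    max_overlap_per_rx_days = max_overlap_per_rx_days,
    annual_overlap_fraction = annual_overlap_fraction,
    annual_overlap_cap_days = annual_overlap_cap_days,
    annual_period_breakpoint_days = annual_period_breakpoint_days,
    max_institutions = max_institutions,
    working_age_upper = working_age_upper
  )
  if (any(unlist(th) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  structure(th, class = "criteria_thresholds")
}

# Per-prescription overlaps between consecutive reimbursements of one
# patient-year, in days: (start_i + ftd_duration_i) - start_{i+1}, floored
# at zero. Overlap is judged on the FTD's covered days only; co-opioid
# supplies do not extend the interval.
pairwise_overlaps <- function(visit_dates, ftd_durations) {
  n <- length(visit_dates)
  if (n < 2) return(numeric(0))
  intervals <- as.numeric(diff(visit_dates))
  pmax(0, ftd_durations[-n] - intervals)
}

#' Prescription-period criterion
#'
#' Flags a patient-year when any single reimbursement's FTD covers more
#' than the allowed 90 days (more than 30 patches). Consecutive use across
#' reimbursements never triggers this criterion, however long the total.
#'
#' @param rx One patient-year's reimbursement summaries (date-ordered).
#' @param thresholds A [criteria_thresholds()] object.
#' @return List with `flag` (logical) and `evidence` (worst FTD duration,
#'   days).
#' @export
check_period <- function(rx, thresholds = criteria_thresholds()) {
  worst <- max(rx$ftd_duration_days)
  list(flag = worst > thresholds$max_period_days, evidence = worst)
}

#' Dose criterion
#'
#' Single-prescription patients are flagged when the reimbursement's
#' MME/day exceeds 90; multiple-prescription patients when ANY
#' reimbursement's eMME/day exceeds 90.
#'
#' @param rx One patient-year's reimbursement summaries with eMME columns
#'   (see [add_emme()]).
#' @inheritParams check_period
#' @return List with `flag` and `evidence` (worst offending MME/day or
#'   eMME/day).
#' @export
check_dose <- function(rx, thresholds = criteria_thresholds()) {
  dose <- if (nrow(rx) == 1) rx$mme_per_day else rx$emme_per_day
  worst <- max(dose)
  list(flag = worst > thresholds$max_mme_per_day, evidence = worst)
}

#' Per-prescription overlap criterion
#'
#' Patients may revisit up to 3 days before a prescription runs out; a
#' larger overlap between any two consecutive prescriptions is flagged.
#' Applies only to multiple-prescription patient-years.
#'
#' @inheritParams check_dose
#' @return List with `flag` and `evidence` (largest pairwise overlap,
#'   days).
#' @export
check_overlap_rx <- function(rx, thresholds = criteria_thresholds()) {
  if (nrow(rx) < 2) {
    stop("overlap criteria apply to multiple-prescription patient-years only",
         call. = FALSE)
  }
  ov <- pairwise_overlaps(rx$visit_date, rx$ftd_duration_days)
  worst <- max(ov)
  list(flag = worst > thresholds$max_overlap_per_rx_days, evidence = worst)
}

#' Annual overlap criterion
#'
#' Total pairwise overlap over the year is allowed up to 16% of the annual
#' prescription period (first to last visit) when that period is under 182
#' days, and up to a fixed 30 days otherwise. The per-prescription 3-day
#' allowance does not subtract from the total.
#'
#' @inheritParams check_dose
#' @return List with `flag`, `evidence` (total overlap, days) and
#'   `allowance` (days).
#' @export
check_overlap_annual <- function(rx, thresholds = criteria_thresholds()) {
  if (nrow(rx) < 2) {
    stop("overlap criteria apply to multiple-prescription patient-years only",
         call. = FALSE)
  }
  total <- sum(pairwise_overlaps(rx$visit_date, rx$ftd_duration_days))
  period <- as.numeric(max(rx$visit_date) - min(rx$visit_date))
  allowance <- if (period < thresholds$annual_period_breakpoint_days) {
    min(thresholds$annual_overlap_fraction * period,
        thresholds$annual_overlap_cap_days)
  } else {
    thresholds$annual_overlap_cap_days
  }
  list(flag = total > allowance, evidence = total, allowance = allowance)
}

#' Multi-institution criterion
#'
#' Flags a multiple-prescription patient-year whose FTD reimbursements
#' come from more than 3 distinct health care institutions.
#'
#' @inheritParams check_dose
#' @return List with `flag` and `evidence` (distinct institution count).
#' @export
check_multi_institution <- function(rx, thresholds = criteria_thresholds()) {
  n_inst <- dplyr::n_distinct(rx$institution_id)
  list(flag = n_inst > thresholds$max_institutions, evidence = n_inst)
}

classify_one <- function(rx, thresholds) {
  single <- nrow(rx) == 1
  period <- check_period(rx, thresholds)
  dose <- check_dose(rx, thresholds)
  if (single) {
    flags <- c(period = period$flag, dose = dose$flag,
               overlap_rx = NA, overlap_annual = NA,
               multi_institution = NA)
    evid <- list(max_rx_days = period$evidence, max_dose = dose$evidence,
                 max_overlap_rx = NA_real_, total_overlap = NA_real_,
                 annual_allowance = NA_real_, n_institutions = NA_integer_)
  } else {
    ov_rx <- check_overlap_rx(rx, thresholds)
    ov_an <- check_overlap_annual(rx, thresholds)
    multi <- check_multi_institution(rx, thresholds)
    flags <- c(period = period$flag, dose = dose$flag,
               overlap_rx = ov_rx$flag, overlap_annual = ov_an$flag,
               multi_institution = multi$flag)
    evid <- list(max_rx_days = period$evidence, max_dose = dose$evidence,
                 max_overlap_rx = ov_rx$evidence, total_overlap = ov_an$evidence,
                 annual_allowance = ov_an$allowance,
                 n_institutions = multi$evidence)
  }
  age_band <- if (rx$age[1] <= thresholds$working_age_upper) "W" else "O"
  group <- paste0(age_band, if (single) "S" else "M")
  verdict <- if (any(flags, na.rm = TRUE)) "I" else "A"
  c(
    list(patient_id = rx$patient_id[1], year = rx$year[1], sex = rx$sex[1],
         age = rx$age[1], group = group,
         n_reimbursements = nrow(rx)),
    as.list(stats::setNames(flags, paste0("flag_", names(flags)))),
    evid,
    list(verdict = verdict)
  )
}

#' Evaluate patient-years against all applicable criteria
#'
#' Applies the rule engine to every patient-year: single-prescription
#' patients are evaluated on the period and dose criteria only (the
#' overlap and multi-institution flags are NA, not FALSE); multiple-
#' prescription patients on all five. The verdict is "I" (potentially
#' inappropriate) iff any evaluated flag is TRUE, "A" otherwise. Each
#' patient-year lands in one of the groups WS/WM/OS/OM (working-age vs
#' older adult x single vs multiple prescriptions).
#'
#' @param rx Reimbursement summaries for all patient-years, with eMME
#'   columns (from [add_emme()]); rows of one patient-year must share
#'   `patient_id` and `year`.
#' @param thresholds A [criteria_thresholds()] object.
#' @return One row per patient-year: ids, demographics, `group`, the five
#'   `flag_*` columns, per-flag evidence values, and `verdict`.
#' @export
evaluate_patient_years <- function(rx, thresholds = criteria_thresholds()) {
  if (!"emme_per_day" %in% names(rx)) rx <- add_emme(rx)
  split_keys <- paste(rx$patient_id, rx$year, sep = "\r")
  rows <- lapply(split(seq_len(nrow(rx)), split_keys),
                 function(i) classify_one(rx[i, ], thresholds))
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$patient_id, .data$year)
}

#' Re-derive the verdict from flags
#'
#' The verdict is a pure function of the evaluated flags: "I" iff any
#' non-missing flag is TRUE.
#'
#' @param evaluations Output of [evaluate_patient_years()].
#' @return Character vector of "A"/"I".
#' @export
derive_verdict <- function(evaluations) {
  flags <- evaluations[, c("flag_period", "flag_dose", "flag_overlap_rx",
                           "flag_overlap_annual", "flag_multi_institution")]
  ifelse(apply(as.matrix(flags), 1, function(f) any(f, na.rm = TRUE)),
         "I", "A")
}
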