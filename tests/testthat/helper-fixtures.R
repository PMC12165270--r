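# Shared fixture builders and independent oracles. The oracles are written
# as plain element-by-element loops so they share no code path with the
# vectorized implementation they check.

# One claim row with sensible defaults.
claim <- function(patient_id = "P1", sex = "female", age = 50,
                  visit_date = as.Date("2016-03-01"), year = 2016L,
                  institution_id = "H001", setting = "outpatient",
                  drug_code = "FTD25", drug_class = "FTD",
                  strength = 25, quantity = 10L,
                  days_supplied = NA_integer_,
                  diagnosis_codes = "M54") {
  tibble::tibble(
    patient_id = patient_id, sex = sex, age = as.integer(age),
    visit_date = visit_date, year = as.integer(year),
    institution_id = institution_id, setting = setting,
    drug_code = drug_code, drug_class = drug_class,
    strength = strength, quantity = as.integer(quantity),
    days_supplied = as.integer(days_supplied),
    diagnosis_codes = diagnosis_codes
  )
}

# A patient-year of FTD-only reimbursements at given day offsets within
# the year, `patches` patches of `strength` mcg/h each.
ftd_year <- function(offsets, patches = 10L, strength = 25,
                     institutions = "H001", patient_id = "P1",
                     age = 50, year = 2016L) {
  institutions <- rep_len(institutions, length(offsets))
  patches <- rep_len(as.integer(patches), length(offsets))
  dplyr::bind_rows(lapply(seq_along(offsets), function(i) {
    claim(patient_id = patient_id, age = age, year = year,
          visit_date = as.Date(sprintf("%d-01-01", year)) + offsets[i],
          institution_id = institutions[i],
          strength = strength, quantity = patches[i])
  }))
}

# Evaluate a claims table end to end and return the single patient-year
# evaluation row (convenience for boundary tests).
evaluate_one <- function(claims, thresholds = criteria_thresholds()) {
  res <- evaluate_cohort(claims, thresholds = thresholds)
  stopifnot(nrow(res$evaluations) == 1)
  res$evaluations
}

# --- independent dose oracle -------------------------------------------

# Brute-force MME / eMME calculator: loops over reimbursements of one
# patient-year (rows already grouped by rx_id), no dplyr, no shared code.
oracle_dose_summaries <- function(items, ftd_factor = 2.4, days_per_patch = 3,
                                  oral_factors = c(MORPHINE = 1, OXYCODONE = 1.5,
                                                   HYDROCODONE = 1, HYDROMORPHONE = 4,
                                                   TRAMADOL = 0.1, CODEINE = 0.15)) {
  rx_ids <- unique(items$rx_id)
  rows <- list()
  for (id in rx_ids) {
    sub <- items[items$rx_id == id, ]
    mme <- 0
    longest <- 0
    for (j in seq_len(nrow(sub))) {
      if (sub$drug_class[j] == "FTD") {
        mme <- mme + sub$quantity[j] * sub$strength[j] * ftd_factor * days_per_patch
        dur <- sub$quantity[j] * days_per_patch
      } else {
        mme <- mme + sub$strength[j] * sub$quantity[j] *
          oral_factors[[sub$drug_code[j]]]
        dur <- sub$days_supplied[j]
      }
      if (dur > longest) longest <- dur
    }
    rows[[length(rows) + 1]] <- data.frame(
      rx_id = id, patient_id = sub$patient_id[1], year = sub$year[1],
      visit_date = sub$visit_date[1], mme_total = mme, longest_days = longest,
      mme_per_day = mme / longest
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$year, out$visit_date), ]
  # eMME: interval to next visit of the same patient-year; last visit uses
  # its own longest duration; floor intervals at 1 day
  out$emme_per_day <- NA_real_
  for (i in seq_len(nrow(out))) {
    nxt <- which(out$patient_id == out$patient_id[i] &
                 out$year == out$year[i] &
                 out$visit_date > out$visit_date[i])
    interval <- if (length(nxt) == 0) out$longest_days[i] else {
      as.numeric(min(out$visit_date[nxt]) - out$visit_date[i])
    }
    out$emme_per_day[i] <- out$mme_total[i] / max(interval, 1)
  }
  out
}

# --- independent Gini oracles ------------------------------------------

# Mean absolute difference over all ordered pairs, O(n^2).
oracle_gini_mad <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# One minus twice the trapezoidal area under the classic Lorenz curve.
oracle_gini_lorenz <- function(x) {
  xs <- sort(x)
  L <- c(0, cumsum(xs) / sum(xs))
  p <- seq(0, 1, length.out = length(L))
  area <- sum((L[-1] + L[-length(L)]) / 2 * diff(p))
  1 - 2 * area
}
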