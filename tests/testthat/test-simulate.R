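small_mix <- c(
  compliant_single = 3, compliant_multiple = 3, long_period = 3,
  high_dose_single = 3, high_dose_multiple = 3, early_revisit_overlap = 3,
  chronic_annual_overlap = 3, doctor_shopping = 3, mixed_violations = 3,
  excluded_cancer = 2, excluded_pediatric = 2, excluded_inpatient = 2
)

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(simulation_config(seed = 9, archetype_mix = small_mix))
  b <- generate_cohort(simulation_config(seed = 9, archetype_mix = small_mix))
  expect_identical(a, b)
  c <- generate_cohort(simulation_config(seed = 10, archetype_mix = small_mix))
  expect_false(identical(a$claims, c$claims))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(archetype_mix = c(compliant_single = 0)),
               "at least one patient-year")
  expect_error(simulation_config(archetype_mix = c(unicorn = 5)),
               "unknown archetype")
  expect_error(simulation_config(co_opioid_probability = 1.5))
  expect_error(sample_archetype("unicorn", simulation_config()),
               "unknown archetype")
})

test_that("every archetype's label is recovered by the rule engine", {
  for (seed in c(2, 13)) {
    cohort <- generate_cohort(simulation_config(seed = seed,
                                                archetype_mix = small_mix))
    res <- evaluate_cohort(cohort$claims)
    rec <- compare_to_labels(res$evaluations, cohort$labels, res$exclusions)
    expect_equal(rec$agreement, 1)
    expect_true(rec$decoys_ok)
    # all eligible archetypes present and all planted verdicts observed
    eligible <- cohort$labels[!cohort$labels$excluded, ]
    expect_setequal(unique(eligible$expected_verdict), c("A", "I"))
  }
})

test_that("labels are internally consistent: verdict I iff any planted flag", {
  cohort <- generate_cohort(simulation_config(seed = 4, archetype_mix = small_mix))
  eligible <- cohort$labels[!cohort$labels$excluded, ]
  flags <- eligible[, c("flag_period", "flag_dose", "flag_overlap_rx",
                        "flag_overlap_annual", "flag_multi_institution")]
  any_flag <- apply(as.matrix(flags), 1, function(f) any(f, na.rm = TRUE))
  expect_equal(eligible$expected_verdict, ifelse(any_flag, "I", "A"))
  # single-prescription archetypes carry NA overlap/institution flags
  singles <- eligible$expected_group %in% c("WS", "OS")
  expect_true(all(is.na(flags$flag_overlap_rx[singles])))
  expect_true(all(!is.na(flags$flag_overlap_rx[!singles])))
})

test_that("perturbing a violation archetype by its margin flips only the planted flag", {
  cfg <- simulation_config(seed = 21)
  flags_of <- function(claims) {
    ev <- evaluate_cohort(claims)$evaluations
    unlist(ev[, c("flag_period", "flag_dose", "flag_overlap_rx",
                  "flag_overlap_annual", "flag_multi_institution")])
  }

  # long_period: cap the prescription at 30 patches -> compliant
  lp <- sample_archetype("long_period", cfg, "X1")
  expect_true(flags_of(lp$claims)[["flag_period"]])
  relaxed <- lp$claims
  relaxed$quantity[relaxed$drug_class == "FTD"] <- 30L
  expect_false(any(flags_of(relaxed), na.rm = TRUE))

  # early_revisit_overlap: move the early visit 2 days later -> overlap 3
  er <- sample_archetype("early_revisit_overlap", cfg, "X2")
  expect_true(flags_of(er$claims)[["flag_overlap_rx"]])
  relaxed <- er$claims
  dates <- sort(unique(relaxed$visit_date))
  relaxed$visit_date[relaxed$visit_date == dates[4]] <- dates[4] + 2
  expect_false(any(flags_of(relaxed), na.rm = TRUE))

  # chronic_annual_overlap: dropping one visit brings the total to the cap
  ca <- sample_archetype("chronic_annual_overlap", cfg, "X3")
  expect_true(flags_of(ca$claims)[["flag_overlap_annual"]])
  relaxed <- ca$claims[ca$claims$visit_date != max(ca$claims$visit_date), ]
  expect_false(any(flags_of(relaxed), na.rm = TRUE))

  # doctor_shopping: merging institutions back to 3 -> compliant
  ds <- sample_archetype("doctor_shopping", cfg, "X4")
  expect_true(flags_of(ds$claims)[["flag_multi_institution"]])
  relaxed <- ds$claims
  insts <- unique(relaxed$institution_id)
  relaxed$institution_id[!relaxed$institution_id %in% insts[1:3]] <- insts[1]
  expect_false(any(flags_of(relaxed), na.rm = TRUE))

  # high_dose_single: halving the strength to 25 mcg/h -> 60 MME/day
  hd <- sample_archetype("high_dose_single", cfg, "X5")
  expect_true(flags_of(hd$claims)[["flag_dose"]])
  relaxed <- hd$claims
  relaxed$strength <- 25
  relaxed$drug_code <- "FTD25"
  expect_false(any(flags_of(relaxed), na.rm = TRUE))
})

test_that("labels round-trip through the labels file", {
  cohort <- generate_cohort(simulation_config(seed = 6, archetype_mix = small_mix))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(cohort$labels, path)
  expect_equal(as.data.frame(read_labels(path)),
               as.data.frame(cohort$labels))
})
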