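factors <- mme_factor_table()

test_that("patch MME follows strength x 2.4 x 3", {
  expect_equal(patch_mme(25), 180)
  expect_equal(patch_mme(12), 86.4)
  expect_equal(patch_mme(100), 720)
  expect_error(patch_mme(0), "positive")
  # linear in strength
  s <- c(12, 25, 50, 75, 100)
  expect_equal(patch_mme(2 * s), 2 * patch_mme(s))
})

test_that("item standardization handles FTD and oral opioids", {
  ftd <- item_mme(group_reimbursements(claim()), factors)
  expect_equal(ftd$mme_total, 1800)
  expect_equal(ftd$duration_days, 30)

  oxy <- item_mme(group_reimbursements(
    claim(drug_code = "OXYCODONE", drug_class = "other_opioid",
          strength = 5, quantity = 60, days_supplied = 30)
  ), factors)
  expect_equal(oxy$mme_total, 450)
  expect_equal(oxy$duration_days, 30)

  one_patch <- item_mme(group_reimbursements(claim(strength = 12, quantity = 1)),
                        factors)
  expect_equal(one_patch$mme_total, 86.4)
  expect_equal(one_patch$duration_days, 3)

  expect_error(
    item_mme(group_reimbursements(
      claim(drug_code = "MYSTERY", drug_class = "other_opioid",
            strength = 5, quantity = 10, days_supplied = 10)
    ), factors),
    "MYSTERY"
  )
})

test_that("MME/day divides total MME by the longest co-prescribed duration", {
  co <- function(days, quantity) {
    claim(drug_code = "OXYCODONE", drug_class = "other_opioid",
          strength = 5, quantity = quantity, days_supplied = days)
  }
  # FTD 1800/30d + oxycodone 450/30d
  rx <- summarize_reimbursements(
    group_reimbursements(dplyr::bind_rows(claim(), co(30, 60))), factors)
  expect_equal(rx$mme_per_day, 75)

  rx <- summarize_reimbursements(group_reimbursements(claim()), factors)
  expect_equal(rx$mme_per_day, 60)

  # a 60-day co-opioid supply of 600 MME sets the denominator
  rx <- summarize_reimbursements(
    group_reimbursements(dplyr::bind_rows(claim(), co(60, 80))), factors)
  expect_equal(rx$mme_total, 1800 + 600)
  expect_equal(rx$longest_days, 60)
  expect_equal(rx$mme_per_day, 40)
})

test_that("eMME/day uses the interval to the next visit", {
  rx <- add_emme(summarize_reimbursements(
    group_reimbursements(ftd_year(c(0, 30))), factors))
  expect_equal(rx$emme_per_day, c(60, 60))

  rx <- add_emme(summarize_reimbursements(
    group_reimbursements(ftd_year(c(0, 20))), factors))
  expect_equal(rx$emme_per_day[1], 90)

  # same-day visits at two institutions: interval clamps to 1 day
  rx <- add_emme(summarize_reimbursements(
    group_reimbursements(ftd_year(c(0, 0, 30), institutions = c("H001", "H002", "H001"))),
    factors))
  expect_equal(attr(rx, "n_clamped"), 1)
  expect_equal(rx$effective_interval[1], 1)
  expect_equal(rx$emme_per_day[1], 1800)
})

test_that("adherent patients have eMME/day equal to MME/day; early visits raise it", {
  # intervals equal to supply days at every visit
  rx <- add_emme(summarize_reimbursements(
    group_reimbursements(ftd_year(c(0, 30, 60, 90))), factors))
  expect_identical(rx$emme_per_day, rx$mme_per_day)

  # monotone in interval: earlier visit -> higher eMME, later -> lower
  early <- add_emme(summarize_reimbursements(
    group_reimbursements(ftd_year(c(0, 25))), factors))
  late <- add_emme(summarize_reimbursements(
    group_reimbursements(ftd_year(c(0, 35))), factors))
  expect_gt(early$emme_per_day[1], early$mme_per_day[1])
  expect_lt(late$emme_per_day[1], late$mme_per_day[1])
})

test_that("annual usage sums FTD and all-opioid MME per patient-year", {
  items <- group_reimbursements(ftd_year(c(0, 30)))
  expect_equal(annual_usage(items, factors),
               tibble::tibble(patient_id = "P1", year = 2016L,
                              ftd_mme = 3600, opioid_mme = 3600))

  with_co <- group_reimbursements(dplyr::bind_rows(
    claim(),
    claim(drug_code = "OXYCODONE", drug_class = "other_opioid",
          strength = 5, quantity = 60, days_supplied = 30)
  ))
  use <- annual_usage(with_co, factors)
  expect_equal(use$ftd_mme, 1800)
  expect_equal(use$opioid_mme, 2250)
  expect_lte(use$ftd_mme, use$opioid_mme)
})

test_that("dose standardization is homogeneous in quantity", {
  base <- ftd_year(c(0, 30, 65), patches = c(5, 7, 9))
  for (k in c(2L, 3L)) {
    scaled <- base
    scaled$quantity <- scaled$quantity * k
    u1 <- annual_usage(group_reimbursements(base), factors)
    uk <- annual_usage(group_reimbursements(scaled), factors)
    expect_equal(uk$ftd_mme, k * u1$ftd_mme)
    r1 <- summarize_reimbursements(group_reimbursements(base), factors)
    rk <- summarize_reimbursements(group_reimbursements(scaled), factors)
    expect_equal(rk$mme_total, k * r1$mme_total)
    # duration also scales, so MME/day is invariant for FTD-only visits
    expect_equal(rk$mme_per_day, r1$mme_per_day)
  }
})
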