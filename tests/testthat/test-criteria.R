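# rx summaries for one patient-year straight from claims
rx_of <- function(claims) {
  add_emme(summarize_reimbursements(group_reimbursements(claims)))
}

test_that("period criterion judges each prescription alone, never consecutive use", {
  expect_false(check_period(rx_of(ftd_year(0, patches = 30)))$flag)   # 90 d
  flagged <- check_period(rx_of(ftd_year(0, patches = 31)))           # 93 d
  expect_true(flagged$flag)
  expect_equal(flagged$evidence, 93)
  # four consecutive 30-patch prescriptions: 360 covered days, compliant
  expect_false(check_period(rx_of(ftd_year(c(0, 90, 180, 270), patches = 30)))$flag)
})

test_that("dose criterion uses MME/day for singles and any-visit eMME/day for multiples", {
  expect_false(check_dose(rx_of(ftd_year(0, strength = 25)))$flag)     # 60
  expect_false(check_dose(rx_of(ftd_year(0, strength = 37.5)))$flag)   # exactly 90
  expect_true(check_dose(rx_of(ftd_year(0, strength = 50)))$flag)      # 120

  # multiple: one early revisit pushes a single visit past 90 eMME/day
  rx <- rx_of(ftd_year(c(0, 15, 45), strength = 50))
  res <- check_dose(rx)
  expect_true(res$flag)
  expect_equal(res$evidence, 10 * 50 * 2.4 * 3 / 15)  # 240
})

test_that("per-prescription overlap allows up to 3 days of early revisit", {
  expect_false(check_overlap_rx(rx_of(ftd_year(c(0, 27))))$flag)  # overlap 3
  res <- check_overlap_rx(rx_of(ftd_year(c(0, 25))))              # overlap 5
  expect_true(res$flag)
  expect_equal(res$evidence, 5)
  expect_equal(check_overlap_rx(rx_of(ftd_year(c(0, 30))))$evidence, 0)
  expect_error(check_overlap_rx(rx_of(ftd_year(0))), "multiple-prescription")
})

test_that("annual overlap allowance is 16% under 182 days and 30 days beyond", {
  # one 60-day first supply produces the requested overlap against the
  # second visit; the final 30-day visit at `period` overlaps nothing;
  # 12 mcg/h keeps every eMME/day well under the dose threshold
  year_with <- function(overlap_total, period) {
    ftd_year(c(0, 60 - overlap_total, period), patches = c(20, 10, 10),
             strength = 12)
  }
  expect_true(check_overlap_annual(rx_of(year_with(17, 100)))$flag)
  at_limit <- check_overlap_annual(rx_of(year_with(16, 100)))
  expect_false(at_limit$flag)
  expect_equal(at_limit$allowance, 16)
  # P = 200 d: fixed 30-day allowance
  expect_false(check_overlap_annual(rx_of(year_with(30, 200)))$flag)
  expect_true(check_overlap_annual(rx_of(year_with(31, 200)))$flag)
})

test_that("multi-institution criterion counts distinct FTD prescribers", {
  inst <- function(ids, n = length(ids)) {
    rx_of(ftd_year(seq(0, by = 30, length.out = n), institutions = ids))
  }
  expect_false(check_multi_institution(inst(c("H1", "H2", "H3"), 6))$flag)
  res <- check_multi_institution(inst(c("H1", "H2", "H3", "H4")))
  expect_true(res$flag)
  expect_equal(res$evidence, 4)
  expect_false(check_multi_institution(inst("H1", 10))$flag)
})

test_that("classification assigns the age-by-frequency group and propagates flags", {
  ws <- evaluate_patient_years(rx_of(ftd_year(0, age = 64)))
  expect_equal(ws$group, "WS")
  expect_equal(ws$verdict, "A")
  # single-prescription patients: overlap/institution criteria not evaluated
  expect_true(is.na(ws$flag_overlap_rx))
  expect_true(is.na(ws$flag_overlap_annual))
  expect_true(is.na(ws$flag_multi_institution))

  om <- evaluate_patient_years(
    rx_of(ftd_year(c(0, 15, 45, 75, 105), strength = 50, age = 65)))
  expect_equal(om$group, "OM")
  expect_true(om$flag_dose)
  expect_equal(om$verdict, "I")

  ws_period <- evaluate_patient_years(rx_of(ftd_year(0, patches = 31, age = 40)))
  expect_equal(ws_period$group, "WS")
  expect_true(ws_period$flag_period)
  expect_equal(ws_period$verdict, "I")
})

test_that("verdict is a pure function of the evaluated flags", {
  cohort <- generate_cohort(simulation_config(seed = 5))
  ev <- evaluate_cohort(cohort$claims)$evaluations
  expect_equal(derive_verdict(ev), ev$verdict)
  expect_true(all(ev$group %in% c("WS", "WM", "OS", "OM")))
  expect_true(all(paste(ev$group, ev$verdict, sep = "-") %in%
                  paste(rep(c("WS", "WM", "OS", "OM"), each = 2),
                        c("A", "I"), sep = "-")))
})

test_that("raising a patch count never clears a period, dose or overlap flag", {
  flags_at <- function(q) {
    ev <- evaluate_patient_years(rx_of(ftd_year(c(0, 28, 56), patches = q)))
    unlist(ev[, c("flag_period", "flag_dose", "flag_overlap_rx",
                  "flag_overlap_annual")])
  }
  prev <- flags_at(5L)
  for (q in c(10L, 11L, 20L, 31L, 40L)) {
    cur <- flags_at(q)
    expect_true(all(cur >= prev),
                info = sprintf("flags regressed at %d patches", q))
    prev <- cur
  }
})
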