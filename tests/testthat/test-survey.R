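test_that("per-capita disposable income nets out every contribution", {
  h <- data.frame(wage_income = 50000, agricultural_income = 0,
                  business_income = 0, property_income = 0,
                  transfer_income = 0, a3137 = 1000, pension_resident = 500,
                  pension_employee_monthly = 0, medical_premium = 400,
                  n_workers = 1, a2000 = 2)
  expect_equal(as.numeric(per_capita_disposable_income(h)), 23935)
  # no deductions, single member: gross income passes through
  h0 <- data.frame(wage_income = 12000, agricultural_income = 3000,
                   business_income = 0, property_income = 500,
                   transfer_income = 1500, a3137 = 0, pension_resident = 0,
                   pension_employee_monthly = 0, medical_premium = 0,
                   n_workers = 0, a2000 = 1)
  expect_equal(as.numeric(per_capita_disposable_income(h0)), 17000)
  # monthly employee-pension contribution is annualized by 12
  h12 <- h0
  h12$pension_employee_monthly <- 100
  expect_equal(as.numeric(per_capita_disposable_income(h12)), 17000 - 1200)
  # negative disposable income is flagged NA and counted, not propagated
  hneg <- h0
  hneg$a3137 <- 99999
  res <- per_capita_disposable_income(rbind(h0, hneg))
  expect_equal(as.numeric(res), c(17000, NA))
  expect_equal(attr(res, "n_negative"), 1)
  hbad <- h0
  hbad$a2000 <- 0
  expect_error(per_capita_disposable_income(hbad), "positive")
})

test_that("insurance codes 2, 3, 4 map to URRBMI; others do not", {
  out <- classify_urrbmi(c(1, 2, 3, 4, 5, NA))
  expect_equal(as.logical(out), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(out, "unknown"), c(rep(FALSE, 5), TRUE))
  expect_error(classify_urrbmi(7), "1..5")
})

test_that("scheme reimbursements aggregate components 2 + 3 + 4 only", {
  p <- data.frame(f2025_1 = 9999, f2025_2 = 1000, f2025_3 = 0,
                  f2025_4 = 500, f2025_5 = 777,
                  f2029_1 = 50, f2029_2 = 200, f2029_3 = NA,
                  f2029_4 = 0, f2029_5 = 10)
  expect_equal(aggregate_reimbursement(p, "inpatient"), 1500)
  expect_equal(aggregate_reimbursement(p, "noninpatient"), 200)
  p_na <- data.frame(f2025_2 = NA, f2025_3 = NA, f2025_4 = NA)
  expect_equal(aggregate_reimbursement(p_na, "inpatient"), 0)
  expect_error(aggregate_reimbursement(data.frame(x = 1), "inpatient"),
               "missing reimbursement column")
})

test_that("tercile bracketing uses empirical cut points with ties to lower", {
  b <- tercile_brackets(1:9)
  expect_equal(as.vector(table(b)), c(3, 3, 3))
  expect_equal(as.character(tercile_brackets(c(10, 20, 30))),
               c("low", "medium", "high"))
  # degenerate ties: everything at the cut point goes low
  expect_equal(as.character(tercile_brackets(rep(5, 4))), rep("low", 4))
  # zeros and missings carry no expenditure and stay unbracketed
  b2 <- tercile_brackets(c(0, NA, 1, 2, 3))
  expect_true(all(is.na(b2[1:2])))
  expect_equal(as.character(b2[3:5]), c("low", "medium", "high"))
  expect_error(tercile_brackets(c(0, 0, 1, 2)), "at least 3 positive")
})

test_that("analysis rows conserve counts and log every exclusion", {
  df <- make_survey_fixture()
  rows <- build_analysis_rows(df, survey_config())
  log <- attr(rows, "drop_log")
  expect_equal(attr(rows, "n_input"), nrow(df))
  expect_equal(nrow(rows) + sum(log$n), nrow(df))
  # household 1 carries the worked-example income
  expect_equal(rows$income[rows$hid == 1][1], 23935)
  # URRBMI flags follow the insurance codes
  expect_equal(rows$insured_urrbmi[order(rows$hid, decreasing = FALSE)],
               c(TRUE, TRUE, FALSE, TRUE, FALSE))
  # scheme reimbursement excludes the employee-scheme payout of household 2
  expect_equal(sort(unique(rows$reimb_inpatient)), c(0, 1500, 2000))
  # restricting the sample to enrollees drops and logs the rest
  rows_u <- build_analysis_rows(df, survey_config(sample = "urrbmi"))
  expect_equal(nrow(rows_u), 3)
  lg <- attr(rows_u, "drop_log")
  expect_equal(lg$n[lg$reason == "not_urrbmi_enrolled"], 2)
})

test_that("stratified indices: zero transfers give MT 0, flat transfers MT > 0", {
  df <- make_survey_fixture()
  rows <- build_analysis_rows(df, survey_config())
  z <- rows
  z$reimb_inpatient <- 0
  res0 <- redistribution_by_stratum(z, "national", "inpatient")
  expect_equal(res0$mt, 0)
  flat <- rows
  flat$reimb_inpatient <- 2000
  resf <- redistribution_by_stratum(flat, "national", "inpatient")
  expect_gt(resf$mt, 0)
})

test_that("regional strata report missing regions as NA, never zero", {
  df <- make_survey_fixture() # East, Central, West only
  rows <- build_analysis_rows(df, survey_config())
  res <- redistribution_by_stratum(rows, "region", "inpatient")
  expect_equal(nrow(res), 4)
  ne <- res[res$stratum == "Northeast", ]
  expect_equal(ne$n, 0)
  expect_true(is.na(ne$gini_before))
  expect_true(is.na(ne$mt))
})

test_that("province column maps through the NBS four-region lookup", {
  df <- make_survey_fixture()
  df$province <- c("Shandong", "Shandong", "Hunan", "Sichuan", "Sichuan")
  df$region <- NULL
  rows <- build_analysis_rows(df, survey_config())
  expect_equal(as.character(sort(unique(rows$region))),
               c("East", "Central", "West"))
  df$province <- "Atlantis"
  expect_error(build_analysis_rows(df), "region")
})

test_that("the pipeline is deterministic on identical input", {
  df <- make_survey_fixture()
  a <- analyze_survey(df)
  b <- analyze_survey(df)
  expect_identical(a, b)
})
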