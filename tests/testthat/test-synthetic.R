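test_that("the generator is deterministic given a seed", {
  cfg <- generator_config(n_households = 150, seed = 42)
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  f1 <- file.path(tempdir(), "sim1.csv")
  f2 <- file.path(tempdir(), "sim2.csv")
  write_synthetic_survey(cfg, f1)
  write_synthetic_survey(cfg, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives different draws
  expect_false(identical(
    simulate_survey(generator_config(n_households = 150, seed = 43))$data,
    a$data))
})

test_that("generated data carry the assumed structure", {
  sim <- simulate_survey(generator_config(n_households = 400, seed = 5))
  d <- sim$data
  expect_true(all(c("hid", "a2000", "f2001a", "f2024", "f2025_4",
                    "province", "region", "wage_income") %in% names(d)))
  # income components reassemble the household draw exactly
  gross <- d$wage_income + d$agricultural_income + d$business_income +
    d$property_income + d$transfer_income
  expect_true(all(gross > 0))
  # right-skewed: mean well above median
  hh <- d[!duplicated(d$hid), ]
  expect_gt(mean(hh$wage_income), 1.2 * median(hh$wage_income))
  # household size consistent with the person rows
  expect_equal(as.vector(table(d$hid)), hh$a2000)
  # reimbursements obey the benefit rule: never exceed the bill, zero for
  # the uninsured
  r2 <- d$f2025_2 + d$f2025_3 + d$f2025_4
  expect_true(all(r2 <= pmax(0, d$f2024 - 800) * 0.78 + 1e-9))
  uninsured <- is.na(d$f2001a) | !(d$f2001a %in% 2:4)
  expect_true(all(r2[uninsured] == 0))
})

test_that("pipeline output recovers the embedded truth sheet exactly", {
  sim <- simulate_survey(generator_config(n_households = 800, seed = 9))
  res <- analyze_survey(sim$data)
  tr <- sim$truth$inpatient
  expect_equal(res$national$n, tr$national$n)
  expect_equal(res$national$gini_before, tr$national$gini_before,
               tolerance = 1e-12)
  expect_equal(res$national$gini_after, tr$national$gini_after,
               tolerance = 1e-12)
  expect_equal(res$national$mt, tr$national$mt, tolerance = 1e-12)
  expect_equal(res$by_bracket_inpatient$mt, tr$by_bracket$mt,
               tolerance = 1e-12)
  tro <- sim$truth$noninpatient
  expect_equal(res$by_bracket_noninpatient$mt, tro$by_bracket$mt,
               tolerance = 1e-12)
})

test_that("no enrolment means no scheme transfers and MT exactly zero", {
  cfg <- generator_config(
    n_households = 300, seed = 21,
    urrbmi_rate = c(East = 0, Central = 0, West = 0, Northeast = 0))
  sim <- simulate_survey(cfg)
  expect_true(all(sim$data$f2025_2 + sim$data$f2025_3 + sim$data$f2025_4 == 0))
  expect_true(all(sim$data$f2029_2 + sim$data$f2029_3 + sim$data$f2029_4 == 0))
  res <- analyze_survey(sim$data)
  expect_equal(res$national$mt, 0)
  expect_true(all(res$by_region$mt[!is.na(res$by_region$mt)] == 0))
  expect_true(all(res$by_bracket_inpatient$mt == 0))
  expect_equal(sim$truth$inpatient$national$mt, 0)
})

test_that("a more generous coinsurance rate strengthens redistribution", {
  base <- generator_config(n_households = 600, seed = 31)
  half <- generator_config(
    n_households = 600, seed = 31,
    schedule = policy_schedule(400, 800, 0.39, 240000, units = "rmb"))
  mt_base <- simulate_survey(base)$truth$inpatient$national$mt
  mt_half <- simulate_survey(half)$truth$inpatient$national$mt
  expect_gt(mt_base, mt_half)
  expect_gt(mt_half, 0)
})

test_that("income-independent expenses still yield positive national MT", {
  cfg <- generator_config(n_households = 600, seed = 13,
                          expense_gradient = 0)
  res <- analyze_survey(simulate_survey(cfg)$data)
  expect_gt(res$national$mt, 0)
})

test_that("config validation lists every offending field", {
  expect_error(generator_config(n_households = 0), "n_households")
  err <- tryCatch(
    generator_config(n_households = 0, worker_rate = 2,
                     expense_gradient = 0.2),
    error = function(e) conditionMessage(e))
  expect_match(err, "n_households")
  expect_match(err, "worker_rate")
  expect_match(err, "expense_gradient")
  expect_error(
    generator_config(region_shares = c(East = 1, Central = 0, West = 0,
                                       Northeast = 0.5)),
    "region_shares")
})
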