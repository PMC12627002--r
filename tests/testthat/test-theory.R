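# Published benchmark tables for the default calibration (five quintiles
# 0.3-3 W_r; premium 0.01, deductible 0.02, coinsurance 78%; default
# probability gradient). Incomes are multiples of W_r; the published MT and
# RMT columns derive from the 4-dp-rounded Ginis.
after_oop_ref <- rbind(
  c(0.288, 0.587, 0.986, 1.985, 2.984),
  c(0.278, 0.576, 0.974, 1.972, 2.970),
  c(0.262, 0.562, 0.962, 1.962, 2.962),
  c(0.240, 0.545, 0.950, 1.955, 2.960),
  c(0.212, 0.525, 0.938, 1.951, 2.964))
after_reimb_ref <- rbind(
  c(0.2880, 0.5870, 0.9860, 1.9850, 2.9840),
  c(0.3248, 0.6228, 1.0208, 2.0188, 3.0168),
  c(0.3556, 0.6556, 1.0556, 2.0556, 3.0556),
  c(0.3804, 0.6854, 1.0904, 2.0954, 3.1004),
  c(0.3992, 0.7122, 1.1252, 2.1382, 3.1512))
uninsured_ref <- rbind(
  c(0.298, 0.597, 0.996, 1.995, 2.994),
  c(0.288, 0.586, 0.984, 1.982, 2.980),
  c(0.272, 0.572, 0.972, 1.972, 2.972),
  c(0.250, 0.555, 0.960, 1.965, 2.970),
  c(0.222, 0.535, 0.948, 1.961, 2.974))

cal <- urrbmi_calibration()
probs <- expenditure_probabilities()

test_that("four-stage income evolution reproduces every benchmark income cell", {
  si <- stage_incomes(cal, probs)
  expect_equal(si$initial, c(0.3, 0.6, 1, 2, 3))
  expect_equal(si$after_premium, c(0.29, 0.59, 0.99, 1.99, 2.99))
  expect_equal(unname(si$after_oop), after_oop_ref, tolerance = 5e-5)
  expect_equal(unname(si$after_reimbursement), after_reimb_ref,
               tolerance = 5e-5)
})

test_that("the middle-income worked example traces through all four stages", {
  si <- stage_incomes(cal, probs)
  # initial W_r -> 0.99 after premium -> 0.95 after OOP -> 1.0904 reimbursed
  expect_equal(si$initial[3], 1)
  expect_equal(si$after_premium[3], 0.99)
  expect_equal(si$after_oop["b4", "q3"], 0.95, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(si$after_reimbursement["b4", "q3"], 1.0904, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Scenario 1 reproduces the published Gini, MT and RMT columns", {
  s1 <- scenario1(cal, probs)
  expect_equal(s1$gini_after_oop, c(0.3977, 0.4006, 0.4054, 0.4120, 0.4206),
               tolerance = 5e-5)
  expect_equal(s1$gini_after_reimb, c(0.3977, 0.3872, 0.3789, 0.3727, 0.3683),
               tolerance = 5e-5)
  expect_equal(s1$mt, c(0, 0.0134, 0.0265, 0.0393, 0.0523), tolerance = 5e-5)
  expect_equal(round(s1$rmt_percent, 2), c(0.00, 3.34, 6.54, 9.54, 12.43))
})

test_that("Scenario 2 reproduces the uninsured Ginis and comparison MT", {
  s2 <- scenario2(cal, probs)
  expect_abs_equal(apply(uninsured_ref, 1, gini_grouped),
                   c(0.3948, 0.3977, 0.4024, 0.4090, 0.4175))
  expect_equal(s2$gini_uninsured, c(0.3948, 0.3977, 0.4024, 0.4090, 0.4175),
               tolerance = 5e-5)
  expect_equal(s2$mt, c(-0.0029, 0.0105, 0.0235, 0.0363, 0.0492),
               tolerance = 5e-5)
})

test_that("redistribution strengthens with claim size; OOP widens the gap", {
  s1 <- scenario1(cal, probs, digits = NULL)
  s2 <- scenario2(cal, probs, digits = NULL)
  # MT and RMT strictly increase across brackets above the deductible
  expect_true(all(diff(s1$mt[2:5]) > 0))
  expect_true(all(diff(s1$rmt_percent[2:5]) > 0))
  expect_gt(s1$mt[2], s1$mt[1])
  # post-OOP Gini rises with the bill, post-reimbursement Gini falls
  expect_true(all(diff(s1$gini_after_oop) > 0))
  expect_true(all(diff(s1$gini_after_reimb[2:5]) < 0))
  # insured-vs-uninsured: negative exactly at the deductible bracket
  expect_lt(s2$mt[1], 0)
  expect_true(all(s2$mt[2:5] > 0))
  expect_true(all(diff(s2$mt[2:5]) > 0))
})

test_that("degenerate schedules switch redistribution off", {
  no_benefit <- urrbmi_calibration(
    schedule = policy_schedule(0.01, 0.02, 0, 6))
  s1 <- scenario1(no_benefit, probs, digits = NULL)
  expect_equal(s1$mt, rep(0, 5))
  # a uniform probability matrix changes nothing about that conclusion
  unif <- expenditure_probabilities(matrix(0.2, 5, 5))
  expect_equal(scenario1(no_benefit, unif, digits = NULL)$mt, rep(0, 5))
  # no premium and no benefit: insured and uninsured coincide
  free <- urrbmi_calibration(schedule = policy_schedule(0, 0.02, 0, 6))
  expect_equal(scenario2(free, probs, digits = NULL)$mt, rep(0, 5))
})

test_that("results are invariant to the numeraire W_r", {
  rmb <- urrbmi_calibration(w_r = 40000)
  s1a <- scenario1(cal, probs, digits = NULL)
  s1b <- scenario1(rmb, probs, digits = NULL)
  expect_equal(s1a$gini_after_oop, s1b$gini_after_oop, tolerance = 1e-12)
  expect_equal(s1a$mt, s1b$mt, tolerance = 1e-12)
  s2a <- scenario2(cal, probs, digits = NULL)
  s2b <- scenario2(rmb, probs, digits = NULL)
  expect_equal(s2a$mt, s2b$mt, tolerance = 1e-12)
})

test_that("probability-matrix and calibration validation catch bad input", {
  expect_error(expenditure_probabilities(matrix(0.1, 5, 5)), "sum to 1")
  expect_error(expenditure_probabilities(matrix(0.2, 4, 5)), "5 x 5")
  bad <- expenditure_probabilities()
  bad[1, 1] <- -0.1
  bad[5, 1] <- 0.6
  expect_error(expenditure_probabilities(bad), "\\[0, 1\\]")
  expect_error(urrbmi_calibration(quintile_multipliers = c(1, 1, 2, 3, 4)),
               "strictly increasing")
  # expense bracket so large a poor quintile would go negative
  expect_error(
    stage_incomes(urrbmi_calibration(
      bracket_multipliers = c(0.02, 2, 3, 4, 5))),
    "negative income")
  # per-claim ceiling binding breaks the closed-form regime: warn
  expect_warning(
    stage_incomes(urrbmi_calibration(
      schedule = policy_schedule(0.01, 0.02, 0.78, 0.05))),
    "ceiling")
})

test_that("emitted table files carry the published shapes and precision", {
  out <- file.path(tempdir(), "theory-tables")
  tabs <- emit_tables(cal, probs, out)
  expect_true(all(file.exists(file.path(
    out, c("table3.csv", "table4.csv", "table5.csv", "table6.csv",
           "theory_tables.json")))))
  t4 <- read.csv(file.path(out, "table4.csv"))
  expect_equal(nrow(t4), 5)
  expect_equal(t4$rmt_percent, c(0.00, 3.34, 6.54, 9.54, 12.43))
  t6 <- read.csv(file.path(out, "table6.csv"))
  expect_equal(t6$mt, c(-0.0029, 0.0105, 0.0235, 0.0363, 0.0492))
  t5 <- read.csv(file.path(out, "table5.csv"))
  expect_equal(t5$gini[2:6], c(0.3948, 0.3977, 0.4024, 0.4090, 0.4175))
})
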