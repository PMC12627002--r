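#' Calibration of the theoretical URRBMI model
#'
#' The theoretical model works on five equally sized income quintiles whose
#' per-capita disposable incomes are fixed multiples of a reference income
#' `W_r` (RMB 40,000, the rounded national per-capita disposable income),
#' and five inpatient-expenditure brackets, also multiples of `W_r`. The
#' benefit schedule follows the Beijing 2024 secondary-tier hospital rule:
#' flat premium 0.01 W_r (RMB 400), deductible 0.02 W_r (RMB 800),
#' coinsurance 78%, per-claim ceiling 6 W_r. The lowest expenditure bracket
#' equals the deductible and also stands in for zero spending.
#'
#' All computations are homogeneous of degree zero in `w_r`: results are
#' identical whether expressed in currency or in multiples of the reference
#' income.
#'
#' @param w_r reference per-capita disposable income (the numeraire);
#'   1 computes in multiples of W_r, 40000 in RMB.
#' @param quintile_multipliers incomes of the five quintiles as multiples
#'   of `w_r`, strictly increasing.
#' @param bracket_multipliers the five inpatient-expenditure brackets as
#'   multiples of `w_r`, strictly increasing; the first must equal the
#'   schedule deductible (in `w_r` units).
#' @param schedule a [policy_schedule()] in the same units as `w_r`;
#'   defaults to the Beijing 2024 secondary-tier calibration scaled by `w_r`.
#' @return An object of class `urrbmi_calibration`.
#' @examples
#' urrbmi_calibration()          # dimensionless, in multiples of W_r
#' urrbmi_calibration(w_r = 40000) # in RMB
#' @export
urrbmi_calibration <- function(w_r = 1,
                               quintile_multipliers = c(0.3, 0.6, 1, 2, 3),
                               bracket_multipliers = c(0.02, 0.08, 0.14, 0.20, 0.26),
                               schedule = NULL) {
  stopifnot(is.numeric(w_r), length(w_r) == 1L, w_r > 0)
  if (is.null(schedule)) {
    schedule <- policy_schedule(
      premium = 0.01 * w_r, deductible = 0.02 * w_r,
      coinsurance_rate = 0.78, ceiling = 6 * w_r,
      label = "secondary-tier hospital (Beijing 2024)",
      units = if (w_r == 1) "w_r" else "rmb"
    )
  }
  stopifnot(inherits(schedule, "policy_schedule"))
  if (any(diff(quintile_multipliers) <= 0) || any(diff(bracket_multipliers) <= 0)) {
    stop("quintile and bracket multipliers must be strictly increasing",
         call. = FALSE)
  }
  if (any(quintile_multipliers <= 0)) {
    stop("quintile multipliers must be positive", call. = FALSE)
  }
  if (abs(bracket_multipliers[1] * w_r - schedule$deductible) > 1e-9 * w_r) {
    warning("lowest expenditure bracket does not equal the deductible; ",
            "it no longer represents the zero-reimbursement case")
  }
  structure(
    list(w_r = w_r,
         quintile_multipliers = quintile_multipliers,
         bracket_multipliers = bracket_multipliers,
         schedule = schedule),
    class = "urrbmi_calibration"
  )
}

#' @export
print.urrbmi_calibration <- function(x, ...) {
  cat(sprintf("URRBMI theoretical calibration (W_r = %g)\n", x$w_r))
  cat("  quintile incomes: ", paste(x$quintile_multipliers, collapse = ", "),
      " (x W_r)\n", sep = "")
  cat("  expense brackets: ", paste(x$bracket_multipliers, collapse = ", "),
      " (x W_r)\n", sep = "")
  print(x$schedule)
  invisible(x)
}

#' Inpatient expenditure probabilities by income quintile
#'
#' Probability that a member of each income quintile incurs an inpatient
#' episode in each expenditure bracket. The default encodes the calibrated
#' income gradient: for the poorest quintile the probabilities of the five
#' brackets (low to high cost) rise linearly 0.10 to 0.30 in 0.05 steps;
#' the lower-middle quintile rises 0.15 to 0.25 in 0.025 steps; the middle
#' quintile is uniform at 0.20; the upper-middle and top quintiles mirror
#' the first two downwards. Poorer groups are thus more likely to face
#' high-cost admissions. Each quintile's five bracket probabilities sum to 1.
#'
#' @param probs optional 5 x 5 numeric matrix, rows = expenditure brackets
#'   (low to high), columns = income quintiles (poorest to richest); each
#'   column must sum to 1 with all entries in \[0, 1\].
#' @return A 5 x 5 matrix of class `matrix` with dimnames
#'   `bracket` x `quintile`.
#' @examples
#' expenditure_probabilities()
#' @export
expenditure_probabilities <- function(probs = NULL) {
  if (is.null(probs)) {
    probs <- cbind(
      q1 = c(0.10, 0.15, 0.20, 0.25, 0.30),
      q2 = c(0.15, 0.175, 0.20, 0.225, 0.25),
      q3 = c(0.20, 0.20, 0.20, 0.20, 0.20),
      q4 = c(0.25, 0.225, 0.20, 0.175, 0.15),
      q5 = c(0.30, 0.25, 0.20, 0.15, 0.10)
    )
  }
  probs <- as.matrix(probs)
  if (!is.numeric(probs) || any(dim(probs) != c(5L, 5L))) {
    stop("expenditure probabilities must be a numeric 5 x 5 matrix",
         call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  csum <- colSums(probs)
  if (any(abs(csum - 1) > 1e-8)) {
    stop("each quintile's bracket probabilities must sum to 1 (columns sum to ",
         paste(signif(csum, 6), collapse = ", "), ")", call. = FALSE)
  }
  dimnames(probs) <- list(bracket = paste0("b", 1:5),
                          quintile = paste0("q", 1:5))
  probs
}

#' Four-stage income evolution of the insured quintiles
#'
#' For each quintile the disposable income passes through four states:
#' (1) initial disposable income; (2) after paying the flat premium;
#' (3) after out-of-pocket inpatient spending, where the expense is weighted
#' by the quintile's probability of incurring that bracket's episode; and
#' (4) after reimbursement, where the full benefit
#' `coinsurance_rate * (expense - deductible)` is added back, unweighted.
#' The asymmetry — probability-weighted spending but unweighted benefit — is
#' the convention of the calibrated model and is kept deliberately (see the
#' methods vignette).
#'
#' @param cal an [urrbmi_calibration()].
#' @param probs an [expenditure_probabilities()] matrix.
#' @return A list of class `stage_incomes` with elements `initial`,
#'   `after_premium` (length-5 vectors), `after_oop` and
#'   `after_reimbursement` (5 x 5 matrices, brackets x quintiles), all in
#'   the units of `cal$w_r`.
#' @examples
#' si <- stage_incomes(urrbmi_calibration(), expenditure_probabilities())
#' si$after_oop["b4", "q3"]            # 0.95: the mid-income worked example
#' si$after_reimbursement["b4", "q3"]  # 1.0904
#' @export
stage_incomes <- function(cal, probs = expenditure_probabilities()) {
  stopifnot(inherits(cal, "urrbmi_calibration"))
  probs <- expenditure_probabilities(probs)
  sched <- cal$schedule
  initial <- cal$quintile_multipliers * cal$w_r
  after_premium <- apply_premium(initial, sched)
  expenses <- cal$bracket_multipliers * cal$w_r

  # rows: brackets; columns: quintiles
  oop <- outer(expenses, rep(1, 5)) * probs
  after_oop <- matrix(after_premium, 5, 5, byrow = TRUE) - oop
  benefit <- reimbursement(expenses, sched)
  if (any(sched$coinsurance_rate * pmax(0, expenses - sched$deductible) >
          sched$ceiling)) {
    warning("the per-claim ceiling binds for at least one bracket; ",
            "the closed-form stage evolution assumes it never does")
  }
  after_reimb <- after_oop + matrix(benefit, 5, 5)

  bad <- which(after_oop < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "negative income after out-of-pocket payment at bracket %d, quintile %d",
      bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  dimnames(after_oop) <- dimnames(after_reimb) <- dimnames(probs)
  structure(
    list(initial = initial, after_premium = after_premium,
         after_oop = after_oop, after_reimbursement = after_reimb,
         bracket_multipliers = cal$bracket_multipliers, w_r = cal$w_r),
    class = "stage_incomes"
  )
}

#' Scenario 1: redistribution among the insured who receive reimbursement
#'
#' For each expenditure bracket, compares the Gini coefficient of the
#' after-out-of-pocket income vector (`G`, before benefit) with that of the
#' after-reimbursement vector (`G*`), yielding the MT index `G - G*` and the
#' relative effect RMT. At the deductible bracket no benefit is triggered
#' and MT = 0; above it MT and RMT rise with the size of the claim.
#'
#' @inheritParams stage_incomes
#' @param digits number of decimals the Gini coefficients are rounded to
#'   before MT and RMT are formed. The default 4 reproduces the published
#'   reporting convention, under which MT and RMT derive from the 4-dp
#'   Ginis; use `NULL` for full precision.
#' @return A data frame with one row per bracket: `bracket` (multiple of
#'   W_r), `gini_after_oop`, `gini_after_reimb`, `mt`, `rmt_percent`.
#' @examples
#' scenario1(urrbmi_calibration())
#' @export
scenario1 <- function(cal, probs = expenditure_probabilities(), digits = 4) {
  si <- stage_incomes(cal, probs)
  g_oop <- apply(si$after_oop, 1, gini_grouped)
  g_reimb <- apply(si$after_reimbursement, 1, gini_grouped)
  if (!is.null(digits)) {
    g_oop <- round(g_oop, digits)
    g_reimb <- round(g_reimb, digits)
  }
  mt <- g_oop - g_reimb
  data.frame(
    bracket = si$bracket_multipliers,
    gini_after_oop = g_oop,
    gini_after_reimb = g_reimb,
    mt = mt,
    rmt_percent = 100 * mt / g_oop,
    row.names = NULL
  )
}

#' Scenario 2: insured with reimbursement vs. remaining uninsured
#'
#' The counterfactual uninsured population pays no premium and bears the
#' full probability-weighted inpatient bill. Per bracket, the MT index is
#' the uninsured Gini minus the insured post-reimbursement Gini: positive
#' values mean enrolment plus reimbursement leaves a more equal
#' distribution than non-coverage. At the deductible bracket the insured
#' pay the premium but receive nothing, so MT is slightly negative.
#'
#' @inheritParams scenario1
#' @return A data frame with one row per bracket: `bracket`,
#'   `gini_uninsured`, `gini_insured_reimb`, `mt`.
#' @examples
#' scenario2(urrbmi_calibration())
#' @export
scenario2 <- function(cal, probs = expenditure_probabilities(), digits = 4) {
  probs <- expenditure_probabilities(probs)
  si <- stage_incomes(cal, probs)
  expenses <- cal$bracket_multipliers * cal$w_r
  uninsured <- matrix(si$initial, 5, 5, byrow = TRUE) -
    outer(expenses, rep(1, 5)) * probs
  if (any(uninsured < 0)) {
    stop("negative uninsured income; expense brackets too large for the ",
         "income quintiles", call. = FALSE)
  }
  g_unins <- apply(uninsured, 1, gini_grouped)
  g_reimb <- apply(si$after_reimbursement, 1, gini_grouped)
  if (!is.null(digits)) {
    g_unins <- round(g_unins, digits)
    g_reimb <- round(g_reimb, digits)
  }
  data.frame(
    bracket = si$bracket_multipliers,
    gini_uninsured = g_unins,
    gini_insured_reimb = g_reimb,
    mt = g_unins - g_reimb,
    row.names = NULL
  )
}

#' Assemble the four result tables of the theoretical model
#'
#' Builds the published table set for a calibration: the insured four-stage
#' income evolution with Ginis (table 3), the Scenario 1 redistribution
#' indicators (table 4), the uninsured full-self-payment incomes with Ginis
#' (table 5), and the Scenario 2 insured-vs-uninsured comparison (table 6).
#'
#' @inheritParams scenario1
#' @return A named list of four data frames:
#'   `insured_stages`, `scenario1`, `uninsured_stages`, `scenario2`.
#' @export
theory_tables <- function(cal = urrbmi_calibration(),
                          probs = expenditure_probabilities(),
                          digits = 4) {
  probs <- expenditure_probabilities(probs)
  si <- stage_incomes(cal, probs)
  rnd <- function(x) if (is.null(digits)) x else round(x, digits)

  inc_row <- function(stage, values, bracket = NA_real_) {
    values <- unname(values)
    data.frame(stage = stage, bracket = bracket,
               q1 = values[1], q2 = values[2], q3 = values[3],
               q4 = values[4], q5 = values[5],
               gini = rnd(gini_grouped(values)))
  }
  t3 <- rbind(
    inc_row("initial", si$initial),
    inc_row("after_premium", si$after_premium),
    do.call(rbind, lapply(1:5, function(b) {
      inc_row("after_oop", si$after_oop[b, ], si$bracket_multipliers[b])
    })),
    do.call(rbind, lapply(1:5, function(b) {
      inc_row("after_reimbursement", si$after_reimbursement[b, ],
              si$bracket_multipliers[b])
    }))
  )
  uninsured <- matrix(si$initial, 5, 5, byrow = TRUE) -
    outer(cal$bracket_multipliers * cal$w_r, rep(1, 5)) * probs
  t5 <- rbind(
    inc_row("initial", si$initial),
    do.call(rbind, lapply(1:5, function(b) {
      inc_row("net_of_expense", uninsured[b, ], si$bracket_multipliers[b])
    }))
  )
  rownames(t3) <- rownames(t5) <- NULL
  list(
    insured_stages = t3,
    scenario1 = scenario1(cal, probs, digits),
    uninsured_stages = t5,
    scenario2 = scenario2(cal, probs, digits)
  )
}

#' Write the theoretical result tables to disk
#'
#' Renders the four tables of [theory_tables()] as CSV files
#' (`table3.csv` ... `table6.csv`) plus a JSON summary, rounding to the
#' published precision (incomes and Ginis 4 dp, RMT 2 dp percent).
#'
#' @inheritParams scenario1
#' @param dir output directory, created if needed.
#' @return Invisibly, the list of tables written.
#' @export
emit_tables <- function(cal = urrbmi_calibration(),
                        probs = expenditure_probabilities(),
                        dir = ".") {
  tabs <- theory_tables(cal, probs, digits = 4)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- tabs
  out$scenario1$rmt_percent <- round(out$scenario1$rmt_percent, 2)
  num <- vapply(out$insured_stages, is.numeric, logical(1))
  out$insured_stages[num] <- lapply(out$insured_stages[num], round, digits = 4)
  num <- vapply(out$uninsured_stages, is.numeric, logical(1))
  out$uninsured_stages[num] <- lapply(out$uninsured_stages[num], round,
                                      digits = 4)
  files <- c(insured_stages = "table3.csv", scenario1 = "table4.csv",
             uninsured_stages = "table5.csv", scenario2 = "table6.csv")
  for (nm in names(files)) {
    utils::write.csv(out[[nm]], file.path(dir, files[[nm]]),
                     row.names = FALSE)
  }
  jsonlite::write_json(out, file.path(dir, "theory_tables.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Published benchmark values for the default calibration
#'
#' The Gini, MT and RMT values published for the default calibration
#' (five quintiles 0.3-3 W_r, Beijing 2024 secondary-tier schedule,
#' default probability gradient), used by [run_theory()] to report a
#' pass/fail regression comparison.
#'
#' @return A named list of reference vectors, all at published precision.
#' @keywords internal
#' @export
reference_tables <- function() {
  list(
    gini_initial = 0.3942,
    gini_after_premium = 0.3971,
    gini_after_oop = c(0.3977, 0.4006, 0.4054, 0.4120, 0.4206),
    gini_after_reimb = c(0.3977, 0.3872, 0.3789, 0.3727, 0.3683),
    mt_scenario1 = c(0, 0.0134, 0.0265, 0.0393, 0.0523),
    rmt_scenario1 = c(0.00, 3.34, 6.54, 9.54, 12.43),
    gini_uninsured = c(0.3948, 0.3977, 0.4024, 0.4090, 0.4175),
    mt_scenario2 = c(-0.0029, 0.0105, 0.0235, 0.0363, 0.0492)
  )
}
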