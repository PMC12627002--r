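#' URRBMI benefit schedule
#'
#' A benefit schedule bundles the four parameters of a resident
#' medical-insurance rule: the flat annual premium, the deductible below
#' which nothing is reimbursed, the coinsurance rate applied to eligible
#' spending above the deductible, and the ceiling capping the payout of a
#' single reimbursement claim. Values may be expressed in currency (RMB) or
#' as multiples of a reference income; the `units` field records which.
#'
#' @param premium flat premium per enrollee per year, >= 0.
#' @param deductible reimbursement threshold, >= 0.
#' @param coinsurance_rate fraction of eligible expense reimbursed, in \[0, 1\].
#' @param ceiling maximum payout per claim, > deductible.
#' @param label free-text label, e.g. the hospital tier the schedule applies to.
#' @param units `"w_r"` when parameters are multiples of the reference
#'   per-capita disposable income, `"rmb"` when they are currency.
#' @return An object of class `policy_schedule`.
#' @examples
#' policy_schedule(premium = 0.01, deductible = 0.02,
#'                 coinsurance_rate = 0.78, ceiling = 6)
#' @export
policy_schedule <- function(premium, deductible, coinsurance_rate, ceiling,
                            label = "secondary-tier hospital",
                            units = c("w_r", "rmb")) {
  units <- match.arg(units)
  stopifnot(is.numeric(premium), is.numeric(deductible),
            is.numeric(coinsurance_rate), is.numeric(ceiling))
  if (premium < 0) stop("premium must be >= 0", call. = FALSE)
  if (deductible < 0) stop("deductible must be >= 0", call. = FALSE)
  if (coinsurance_rate < 0 || coinsurance_rate > 1) {
    stop("coinsurance_rate must lie in [0, 1]", call. = FALSE)
  }
  if (ceiling <= deductible) {
    stop("ceiling must exceed the deductible", call. = FALSE)
  }
  structure(
    list(premium = premium, deductible = deductible,
         coinsurance_rate = coinsurance_rate, ceiling = ceiling,
         label = label, units = units),
    class = "policy_schedule"
  )
}

#' @export
print.policy_schedule <- function(x, ...) {
  unit <- if (x$units == "w_r") "x W_r" else "RMB"
  cat(sprintf(
    "URRBMI benefit schedule (%s)\n  premium:     %g %s\n  deductible:  %g %s\n  coinsurance: %g%%\n  ceiling:     %g %s per claim\n",
    x$label, x$premium, unit, x$deductible, unit,
    100 * x$coinsurance_rate, x$ceiling, unit
  ))
  invisible(x)
}

#' Reimbursement paid for a medical expense
#'
#' The scheme pays `coinsurance_rate * (expense - deductible)` on spending
#' above the deductible, capped at the per-claim ceiling:
#' `min(rate * max(0, expense - deductible), ceiling)`. Piecewise linear and
#' nondecreasing in the expense; never negative and never more than the
#' expense itself for coinsurance rates at or below 1.
#'
#' @param expense non-negative medical expense (vectorized).
#' @param schedule a [policy_schedule()].
#' @return Reimbursement amount(s), same length as `expense`.
#' @examples
#' sched <- policy_schedule(0.01, 0.02, 0.78, 6)
#' reimbursement(0.20, sched) # (0.20 - 0.02) * 0.78 = 0.1404
#' reimbursement(0.02, sched) # at the deductible: 0
#' @export
reimbursement <- function(expense, schedule) {
  stopifnot(inherits(schedule, "policy_schedule"), is.numeric(expense))
  if (any(expense < 0, na.rm = TRUE)) {
    stop("medical expense must be >= 0", call. = FALSE)
  }
  pmin(schedule$coinsurance_rate * pmax(0, expense - schedule$deductible),
       schedule$ceiling)
}

#' Deduct the flat premium from disposable income
#'
#' @param income disposable income(s) before the contribution; each must be
#'   at least the premium (the quintile construction excludes incomes that
#'   would turn negative).
#' @param schedule a [policy_schedule()].
#' @return `income - premium`.
#' @export
apply_premium <- function(income, schedule) {
  stopifnot(inherits(schedule, "policy_schedule"), is.numeric(income))
  if (any(income < schedule$premium, na.rm = TRUE)) {
    stop("income below the premium would turn negative after contribution",
         call. = FALSE)
  }
  income - schedule$premium
}

#' Read a benefit schedule from a YAML or JSON config file
#'
#' The file must contain the fields `premium`, `deductible`,
#' `coinsurance_rate` and `ceiling`, and may carry `label` and `units`
#' (`"w_r"` or `"rmb"`). A top-level `schedule:` block is also accepted.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [policy_schedule()].
#' @export
read_policy_schedule <- function(path) {
  cfg <- read_config_file(path)
  if (!is.null(cfg$schedule)) cfg <- cfg$schedule
  required <- c("premium", "deductible", "coinsurance_rate", "ceiling")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("schedule config is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  policy_schedule(
    premium = cfg$premium, deductible = cfg$deductible,
    coinsurance_rate = cfg$coinsurance_rate, ceiling = cfg$ceiling,
    label = cfg$label %||% "unnamed schedule",
    units = cfg$units %||% "w_r"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
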