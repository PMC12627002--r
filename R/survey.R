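#' Pipeline configuration for the survey analysis
#'
#' Switches the survey questionnaire leaves open. `unit` selects the Gini's
#' unit of analysis: `"person"` (default) gives every individual one
#' observation carrying their household's per-capita disposable income;
#' `"household"` collapses to one observation per household. `attach`
#' controls how a person's out-of-pocket expense and reimbursement adjust
#' the per-capita income: `"person"` (default) applies the full amounts to
#' that individual's observation, `"percapita"` spreads them over household
#' members (divides by household size). `sample` restricts the analysis to
#' URRBMI enrollees (`"urrbmi"`) or keeps the full national sample
#' (`"all"`, default — non-enrollees simply have zero scheme reimbursement).
#'
#' @param unit `"person"` or `"household"`.
#' @param attach `"person"` or `"percapita"`.
#' @param sample `"all"` or `"urrbmi"`.
#' @param unemployment_flat flat annual unemployment-insurance contribution
#'   deducted per worker (RMB 230, the 1% combined employer-employee rate on
#'   a reference wage).
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(unit = c("person", "household"),
                          attach = c("person", "percapita"),
                          sample = c("all", "urrbmi"),
                          unemployment_flat = 230) {
  structure(
    list(unit = match.arg(unit), attach = match.arg(attach),
         sample = match.arg(sample),
         unemployment_flat = unemployment_flat),
    class = "survey_config"
  )
}

#' Classify URRBMI enrolment from the insurance-type code
#'
#' The survey insurance-type item codes: 1 = urban employee scheme (UEBMI),
#' 2 = urban resident scheme, 3 = the rural cooperative scheme (NRCMS),
#' 4 = the merged urban-rural resident scheme, 5 = government-funded care.
#' Since the resident and rural schemes were merged into URRBMI by 2019,
#' codes 2, 3 and 4 all count as URRBMI enrolment. Missing codes are
#' treated as not enrolled, with the uncertainty flagged.
#'
#' @param code integer vector of insurance-type codes in 1..5, NA allowed.
#' @return Logical vector, `TRUE` for URRBMI enrolment, with attribute
#'   `"unknown"`: a logical vector marking missing codes.
#' @examples
#' classify_urrbmi(c(1, 2, 3, 4, 5, NA))
#' @export
classify_urrbmi <- function(code) {
  if (!all(is.na(code) | (code %in% 1:5))) {
    stop("insurance-type codes must be in 1..5 or missing", call. = FALSE)
  }
  out <- !is.na(code) & code %in% 2:4
  attr(out, "unknown") <- is.na(code)
  out
}

#' Total URRBMI reimbursement of a person, by channel
#'
#' Sums the resident-scheme components of the reimbursement breakdown:
#' inpatient components 2 + 3 + 4 of `f2025_*` (the series `R2`), or
#' non-inpatient components 2 + 3 + 4 of `f2029_*` (the series `Q2`).
#' Component 1 (employee scheme) and 5 (government-funded) are excluded.
#' Missing components count as zero — no reported claim, no payout.
#'
#' @param persons data frame with columns `f2025_1`..`f2025_5` and/or
#'   `f2029_1`..`f2029_5`.
#' @param channel `"inpatient"` (R2) or `"noninpatient"` (Q2).
#' @return Numeric vector of per-person URRBMI reimbursements.
#' @export
aggregate_reimbursement <- function(persons,
                                    channel = c("inpatient", "noninpatient")) {
  channel <- match.arg(channel)
  stem <- if (channel == "inpatient") "f2025" else "f2029"
  cols <- paste0(stem, "_", 2:4)
  missing <- setdiff(cols, names(persons))
  if (length(missing)) {
    stop("missing reimbursement column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(persons[cols])
  m[is.na(m)] <- 0
  unname(rowSums(m))
}

#' Household per-capita disposable income
#'
#' The survey has no ready-made disposable-income variable; it is built as
#' gross income (wage + agricultural + business + property + transfer)
#' minus individual income tax (`a3137`), annual resident pension
#' contributions (`f1008a`, summed over members), annualized employee
#' pension contributions (12 x monthly `f1008`), medical-insurance premiums
#' (`f2004`) and a flat unemployment-insurance contribution per worker —
#' all social-insurance contributions including the URRBMI premium — then
#' divided by household size (`a2000`). Households whose disposable income
#' turns negative are returned as `NA` and counted in the `"n_negative"`
#' attribute; callers exclude and log them.
#'
#' @param households data frame with one row per household and columns
#'   `wage_income`, `agricultural_income`, `business_income`,
#'   `property_income`, `transfer_income`, `a3137`, `pension_resident`
#'   (household sum of f1008a), `pension_employee_monthly` (household sum of
#'   f1008), `medical_premium` (household sum of f2004), `n_workers`,
#'   `a2000`.
#' @param unemployment_flat flat contribution per worker (default RMB 230).
#' @return Numeric vector of per-capita disposable incomes, `NA` where
#'   negative, with attribute `"n_negative"`.
#' @examples
#' h <- data.frame(wage_income = 50000, agricultural_income = 0,
#'                 business_income = 0, property_income = 0,
#'                 transfer_income = 0, a3137 = 1000, pension_resident = 500,
#'                 pension_employee_monthly = 0, medical_premium = 400,
#'                 n_workers = 1, a2000 = 2)
#' per_capita_disposable_income(h) # (50000-1000-500-400-230)/2 = 23935
#' @export
per_capita_disposable_income <- function(households, unemployment_flat = 230) {
  need <- c("wage_income", "agricultural_income", "business_income",
            "property_income", "transfer_income", "a3137",
            "pension_resident", "pension_employee_monthly",
            "medical_premium", "n_workers", "a2000")
  missing <- setdiff(need, names(households))
  if (length(missing)) {
    stop("household table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(households$a2000)) || any(households$a2000 < 1)) {
    stop("household size (a2000) must be a positive integer", call. = FALSE)
  }
  z <- function(v) ifelse(is.na(v), 0, v)
  gross <- z(households$wage_income) + z(households$agricultural_income) +
    z(households$business_income) + z(households$property_income) +
    z(households$transfer_income)
  disposable <- gross - z(households$a3137) - z(households$pension_resident) -
    12 * z(households$pension_employee_monthly) -
    z(households$medical_premium) -
    unemployment_flat * z(households$n_workers)
  pcdi <- disposable / households$a2000
  neg <- pcdi < 0
  pcdi[neg] <- NA_real_
  attr(pcdi, "n_negative") <- sum(neg)
  pcdi
}

#' Tercile expenditure brackets
#'
#' Classifies reported medical-expenditure amounts into low, medium and
#' high terciles using the empirical 33.33/66.67 percentile cut points of
#' the positive amounts. Ties at a cut point fall to the lower bracket;
#' zero and missing amounts get `NA` (they carry no expenditure to bracket
#' and are excluded from bracketed strata).
#'
#' @param expenses numeric vector of expenditure amounts; needs at least 3
#'   positive observations.
#' @return Factor with levels `low < medium < high`, `NA` for zero/missing.
#' @examples
#' tercile_brackets(c(10, 20, 30))
#' @export
tercile_brackets <- function(expenses) {
  pos <- expenses[!is.na(expenses) & expenses > 0]
  if (length(pos) < 3L) {
    stop("need at least 3 positive expenditure observations to form terciles",
         call. = FALSE)
  }
  cuts <- stats::quantile(pos, c(1, 2) / 3, names = FALSE, type = 7)
  lab <- ifelse(is.na(expenses) | expenses <= 0, NA_character_,
                ifelse(expenses <= cuts[1], "low",
                       ifelse(expenses <= cuts[2], "medium", "high")))
  factor(lab, levels = c("low", "medium", "high"), ordered = TRUE)
}

# Aggregate a person-level survey table to one row per household.
aggregate_households <- function(persons) {
  hh_cols <- c("wage_income", "agricultural_income", "business_income",
               "property_income", "transfer_income", "a3137", "a2000")
  missing <- setdiff(c(hh_cols, "hid"), names(persons))
  if (length(missing)) {
    stop("survey table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  z <- function(v) ifelse(is.na(v), 0, v)
  first <- function(v) v[1]
  hh <- do.call(rbind, lapply(split(persons, persons$hid), function(d) {
    data.frame(
      hid = first(d$hid),
      wage_income = first(d$wage_income),
      agricultural_income = first(d$agricultural_income),
      business_income = first(d$business_income),
      property_income = first(d$property_income),
      transfer_income = first(d$transfer_income),
      a3137 = first(d$a3137),
      a2000 = first(d$a2000),
      pension_resident = sum(z(d$f1008a)),
      pension_employee_monthly = sum(z(d$f1008)),
      medical_premium = sum(z(d$f2004)),
      n_workers = sum(z(d$is_worker)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(hh) <- NULL
  hh
}

# Resolve the region column: use `region` if present, else map `province`
# through the National Bureau of Statistics four-region lookup.
resolve_region <- function(persons, lookup = NULL) {
  regions <- c("East", "Central", "West", "Northeast")
  if ("region" %in% names(persons)) {
    r <- as.character(persons$region)
  } else if ("province" %in% names(persons)) {
    if (is.null(lookup)) {
      lookup <- utils::read.csv(
        system.file("extdata", "nbs_regions.csv", package = "urrbmi"),
        stringsAsFactors = FALSE
      )
    }
    r <- lookup$region[match(persons$province, lookup$province)]
    unmatched <- is.na(r) & !is.na(persons$province)
    if (any(unmatched)) {
      stop("province(s) not in the four-region lookup: ",
           paste(unique(persons$province[unmatched]), collapse = ", "),
           call. = FALSE)
    }
  } else {
    stop("survey table needs a 'region' or 'province' column", call. = FALSE)
  }
  bad <- !is.na(r) & !(r %in% regions)
  if (any(bad)) {
    stop("unrecognized region value(s): ",
         paste(unique(r[bad]), collapse = ", "), call. = FALSE)
  }
  factor(r, levels = regions)
}

#' Build person-level analysis rows from a raw survey table
#'
#' Runs the income-construction stage of the pipeline: aggregates the
#' person-level table to households, constructs per-capita disposable
#' income, maps provinces to the four macro-regions, classifies URRBMI
#' enrolment, sums the scheme reimbursements (R2 and Q2), assigns
#' expenditure terciles, and applies the exclusion rules. Every excluded
#' row is counted by reason in the `"drop_log"` attribute so that rows in =
#' rows analyzed + rows dropped always holds.
#'
#' @param persons data frame in the survey CSV schema (see
#'   [simulate_survey()] for the column list).
#' @param config a [survey_config()].
#' @return Data frame with one row per retained person: `hid`, `region`,
#'   `income` (per-capita disposable), `insured_urrbmi`, `oop_inpatient`,
#'   `reimb_inpatient`, `oop_noninpatient`, `reimb_noninpatient`,
#'   `bracket_inpatient`, `bracket_noninpatient`. Attribute `"drop_log"` is
#'   a data frame of exclusion reasons and counts.
#' @export
build_analysis_rows <- function(persons, config = survey_config()) {
  stopifnot(inherits(config, "survey_config"))
  n_in <- nrow(persons)
  if (!n_in) stop("no records in survey table", call. = FALSE)
  drop <- list()

  region <- resolve_region(persons)
  hh <- aggregate_households(persons)
  hh$pcdi <- per_capita_disposable_income(hh, config$unemployment_flat)
  n_neg_hh <- attr(hh$pcdi, "n_negative")

  pcdi <- hh$pcdi[match(persons$hid, hh$hid)]
  insured <- classify_urrbmi(persons$f2001a)
  div <- if (config$attach == "percapita") persons$a2000 else 1
  rows <- data.frame(
    hid = persons$hid,
    region = region,
    income = pcdi,
    insured_urrbmi = as.logical(insured),
    oop_inpatient = ifelse(is.na(persons$f2024), 0, persons$f2024) / div,
    reimb_inpatient = aggregate_reimbursement(persons, "inpatient") / div,
    oop_noninpatient = ifelse(is.na(persons$f2028), 0, persons$f2028) / div,
    reimb_noninpatient = aggregate_reimbursement(persons, "noninpatient") / div,
    expense_inpatient = persons$f2024,
    expense_noninpatient = persons$f2028,
    stringsAsFactors = FALSE
  )

  keep <- !is.na(rows$income)
  drop$negative_household_income <- sum(!keep)
  rows <- rows[keep, ]

  if (config$sample == "urrbmi") {
    keep <- rows$insured_urrbmi
    drop$not_urrbmi_enrolled <- sum(!keep)
    rows <- rows[keep, ]
  }

  # income left after out-of-pocket payment must stay non-negative for the
  # Lorenz ranking to be meaningful
  keep <- rows$income - rows$oop_inpatient >= 0 &
    rows$income - rows$oop_noninpatient >= 0
  drop$oop_exceeds_income <- sum(!keep)
  rows <- rows[keep, ]

  if (!nrow(rows)) stop("no records remain after exclusions", call. = FALSE)
  rows$bracket_inpatient <- tryCatch(
    tercile_brackets(rows$expense_inpatient),
    error = function(e) factor(rep(NA_character_, nrow(rows)),
                               levels = c("low", "medium", "high"),
                               ordered = TRUE)
  )
  rows$bracket_noninpatient <- tryCatch(
    tercile_brackets(rows$expense_noninpatient),
    error = function(e) factor(rep(NA_character_, nrow(rows)),
                               levels = c("low", "medium", "high"),
                               ordered = TRUE)
  )
  rows$expense_inpatient <- rows$expense_noninpatient <- NULL

  attr(rows, "drop_log") <- data.frame(
    reason = names(drop),
    n = unlist(drop, use.names = FALSE)
  )
  attr(rows, "n_negative_households") <- n_neg_hh
  attr(rows, "n_input") <- n_in
  rownames(rows) <- NULL
  rows
}

#' Before/after-reimbursement inequality by stratum
#'
#' For each stratum, computes the Gini coefficient of disposable income
#' after out-of-pocket payment (`income - oop`), the Gini after the scheme
#' reimbursement is added back (`income - oop + reimb`), and the MT index
#' (their difference). Strata are the national sample, the four
#' macro-regions, or the three expenditure terciles of the chosen channel
#' (bracketed strata keep only rows with a positive reported expense).
#'
#' @param rows analysis rows from [build_analysis_rows()].
#' @param stratifier `"national"`, `"region"` or `"bracket"`.
#' @param channel `"inpatient"` or `"noninpatient"`; selects which expense,
#'   reimbursement and bracket columns are used.
#' @param unit `"person"` (each row one observation) or `"household"`
#'   (collapse to households: per-capita income with household-summed
#'   expense and reimbursement spread over members).
#' @return Data frame with columns `stratum`, `n`, `gini_before`,
#'   `gini_after`, `mt`. A stratum with fewer than 2 usable observations is
#'   reported with `NA` indices, not zero.
#' @export
redistribution_by_stratum <- function(rows,
                                      stratifier = c("national", "region",
                                                     "bracket"),
                                      channel = c("inpatient",
                                                  "noninpatient"),
                                      unit = c("person", "household")) {
  stratifier <- match.arg(stratifier)
  channel <- match.arg(channel)
  unit <- match.arg(unit)
  oop <- rows[[paste0("oop_", channel)]]
  reimb <- rows[[paste0("reimb_", channel)]]
  bracket <- rows[[paste0("bracket_", channel)]]

  d <- data.frame(hid = rows$hid, income = rows$income, oop = oop,
                  reimb = reimb, region = rows$region, bracket = bracket)
  if (unit == "household") {
    d <- do.call(rbind, lapply(split(d, d$hid), function(g) {
      data.frame(hid = g$hid[1], income = g$income[1],
                 oop = sum(g$oop) / nrow(g), reimb = sum(g$reimb) / nrow(g),
                 region = g$region[1],
                 bracket = if (all(is.na(g$bracket))) g$bracket[1] else
                   max(g$bracket, na.rm = TRUE))
    }))
  }

  strata <- switch(stratifier,
    national = list(national = d),
    region = split(d, d$region),
    bracket = split(d[!is.na(d$bracket), ], d$bracket[!is.na(d$bracket)])
  )
  res <- do.call(rbind, lapply(names(strata), function(nm) {
    g <- strata[[nm]]
    before <- g$income - g$oop
    after <- before + g$reimb
    ok <- nrow(g) >= 2 && sum(before) > 0 && all(before >= 0)
    data.frame(
      stratum = nm, n = nrow(g),
      gini_before = if (ok) gini_grouped(before) else NA_real_,
      gini_after = if (ok) gini_grouped(after) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  res$mt <- res$gini_before - res$gini_after
  rownames(res) <- NULL
  res
}

#' Full survey redistribution analysis
#'
#' Convenience wrapper: builds analysis rows and computes the national,
#' regional and bracketed before/after-reimbursement inequality tables for
#' both the inpatient and non-inpatient channels.
#'
#' @inheritParams build_analysis_rows
#' @return A list with elements `national`, `by_region` (both inpatient
#'   channel), `by_bracket_inpatient`, `by_bracket_noninpatient`,
#'   `drop_log`, `n_input`, `n_analyzed`.
#' @export
analyze_survey <- function(persons, config = survey_config()) {
  rows <- build_analysis_rows(persons, config)
  list(
    national = redistribution_by_stratum(rows, "national", "inpatient",
                                         config$unit),
    by_region = redistribution_by_stratum(rows, "region", "inpatient",
                                          config$unit),
    by_bracket_inpatient =
      redistribution_by_stratum(rows, "bracket", "inpatient", config$unit),
    by_bracket_noninpatient =
      redistribution_by_stratum(rows, "bracket", "noninpatient", config$unit),
    drop_log = attr(rows, "drop_log"),
    n_input = attr(rows, "n_input"),
    n_analyzed = nrow(rows)
  )
}
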