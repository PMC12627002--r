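#' Read a theoretical-model calibration from a YAML or JSON config
#'
#' Accepted fields: `w_r`, `quintile_multipliers`, `bracket_multipliers`,
#' a nested `schedule` block (see [read_policy_schedule()]) and an optional
#' `probabilities` 5 x 5 matrix (rows = brackets, columns = quintiles).
#' Omitted fields fall back to the default calibration.
#'
#' @param path path to the config file.
#' @return A list with elements `calibration` ([urrbmi_calibration()]) and
#'   `probs` ([expenditure_probabilities()] matrix).
#' @export
read_calibration <- function(path) {
  cfg <- read_config_file(path)
  w_r <- cfg$w_r %||% 1
  schedule <- NULL
  if (!is.null(cfg$schedule)) {
    s <- cfg$schedule
    schedule <- policy_schedule(s$premium, s$deductible, s$coinsurance_rate,
                                s$ceiling, label = s$label %||% "config",
                                units = s$units %||% "w_r")
  }
  cal <- urrbmi_calibration(
    w_r = w_r,
    quintile_multipliers = unlist(cfg$quintile_multipliers) %||%
      c(0.3, 0.6, 1, 2, 3),
    bracket_multipliers = unlist(cfg$bracket_multipliers) %||%
      c(0.02, 0.08, 0.14, 0.20, 0.26),
    schedule = schedule
  )
  probs <- if (is.null(cfg$probabilities)) {
    expenditure_probabilities()
  } else {
    expenditure_probabilities(
      matrix(unlist(cfg$probabilities), 5, 5, byrow = TRUE)
    )
  }
  list(calibration = cal, probs = probs)
}

# Machine-readable provenance written next to every run's outputs.
write_provenance <- function(dir, kind, params) {
  prov <- list(
    tool = "urrbmi",
    version = as.character(utils::packageVersion("urrbmi")),
    kind = kind,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params
  )
  jsonlite::write_json(prov, file.path(dir, paste0(kind, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(prov)
}

#' Run the theoretical microsimulation and write its table set
#'
#' Writes `table3.csv` ... `table6.csv` (the four published-format result
#' tables), a JSON summary, a provenance block, and — for the default
#' calibration — a pass/fail comparison of every Gini, MT and RMT value
#' against the published benchmarks ([reference_tables()]), at the printed
#' precision.
#'
#' @param out_dir output directory.
#' @param config optional path to a calibration config
#'   (see [read_calibration()]); default calibration when `NULL`.
#' @return Invisibly, a list with the tables and (for the default
#'   calibration) the comparison data frame; `comparison$pass` is all
#'   `TRUE` on a correct build.
#' @export
run_theory <- function(out_dir, config = NULL) {
  if (is.null(config)) {
    cal <- urrbmi_calibration()
    probs <- expenditure_probabilities()
    is_default <- TRUE
  } else {
    cc <- read_calibration(config)
    cal <- cc$calibration
    probs <- cc$probs
    is_default <- identical(cal$quintile_multipliers, c(0.3, 0.6, 1, 2, 3)) &&
      identical(cal$bracket_multipliers, c(0.02, 0.08, 0.14, 0.20, 0.26)) &&
      isTRUE(all.equal(unname(probs), unname(expenditure_probabilities()))) &&
      cal$schedule$premium == 0.01 * cal$w_r &&
      cal$schedule$deductible == 0.02 * cal$w_r &&
      cal$schedule$coinsurance_rate == 0.78
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- emit_tables(cal, probs, out_dir)
  comparison <- NULL
  if (is_default) {
    ref <- reference_tables()
    got <- c(
      gini_initial = tabs$insured_stages$gini[1],
      gini_after_premium = tabs$insured_stages$gini[2],
      gini_after_oop = tabs$insured_stages$gini[3:7],
      gini_after_reimb = tabs$insured_stages$gini[8:12],
      mt_scenario1 = tabs$scenario1$mt,
      rmt_scenario1 = round(tabs$scenario1$rmt_percent, 2),
      gini_uninsured = tabs$uninsured_stages$gini[2:6],
      mt_scenario2 = tabs$scenario2$mt
    )
    want <- unlist(ref)
    names(want) <- names(got)
    comparison <- data.frame(
      quantity = names(got), computed = unname(got), reference = unname(want),
      pass = abs(unname(got) - unname(want)) < 5e-5
    )
    utils::write.csv(comparison, file.path(out_dir, "benchmark_comparison.csv"),
                     row.names = FALSE)
    message(sprintf("benchmark comparison: %d/%d values match",
                    sum(comparison$pass), nrow(comparison)))
  }
  write_provenance(out_dir, "theory",
                   list(w_r = cal$w_r,
                        quintile_multipliers = cal$quintile_multipliers,
                        bracket_multipliers = cal$bracket_multipliers,
                        schedule = unclass(cal$schedule)))
  invisible(list(tables = tabs, comparison = comparison))
}

#' Generate a synthetic survey from a config and write it to disk
#'
#' Writes the survey CSV, the truth-sheet JSON and a provenance block.
#'
#' @param out_csv path for the survey CSV.
#' @param truth_json path for the truth-sheet JSON.
#' @param config optional path to a generator config file overriding
#'   [generator_config()] defaults field by field; or a `generator_config`
#'   object.
#' @param seed optional seed overriding the config's.
#' @return Invisibly, the [simulate_survey()] result.
#' @export
run_simulate <- function(out_csv, truth_json = NULL, config = NULL,
                         seed = NULL) {
  gc_args <- list()
  if (is.character(config)) {
    gc_args <- read_config_file(config)
    for (nm in c("region_shares", "income_meanlog", "income_sdlog",
                 "urrbmi_rate")) {
      if (!is.null(gc_args[[nm]])) gc_args[[nm]] <- unlist(gc_args[[nm]])
    }
    if (!is.null(gc_args$schedule)) {
      s <- gc_args$schedule
      gc_args$schedule <- policy_schedule(
        s$premium, s$deductible, s$coinsurance_rate, s$ceiling,
        label = s$label %||% "config", units = s$units %||% "rmb")
    }
    cfg <- do.call(generator_config, gc_args)
  } else if (inherits(config, "generator_config")) {
    cfg <- config
  } else {
    cfg <- generator_config()
  }
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
  }
  sim <- write_synthetic_survey(cfg, out_csv, truth_json)
  write_provenance(dirname(out_csv), "simulate",
                   list(seed = cfg$seed, n_households = cfg$n_households,
                        expense_gradient = cfg$expense_gradient,
                        urrbmi_rate = as.list(cfg$urrbmi_rate)))
  invisible(sim)
}

#' Analyze a survey CSV and write the redistribution tables
#'
#' Reads a person-level survey CSV in the pipeline schema, runs
#' [analyze_survey()], and writes the national/regional table, the two
#' bracketed tables, the exclusion log and a provenance block.
#'
#' @param in_csv input survey CSV.
#' @param out_dir output directory.
#' @param config a [survey_config()] or a path to a YAML/JSON file with its
#'   fields.
#' @return Invisibly, the [analyze_survey()] result list.
#' @export
run_analyze <- function(in_csv, out_dir, config = survey_config()) {
  if (is.character(config)) {
    cc <- read_config_file(config)
    config <- survey_config(
      unit = cc$unit %||% "person",
      attach = cc$attach %||% "person",
      sample = cc$sample %||% "all",
      unemployment_flat = cc$unemployment_flat %||% 230
    )
  }
  persons <- utils::read.csv(in_csv, stringsAsFactors = FALSE)
  if (!nrow(persons)) stop("no records in ", in_csv, call. = FALSE)
  res <- analyze_survey(persons, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  national_regional <- rbind(
    res$national,
    res$by_region
  )
  utils::write.csv(national_regional,
                   file.path(out_dir, "redistribution_national_regional.csv"),
                   row.names = FALSE)
  utils::write.csv(res$by_bracket_inpatient,
                   file.path(out_dir, "redistribution_brackets_inpatient.csv"),
                   row.names = FALSE)
  utils::write.csv(res$by_bracket_noninpatient,
                   file.path(out_dir,
                             "redistribution_brackets_noninpatient.csv"),
                   row.names = FALSE)
  utils::write.csv(res$drop_log, file.path(out_dir, "exclusion_log.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    res[c("national", "by_region", "by_bracket_inpatient",
          "by_bracket_noninpatient", "n_input", "n_analyzed")],
    file.path(out_dir, "analysis_summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_provenance(out_dir, "analyze", unclass(config))
  invisible(res)
}
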