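# One-call pipeline: validate -> filter -> classify -> aggregate -> growth
# -> decompose -> benchmark/outliers, with an attrition log and a
# deterministic CSV/JSON output bundle.

#' Pipeline run configuration
#'
#' @param panel a `fin_panel`, or `NULL` to read from `panel_path`.
#' @param panel_path CSV panel path (used when `panel` is `NULL`).
#' @param classification classification data frame, or `NULL` to read from
#'   `classification_path`.
#' @param classification_path classification CSV path.
#' @param out_dir output directory for the report bundle; `NULL` for an
#'   in-memory bundle only.
#' @param criteria a [inclusion_criteria()] object.
#' @param base_year,end_year anchor years of the analysis window.
#' @param focus_countries iso3 codes broken out as singleton/complement
#'   reporting groups.
#' @param abuja_threshold,gdp_threshold benchmark thresholds (fractions).
#' @param outlier_lower,outlier_upper percentile bounds for the outlier
#'   screen.
#' @param identity_tolerance,error_tolerance CHE-identity tolerances for
#'   validation.
#' @param pc_scale per-capita scale factor (1e6 when monetary columns are
#'   millions and population persons, giving US$ per person).
#' @return list of class `fin_run_config`.
#' @export
run_config <- function(panel = NULL, panel_path = NULL,
                       classification = NULL, classification_path = NULL,
                       out_dir = NULL,
                       criteria = inclusion_criteria(),
                       base_year = 2000L, end_year = 2015L,
                       focus_countries = character(),
                       abuja_threshold = 0.15, gdp_threshold = 0.05,
                       outlier_lower = 0.01, outlier_upper = 0.99,
                       identity_tolerance = 0.01, error_tolerance = 0.05,
                       pc_scale = 1e6) {
  if (is.null(panel) && is.null(panel_path)) {
    abort("run_config needs a panel or a panel_path")
  }
  if (is.null(classification) && is.null(classification_path)) {
    abort("run_config needs a classification table or path")
  }
  structure(
    list(panel = panel, panel_path = panel_path,
         classification = classification,
         classification_path = classification_path,
         out_dir = out_dir, criteria = criteria,
         base_year = as.integer(base_year), end_year = as.integer(end_year),
         focus_countries = focus_countries,
         abuja_threshold = abuja_threshold, gdp_threshold = gdp_threshold,
         outlier_lower = outlier_lower, outlier_upper = outlier_upper,
         identity_tolerance = identity_tolerance,
         error_tolerance = error_tolerance,
         pc_scale = pc_scale),
    class = "fin_run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes validation, cohort filtering, income grouping, aggregation,
#' growth metrics, the GGHE-D decomposition, benchmark flags and the
#' outlier screen in order, collecting everything into a report bundle.
#' The run log records country counts at each attrition stage. Validation
#' errors abort the run. With an `out_dir`, the bundle is written as CSV
#' tables and JSON reports with fixed column order, so identical inputs
#' give identical files.
#'
#' @param config a [run_config()].
#' @return list of class `fin_report_bundle`: validation, exclusions,
#'   assignment, composition, per_capita_table, growth_levels,
#'   growth_ratios, decomposition, benchmarks, country_weighted,
#'   outliers, log (character vector), config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fin_run_config"))
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  panel <- if (is.null(config$panel)) {
    read_panel(config$panel_path)
  } else {
    config$panel
  }
  classification <- if (is.null(config$classification)) {
    read_classification(config$classification_path)
  } else {
    config$classification
  }
  say("stage validate: ", length(unique(panel$iso3)), " countries, ",
      nrow(panel), " records")
  validation <- validate_panel(panel,
                               identity_tolerance = config$identity_tolerance,
                               error_tolerance = config$error_tolerance)
  if (!validation$accepted) {
    abort(paste0("pipeline aborted at stage validate: ",
                 sum(validation$findings$severity == "error"),
                 " error-level finding(s)"))
  }
  exclusions <- apply_inclusion_filters(panel, config$criteria)
  included <- included_countries(exclusions)
  n_total <- nrow(exclusions$decisions)
  n_after_pop <- n_total - sum(exclusions$decisions$decision ==
                                 "excluded_small_population")
  say("stage filter: ", n_total, " -> ", n_after_pop,
      " after population rule -> ", length(included),
      " after missing-data rule")
  assignment <- assign_income_groups(exclusions, classification,
                                     focus_countries = config$focus_countries)
  say("stage classify: ", length(reporting_groups(assignment)),
      " reporting groups (", length(assignment$base_groups), " base + ",
      2 * length(config$focus_countries), " breakout)")

  anchor_years <- c(config$base_year, config$end_year)
  income_groups <- setdiff(assignment$base_groups, "UNCLASSIFIED")
  agg_groups <- unique(c(income_groups,
                         setdiff(reporting_groups(assignment),
                                 assignment$base_groups)))
  composition <- composition_shares(panel, assignment, years = anchor_years,
                                    groups = agg_groups)
  say("stage aggregate: composition for ", length(agg_groups), " groups")
  pc_tab <- growth_table(panel, assignment, config$base_year,
                         config$end_year,
                         per_capita_of = c("che", "gghe_d", "ext", "oop"),
                         pc_scale = config$pc_scale, groups = agg_groups)
  growth_levels <- growth_table(panel, assignment, config$base_year,
                                config$end_year,
                                levels = c("population", "gdp", "gge",
                                           "che", "oop", "gghe_d"),
                                groups = agg_groups)
  growth_ratios <- growth_table(panel, assignment, config$base_year,
                                config$end_year,
                                ratios = list(c("gghe_d", "gdp"),
                                              c("gghe_d", "gge"),
                                              c("gghe_d", "che"),
                                              c("oop", "che")),
                                per_capita_of = c("gdp", "gge", "gghe_d",
                                                  "che"),
                                pc_scale = config$pc_scale,
                                groups = agg_groups)
  say("stage growth: level and ratio tables for ", length(agg_groups),
      " groups")
  decomposition <- group_decomposition(panel, assignment, config$base_year,
                                       config$end_year, groups = agg_groups)
  say("stage decompose: max |residual| ",
      format(max(abs(decomposition$residual_nats)), digits = 3), " nats")
  benchmarks <- benchmark_flags(panel, assignment, years = anchor_years,
                                abuja_threshold = config$abuja_threshold,
                                gdp_threshold = config$gdp_threshold)
  benchmarks <- benchmarks[benchmarks$entity %in% agg_groups, ]
  country_weighted <- dplyr::bind_rows(
    country_weighted_average(panel, assignment, "che", "population",
                             years = anchor_years, groups = agg_groups),
    country_weighted_average(panel, assignment, "gghe_d", "population",
                             years = anchor_years, groups = agg_groups)
  )
  country_weighted$value <- country_weighted$value * config$pc_scale
  outliers <- if (length(included) >= 10) {
    flag_outliers(panel, "gghe_d", "gdp", years = anchor_years,
                  countries = included, lower = config$outlier_lower,
                  upper = config$outlier_upper)
  } else {
    NULL
  }
  say("stage benchmark/outlier: ", nrow(benchmarks), " benchmark rows, ",
      if (is.null(outliers)) "outlier screen skipped (under 10 countries)"
      else paste0(nrow(outliers$flagged), " outlier flags"))

  bundle <- structure(
    list(validation = validation, exclusions = exclusions,
         assignment = assignment, composition = composition,
         per_capita_table = pc_tab, growth_levels = growth_levels,
         growth_ratios = growth_ratios, decomposition = decomposition,
         benchmarks = benchmarks, country_weighted = country_weighted,
         outliers = outliers, log = log_lines, config = config),
    class = "fin_report_bundle"
  )
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
  }
  bundle
}

#' Write a report bundle to a directory
#'
#' @param bundle a `fin_report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(dir, name)
  write_exclusions(bundle$exclusions, json_path = out("exclusions.json"),
                   csv_path = out("exclusions.csv"))
  readr::write_csv(bundle$composition, out("composition.csv"), na = "")
  readr::write_csv(bundle$per_capita_table, out("per_capita.csv"), na = "")
  readr::write_csv(bundle$growth_levels, out("growth_levels.csv"), na = "")
  readr::write_csv(bundle$growth_ratios, out("growth_ratios.csv"), na = "")
  readr::write_csv(bundle$decomposition, out("decomposition.csv"), na = "")
  readr::write_csv(bundle$benchmarks, out("benchmarks.csv"), na = "")
  readr::write_csv(bundle$country_weighted, out("country_weighted.csv"),
                   na = "")
  if (!is.null(bundle$outliers)) {
    readr::write_csv(bundle$outliers$flagged, out("outliers.csv"), na = "")
  }
  writeLines(bundle$log, out("run_log.txt"))
  cfg <- bundle$config
  echo <- cfg[setdiff(names(cfg), c("panel", "classification"))]
  echo$criteria <- unclass(echo$criteria)
  jsonlite::write_json(echo, out("config_echo.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.fin_report_bundle <- function(x, ...) {
  cat("Health-financing report bundle\n")
  for (line in x$log) cat("  ", line, "\n", sep = "")
  invisible(x)
}
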