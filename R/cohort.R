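#' Inclusion criteria for the analysis cohort
#'
#' The defaults encode the study design used throughout the package: keep a
#' country when (i) its population in the reference year is at least
#' `pop_threshold` persons and (ii) every required indicator is present in
#' every anchor year. The population rule is checked first; a country
#' failing both is reported under the population rule.
#'
#' @param pop_threshold minimum population, persons (default 600,000). A
#'   country at exactly the threshold is included.
#' @param pop_reference_year year in which population is tested
#'   (default 2015).
#' @param required_indicators indicators that must be present in every
#'   anchor year (default GDP, GGE, GGHE-D, CHE, OOP).
#' @param anchor_years years in which the indicators must be present
#'   (default 2000 and 2015).
#' @return A list of class `fin_criteria`.
#' @export
inclusion_criteria <- function(pop_threshold = 600000,
                               pop_reference_year = 2015,
                               required_indicators = c("gdp", "gge", "gghe_d",
                                                       "che", "oop"),
                               anchor_years = c(2000L, 2015L)) {
  stopifnot(pop_threshold > 0, length(anchor_years) >= 1)
  known <- c("population", panel_monetary_cols())
  unknown <- setdiff(required_indicators, known)
  if (length(unknown) > 0) {
    abort(paste0("unknown indicator(s) in criteria: ",
                 paste(unknown, collapse = ", ")))
  }
  structure(
    list(pop_threshold = pop_threshold,
         pop_reference_year = as.integer(pop_reference_year),
         required_indicators = required_indicators,
         anchor_years = as.integer(anchor_years)),
    class = "fin_criteria"
  )
}

#' Apply inclusion criteria to a panel
#'
#' Produces a deterministic per-country decision:
#' `included`, `excluded_small_population` (population below threshold or
#' missing in the reference year), or `excluded_missing_data` (a required
#' indicator missing in an anchor year). The decision is reproducible from
#' the panel and criteria alone; input row order is irrelevant.
#'
#' @param panel a `fin_panel`.
#' @param criteria a `fin_criteria` object, see [inclusion_criteria()].
#' @return An object of class `fin_exclusions`: a list with `decisions`
#'   (tibble: iso3, decision, population_ref, missing — list-column of
#'   "indicator@year" strings), `counts`, and the criteria used.
#' @export
apply_inclusion_filters <- function(panel, criteria = inclusion_criteria()) {
  if (!criteria$pop_reference_year %in% panel$year) {
    abort(paste0("panel contains no record for the population reference year ",
                 criteria$pop_reference_year))
  }
  countries <- sort(unique(panel$iso3))
  decisions <- purrr::map(countries, function(cc) {
    rows <- panel[panel$iso3 == cc, ]
    pop_row <- rows[rows$year == criteria$pop_reference_year, ]
    pop <- if (nrow(pop_row) == 1) pop_row$population else NA_real_
    if (is.na(pop)) {
      return(tibble::tibble(iso3 = cc, decision = "excluded_small_population",
                            population_ref = NA_real_,
                            missing = list(sprintf("population missing@%d",
                                                   criteria$pop_reference_year))))
    }
    if (pop < criteria$pop_threshold) {
      return(tibble::tibble(iso3 = cc, decision = "excluded_small_population",
                            population_ref = pop, missing = list(character())))
    }
    miss <- character()
    for (yr in criteria$anchor_years) {
      yr_row <- rows[rows$year == yr, ]
      for (ind in criteria$required_indicators) {
        v <- if (nrow(yr_row) == 1) yr_row[[ind]] else NA_real_
        if (is.na(v)) miss <- c(miss, paste0(ind, "@", yr))
      }
    }
    decision <- if (length(miss) > 0) "excluded_missing_data" else "included"
    tibble::tibble(iso3 = cc, decision = decision, population_ref = pop,
                   missing = list(miss))
  })
  decisions <- dplyr::bind_rows(decisions)
  counts <- decisions %>% dplyr::count(.data$decision)
  structure(
    list(decisions = decisions, counts = counts, criteria = criteria),
    class = "fin_exclusions"
  )
}

#' Countries retained by an exclusion report
#'
#' @param report a `fin_exclusions` object.
#' @return character vector of included iso3 codes, sorted.
#' @export
included_countries <- function(report) {
  report$decisions$iso3[report$decisions$decision == "included"]
}

#' @export
print.fin_exclusions <- function(x, ...) {
  cat("Cohort filter:", nrow(x$decisions), "countries ->",
      length(included_countries(x)), "included\n")
  print(x$counts)
  invisible(x)
}

#' Read a country to income-group classification table
#'
#' @param path CSV with columns `iso3`, `group` and optionally
#'   `classification_year`.
#' @return tibble with those columns.
#' @export
read_classification <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE, progress = FALSE)
  if (!all(c("iso3", "group") %in% names(tab))) {
    abort("classification table needs columns iso3 and group")
  }
  tab
}

#' Assign included countries to fixed income groups
#'
#' Countries are grouped by their income classification at the base year and
#' the groups are held constant across all analysis years. Beyond the base
#' partition (LIC, LMIC, UMIC, HIC, plus UNCLASSIFIED countries retained as
#' their own group), each focus country generates two reporting groups: a
#' singleton named by its iso3 code and a complement group
#' `"<base> excluding <iso3>"`, mirroring the large-economy breakouts used
#' when one country dominates its group.
#'
#' @param report a `fin_exclusions` object.
#' @param classification data frame with columns `iso3`, `group`
#'   (`LIC`/`LMIC`/`UMIC`/`HIC`/`UNCLASSIFIED`) and optionally
#'   `classification_year`.
#' @param focus_countries iso3 codes to break out (e.g. the group-dominating
#'   large economies). Each must be an included country in one of the four
#'   income groups.
#' @return An object of class `fin_groups` with `membership` (tibble:
#'   group, iso3, type in base/singleton/complement), `base_of` (named map
#'   iso3 -> base group), `base_groups`, `focus`, `classification_year`.
#' @export
assign_income_groups <- function(report, classification,
                                 focus_countries = character()) {
  included <- included_countries(report)
  classification <- tibble::as_tibble(classification)
  base_of <- stats::setNames(classification$group, classification$iso3)
  absent <- setdiff(included, names(base_of))
  if (length(absent) > 0) {
    abort(paste0("included countries missing from classification table: ",
                 paste(absent, collapse = ", ")))
  }
  base_of <- base_of[included]
  income_groups <- c("LIC", "LMIC", "UMIC", "HIC")
  bad_group <- setdiff(unique(base_of), c(income_groups, "UNCLASSIFIED"))
  if (length(bad_group) > 0) {
    abort(paste0("unknown income group label(s): ",
                 paste(bad_group, collapse = ", ")))
  }
  membership <- tibble::tibble(
    group = unname(base_of), iso3 = names(base_of), type = "base"
  )
  for (fc in focus_countries) {
    if (!fc %in% included) {
      abort(paste0("focus country ", fc, " is not an included country"))
    }
    fc_group <- unname(base_of[[fc]])
    if (!fc_group %in% income_groups) {
      abort(paste0("focus country ", fc,
                   " is not in one of the four income groups (found ",
                   fc_group, ")"))
    }
    complement <- setdiff(names(base_of)[base_of == fc_group], fc)
    membership <- dplyr::bind_rows(
      membership,
      tibble::tibble(group = fc, iso3 = fc, type = "singleton"),
      tibble::tibble(group = paste0(fc_group, " excluding ", fc),
                     iso3 = complement, type = "complement")
    )
  }
  cls_year <- if ("classification_year" %in% names(classification)) {
    suppressWarnings(as.integer(classification$classification_year[1]))
  } else {
    NA_integer_
  }
  structure(
    list(membership = membership,
         base_of = base_of,
         base_groups = intersect(c(income_groups, "UNCLASSIFIED"),
                                 unique(base_of)),
         focus = focus_countries,
         classification_year = cls_year),
    class = "fin_groups"
  )
}

#' Reporting groups of an assignment
#'
#' @param assignment a `fin_groups` object.
#' @param base_only if TRUE, only the base partition groups.
#' @return character vector of group labels in reporting order.
#' @export
reporting_groups <- function(assignment, base_only = FALSE) {
  if (base_only) {
    return(assignment$base_groups)
  }
  unique(assignment$membership$group)
}

#' Members of one reporting group
#'
#' @param assignment a `fin_groups` object.
#' @param group a group label, base or derived.
#' @return character vector of iso3 codes.
#' @export
group_members <- function(assignment, group) {
  m <- assignment$membership$iso3[assignment$membership$group == group]
  if (length(m) == 0 && !group %in% assignment$membership$group) {
    abort(paste0("unknown reporting group: ", group))
  }
  m
}

#' Write an exclusion report to JSON and CSV
#'
#' @param report a `fin_exclusions` object.
#' @param json_path,csv_path optional output paths.
#' @return the report, invisibly.
#' @export
write_exclusions <- function(report, json_path = NULL, csv_path = NULL) {
  flat <- report$decisions %>%
    dplyr::mutate(missing = purrr::map_chr(.data$missing, paste,
                                           collapse = ";"))
  if (!is.null(csv_path)) readr::write_csv(flat, csv_path, na = "")
  if (!is.null(json_path)) {
    obj <- list(
      criteria = unclass(report$criteria),
      counts = report$counts,
      decisions = flat
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
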