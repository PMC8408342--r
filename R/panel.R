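#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Canonical column sets for the long-format panel. All monetary columns share
# one unit scale declared at panel level (attribute "unit_scale").
panel_monetary_cols <- function() {
  c("gdp", "gge", "gghe_d", "che", "oop", "ext", "vpp", "pvt_other")
}

panel_required_cols <- function() {
  c("iso3", "year", "population", "gdp", "gge", "gghe_d", "che", "oop")
}

panel_optional_cols <- function() {
  c("name", "ext", "vpp", "pvt_other")
}

panel_all_cols <- function() {
  c("iso3", "name", "year", "population", panel_monetary_cols())
}

#' Construct a health-financing panel from a data frame
#'
#' A panel is a tibble in long format, one row per (iso3, year), carrying
#' population and the health-financing indicators (GDP, GGE, GGHE-D, CHE,
#' OOP, EXT, voluntary prepayment, other private) in a single declared unit
#' scale (constant dollars). Missing values are `NA`, never zero.
#'
#' @param df data frame with at least the required columns
#'   (`iso3`, `year`, `population`, `gdp`, `gge`, `gghe_d`, `che`, `oop`);
#'   optional columns `name`, `ext`, `vpp`, `pvt_other` are filled with
#'   `NA` when absent.
#' @param unit_scale character tag describing the monetary unit of all
#'   monetary columns, e.g. `"millions, constant 2010 US$"`.
#' @param provenance free-text description of where the data came from.
#' @return A tibble of class `fin_panel` with attributes `unit_scale`,
#'   `provenance` and `year_span`.
#' @export
as_fin_panel <- function(df, unit_scale = "millions, constant 2010 US$",
                         provenance = "unspecified") {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(panel_required_cols(), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in panel_optional_cols()) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "name") NA_character_ else NA_real_
    }
  }
  df$iso3 <- as.character(df$iso3)
  df$name <- as.character(df$name)
  df$year <- as.integer(df$year)
  for (col in c("population", panel_monetary_cols())) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df <- df[, panel_all_cols()]
  dup <- df %>%
    dplyr::count(.data$iso3, .data$year) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    keys <- paste0(dup$iso3, ":", dup$year, collapse = ", ")
    abort(paste0("duplicate (iso3, year) pairs in panel: ", keys))
  }
  structure(
    df,
    unit_scale = unit_scale,
    provenance = provenance,
    year_span = if (nrow(df) > 0) range(df$year) else c(NA_integer_, NA_integer_),
    class = c("fin_panel", class(df))
  )
}

#' Read a health-financing panel from CSV
#'
#' Reads a long-format CSV (one row per country-year, header row required)
#' into a [as_fin_panel()] panel. Blank cells and the tokens `NA` and `N/A`
#' become missing values, never zeros. Row order is preserved.
#'
#' @param path path to a UTF-8 CSV file.
#' @param column_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(gghe_d = "GGHE_D_millions")`. Unmapped columns are matched by name.
#' @param unit_scale,provenance passed to [as_fin_panel()]; `provenance`
#'   defaults to the file path.
#' @return A `fin_panel` tibble.
#' @export
read_panel <- function(path, column_map = NULL,
                       unit_scale = "millions, constant 2010 US$",
                       provenance = path) {
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      file_col <- column_map[[canon]]
      if (!file_col %in% names(raw)) {
        abort(paste0("column_map names column '", file_col,
                     "' which is absent from ", path))
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(panel_required_cols(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("panel file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  numeric_cols <- intersect(c("year", "population", panel_monetary_cols()),
                            names(raw))
  for (col in numeric_cols) {
    txt <- trimws(raw[[col]])
    txt[txt %in% c("", "NA", "N/A", "n/a")] <- NA_character_
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(val))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value in column '", col, "' at data row(s) ",
                   paste(utils::head(bad, 5), collapse = ", "),
                   " (e.g. '", txt[bad[1]], "')"))
    }
    raw[[col]] <- val
  }
  as_fin_panel(raw, unit_scale = unit_scale, provenance = provenance)
}

#' Write a panel to CSV
#'
#' Inverse of [read_panel()]: missing values are written as empty cells so
#' that a read/write round trip preserves all present values.
#'
#' @param panel a `fin_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(panel), path, na = "")
  invisible(path)
}

#' Validate a panel against its accounting identities
#'
#' Checks every record against the data-model invariants: non-negative
#' monetary values, positive population, OOP not exceeding CHE, GGHE-D not
#' exceeding GGE, GGE not exceeding GDP, and the CHE additivity identity
#' CHE = GGHE-D + EXT + OOP + VPP + other private (checked only when all
#' five components are present). The identity is a warning when the relative
#' gap exceeds `identity_tolerance` and an error when it exceeds
#' `error_tolerance`. The panel is never mutated and validation is
#' idempotent.
#'
#' @param panel a `fin_panel` with at least one record.
#' @param identity_tolerance relative CHE gap above which a warning finding
#'   is recorded (default 0.01).
#' @param error_tolerance relative CHE gap above which the finding is an
#'   error (default 0.05).
#' @return An object of class `fin_validation`: a list with `findings`
#'   (tibble: iso3, year, rule, severity, detail), `counts` (findings per
#'   rule), and `accepted` (TRUE iff no error-severity findings).
#' @export
validate_panel <- function(panel, identity_tolerance = 0.01,
                           error_tolerance = 0.05) {
  if (nrow(panel) == 0) {
    abort("cannot validate an empty panel")
  }
  stopifnot(identity_tolerance > 0, identity_tolerance < 1,
            error_tolerance >= identity_tolerance)
  findings <- list()
  add <- function(iso3, year, rule, severity, detail) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      iso3 = iso3, year = as.integer(year), rule = rule,
      severity = severity, detail = detail
    )
  }
  for (i in seq_len(nrow(panel))) {
    rec <- panel[i, ]
    for (col in panel_monetary_cols()) {
      v <- rec[[col]]
      if (!is.na(v) && v < 0) {
        add(rec$iso3, rec$year, "negative_value", "error",
            paste0(col, " = ", v))
      }
    }
    if (!is.na(rec$population) && rec$population <= 0) {
      add(rec$iso3, rec$year, "nonpositive_population", "error",
          paste0("population = ", rec$population))
    }
    if (!is.na(rec$oop) && !is.na(rec$che) && rec$oop > rec$che) {
      add(rec$iso3, rec$year, "oop_exceeds_che", "warning",
          paste0("oop ", rec$oop, " > che ", rec$che))
    }
    if (!is.na(rec$gghe_d) && !is.na(rec$gge) && rec$gghe_d > rec$gge) {
      add(rec$iso3, rec$year, "gghed_exceeds_gge", "warning",
          paste0("gghe_d ", rec$gghe_d, " > gge ", rec$gge))
    }
    if (!is.na(rec$gge) && !is.na(rec$gdp) && rec$gge > rec$gdp) {
      add(rec$iso3, rec$year, "gge_exceeds_gdp", "warning",
          paste0("gge ", rec$gge, " > gdp ", rec$gdp))
    }
    comp <- c(rec$gghe_d, rec$ext, rec$oop, rec$vpp, rec$pvt_other)
    if (!is.na(rec$che) && rec$che > 0 && !anyNA(comp)) {
      gap <- abs(rec$che - sum(comp)) / rec$che
      if (gap > identity_tolerance) {
        sev <- if (gap > error_tolerance) "error" else "warning"
        add(rec$iso3, rec$year, "che_identity", sev,
            sprintf("relative gap %.4g between che and component sum", gap))
      }
    }
  }
  findings <- if (length(findings) > 0) {
    dplyr::bind_rows(findings)
  } else {
    tibble::tibble(iso3 = character(), year = integer(), rule = character(),
                   severity = character(), detail = character())
  }
  counts <- findings %>% dplyr::count(.data$rule, .data$severity)
  structure(
    list(findings = findings, counts = counts,
         accepted = !any(findings$severity == "error"),
         identity_tolerance = identity_tolerance,
         error_tolerance = error_tolerance),
    class = "fin_validation"
  )
}

#' @export
print.fin_validation <- function(x, ...) {
  cat("Panel validation report\n")
  cat("  findings:", nrow(x$findings),
      sprintf("(errors: %d, warnings: %d)\n",
              sum(x$findings$severity == "error"),
              sum(x$findings$severity == "warning")))
  cat("  accepted for analysis:", x$accepted, "\n")
  if (nrow(x$counts) > 0) {
    print(x$counts)
  }
  invisible(x)
}

#' Write a validation report as JSON and text
#'
#' @param report a `fin_validation` object.
#' @param json_path optional path for the JSON form (stable key order).
#' @param text_path optional path for the human-readable form.
#' @return the report, invisibly.
#' @export
write_validation <- function(report, json_path = NULL, text_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      accepted = report$accepted,
      n_findings = nrow(report$findings),
      counts = report$counts,
      findings = report$findings
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(text_path)) {
    con <- file(text_path, open = "wt")
    on.exit(close(con))
    sink(con)
    print(report)
    if (nrow(report$findings) > 0) print(report$findings, n = Inf)
    sink()
  }
  invisible(report)
}
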