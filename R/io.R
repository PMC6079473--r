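COHORT_SCHEMA_VERSION <- "1.0"

#' The cohort CSV schema
#'
#' Canonical column names, types and units for per-subject records. Missing
#' values are empty fields (read as `NA`); unknown extra columns are
#' preserved on read but ignored by the pipeline.
#'
#' @return A tibble with columns `column`, `type`, `unit`, `required` and a
#'   `version` attribute.
#' @export
cohort_schema <- function() {
  out <- tibble::tribble(
    ~column, ~type, ~unit, ~required,
    "id", "integer", "", TRUE,
    "age", "double", "years", TRUE,
    "sex", "character", "male|female", TRUE,
    "race_black", "integer", "0/1", TRUE,
    "height_cm", "double", "cm", TRUE,
    "weight_kg", "double", "kg", TRUE,
    "waist_cm", "double", "cm", TRUE,
    "hip_cm", "double", "cm", TRUE,
    "sbp_mmhg", "double", "mmHg", TRUE,
    "dbp_mmhg", "double", "mmHg", TRUE,
    "bp_meds", "integer", "0/1", TRUE,
    "tg_mg_dl", "double", "mg/dL (fasting)", TRUE,
    "hdl_mg_dl", "double", "mg/dL", TRUE,
    "glu_mg_dl", "double", "mg/dL (fasting)", TRUE,
    "diabetes_pills", "integer", "0/1", TRUE,
    "pregnant", "integer", "0/1", FALSE,
    "followup_years", "double", "years", TRUE,
    "died", "integer", "0/1", TRUE,
    "sample_weight", "double", "relative", FALSE,
    "training", "integer", "0/1", FALSE
  )
  attr(out, "version") <- COHORT_SCHEMA_VERSION
  out
}

#' Read and write cohort CSV files
#'
#' [read_cohort()] parses and validates a cohort file against
#' [cohort_schema()] and, by default, applies the standard exclusion rules
#' via [filter_cohort()]. [write_cohort()] writes all columns; reading back
#' a written cohort reproduces it exactly.
#'
#' @param path CSV file path.
#' @param apply_filters Apply cohort exclusion rules (default `TRUE`).
#' @param data Cohort data frame.
#' @return [read_cohort()]: the cohort tibble, with the exclusion accounting
#'   (see [filter_report()]) attached when filtered. [write_cohort()]:
#'   `path`, invisibly.
#' @export
read_cohort <- function(path, apply_filters = TRUE) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  sch <- cohort_schema()
  known_types <- setNames(
    vapply(sch$type, function(tp) switch(tp, integer = "i", double = "d",
                                         character = "c"), character(1)),
    sch$column
  )
  header <- names(suppressMessages(readr::read_csv(path, n_max = 0,
                                                   show_col_types = FALSE)))
  known_types <- known_types[intersect(names(known_types), header)]
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = do.call(readr::cols,
                                        c(as.list(known_types),
                                          list(.default = "?")))),
    error = function(e) abort(paste0("failed to parse ", path, ": ", conditionMessage(e)))
  )
  if (nrow(out) == 0) abort(paste0("cohort file is empty: ", path))
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    abort(paste0("malformed rows in ", path, " (first at line ", prob$row[1], "): ",
                 prob$expected[1], " expected, got ", prob$actual[1]))
  }
  required <- sch$column[sch$required]
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(out), sch$column)
  extra <- extra[!grepl("^true_", extra)]
  if (length(extra) > 0) {
    inform(paste0("preserving unknown column(s): ", paste(extra, collapse = ", ")))
  }
  check_sex(out$sex)
  if (apply_filters) out <- filter_cohort(out)
  out
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' Apply the standard cohort exclusion rules
#'
#' Exclusions, applied in this fixed order (a record is counted against the
#' first rule it violates): (1) age under 18; (2) pregnant; (3) missing or
#' implausibility-flagged anthropometrics; (4) missing metabolic-syndrome
#' inputs (any unscoreable component); (5) missing mortality follow-up
#' (`followup_years` or `died` absent, or nonpositive follow-up). The
#' accounting is attached as the `filter_report` attribute and retrievable
#' with [filter_report()].
#'
#' @param data Cohort tibble.
#' @return The retained records, with a `filter_report` attribute.
#' @export
filter_cohort <- function(data) {
  data <- as_tibble(data)
  n_in <- nrow(data)
  idx <- add_anthro_indices(data)
  scored <- suppressWarnings(score_ms(idx))
  anthro_missing <- !complete.cases(data[c("height_cm", "weight_kg", "waist_cm", "hip_cm")]) |
    !is.na(idx$anthro_flag)
  ms_missing <- !complete.cases(
    scored[c("ms_waist", "ms_bp", "ms_tg", "ms_hdl", "ms_glu")]
  )
  mort_missing <- is.na(data$followup_years) | is.na(data$died) |
    (!is.na(data$followup_years) & data$followup_years <= 0)
  preg <- if ("pregnant" %in% names(data)) !is.na(data$pregnant) & data$pregnant == 1 else
    rep(FALSE, n_in)

  reason <- rep(NA_character_, n_in)
  rules <- list(
    under_18 = is.na(data$age) | data$age < 18,
    pregnant = preg,
    missing_anthro = anthro_missing,
    missing_ms_inputs = ms_missing,
    missing_mortality = mort_missing
  )
  for (rl in names(rules)) {
    hit <- rules[[rl]] & is.na(reason)
    reason[hit] <- rl
  }
  keep <- is.na(reason)
  report <- tibble(
    rule = names(rules),
    excluded = unname(vapply(names(rules),
                             function(rl) sum(reason == rl, na.rm = TRUE),
                             integer(1)))
  )
  attr(report, "n_input") <- n_in
  attr(report, "n_retained") <- sum(keep)
  out <- data[keep, ]
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_cohort
#' @param cohort A cohort returned by [filter_cohort()] or [read_cohort()].
#' @export
filter_report <- function(cohort) {
  attr(cohort, "filter_report")
}

#' Rename and recode an external extract to the cohort schema
#'
#' Column-mapping adapter for externally extracted survey CSVs (e.g. NHANES
#' III variables exported to CSV): renames source columns to the canonical
#' schema, recodes sex, and converts follow-up given in months. The map can
#' be a named list (`canonical = "SOURCE_COLUMN"`, plus optional `sex_codes`
#' named vector such as `c("1" = "male", "2" = "female")` and
#' `followup_unit = "months"`), or a path to a YAML file with those keys
#' under `columns`, `sex_codes`, `followup_unit`.
#'
#' @param data Source data frame.
#' @param map Named list or YAML path as described above.
#' @return Tibble in the cohort schema (validate with [filter_cohort()]).
#' @export
apply_column_map <- function(data, map) {
  if (is.character(map) && length(map) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML column map requires the yaml package")
    }
    map <- yaml::read_yaml(map)
  }
  columns <- map$columns %||% map[setdiff(names(map), c("sex_codes", "followup_unit"))]
  out <- as_tibble(data)
  for (canonical in names(columns)) {
    src <- columns[[canonical]]
    if (!src %in% names(out)) {
      abort(paste0("mapped source column not found: ", src, " (for ", canonical, ")"))
    }
    out[[canonical]] <- out[[src]]
  }
  if (!is.null(map$sex_codes)) {
    codes <- unlist(map$sex_codes)
    out$sex <- unname(codes[as.character(out$sex)])
  }
  if (identical(map$followup_unit, "months") && "followup_years" %in% names(out)) {
    out$followup_years <- out$followup_years / 12
  }
  out
}
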