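# CSV schema for case records: one row per surgical candidate, header names
# matching the case-record fields. Files are RFC-4180, UTF-8, "." decimal;
# lines starting with '#' are metadata comments.

case_columns <- function() {
  list(
    character = c("case_id", "site_id", "menopausal_status", "race_ethnicity",
                  "lung_disease", "smoking_status", "osa_status",
                  "cardiovascular_disease", "diabetes_status",
                  "diabetes_end_organ", "covid_status", "expected_los",
                  "icu_need", "least_invasive_anesthesia",
                  "surgical_site_approach", "nonoperative_effectiveness",
                  "nonoperative_resource_use", "delay_impact_3_6mo",
                  "delay_impact_gt6mo", "indication",
                  "planned_procedure_class", "acuity_tier"),
    numeric = c("age", "bmi", "hba1c", "expected_or_time"),
    integer = "parity",
    logical = "immunocompromised"
  )
}

# columns a rubric scoring run cannot do without; the rest are optional
required_case_columns <- function() {
  c("case_id", "site_id", "age", "bmi", "parity", "menopausal_status",
    "race_ethnicity", "lung_disease", "smoking_status", "osa_status",
    "cardiovascular_disease", "diabetes_status", "immunocompromised",
    "covid_status", "expected_or_time", "expected_los", "icu_need",
    "least_invasive_anesthesia", "surgical_site_approach",
    "nonoperative_effectiveness", "nonoperative_resource_use",
    "delay_impact_3_6mo", "delay_impact_gt6mo", "indication",
    "planned_procedure_class")
}

case_col_types <- function() {
  cc <- case_columns()
  spec <- c(
    stats::setNames(rep(list(readr::col_character()), length(cc$character)),
                    cc$character),
    stats::setNames(rep(list(readr::col_double()), length(cc$numeric)),
                    cc$numeric),
    stats::setNames(list(readr::col_integer()), cc$integer),
    stats::setNames(list(readr::col_logical()), cc$logical)
  )
  do.call(readr::cols, c(spec, .default = list(readr::col_character())))
}

abort_parse_problems <- function(df, path) {
  probs <- readr::problems(df)
  if (nrow(probs)) {
    p <- probs[1, ]
    col_name <- if (!is.na(p$col) && p$col <= ncol(df)) names(df)[p$col] else p$col
    rlang::abort(paste0(
      "cannot parse '", path, "': row ", p$row - 1L, ", column '", col_name,
      "': expected ", p$expected, ", got '", p$actual, "'"),
      class = "mentsr_io_error")
  }
  invisible(df)
}

#' Read case records from CSV
#'
#' Reads and type-checks a case-record file against the documented schema.
#' Missing required columns and unparseable cells are errors carrying the
#' column name and row number; unknown extra columns are kept with a warning.
#'
#' @param path CSV path (metadata comment lines starting `#` are skipped).
#' @return A case-record tibble.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("case file not found: ", path),
                 class = "mentsr_io_error")
  }
  header <- names(readr::read_csv(path, comment = "#", n_max = 0,
                                  show_col_types = FALSE))
  missing <- setdiff(required_case_columns(), header)
  if (length(missing)) {
    rlang::abort(paste0("case file '", path, "' lacks required column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mentsr_io_error")
  }
  unknown <- setdiff(header, unlist(case_columns()))
  if (length(unknown)) {
    rlang::warn(paste0("case file has unknown column(s), kept as character: ",
                       paste(unknown, collapse = ", ")))
  }
  # parse issues are promoted to errors below; silence readr's own warning
  df <- suppressWarnings(
    readr::read_csv(path, comment = "#", col_types = case_col_types(),
                    show_col_types = FALSE, progress = FALSE))
  abort_parse_problems(df, path)
  bad_age <- which(!is.na(df$age) & df$age <= 0)
  if (length(bad_age)) {
    rlang::abort(paste0("invalid age (must be > 0) at data row ", bad_age[1]),
                 class = "mentsr_io_error")
  }
  bad_bmi <- which(!is.na(df$bmi) & (df$bmi <= 10 | df$bmi >= 80))
  if (length(bad_bmi)) {
    rlang::abort(paste0("invalid bmi (must be within (10, 80)) at data row ",
                        bad_bmi[1]), class = "mentsr_io_error")
  }
  df
}

# write a data frame as CSV with '#' metadata header lines, atomically: the
# output file appears only if the whole write succeeds
write_with_metadata <- function(df, path, metadata) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    rlang::abort(paste0("output directory does not exist: ", dir),
                 class = "mentsr_io_error")
  }
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  lines <- paste0("# ", names(metadata), ": ", unlist(metadata))
  writeLines(lines, tmp)
  readr::write_csv(df, tmp, append = TRUE, col_names = TRUE, progress = FALSE)
  if (!file.rename(tmp, path)) {
    rlang::abort(paste0("cannot write output file: ", path),
                 class = "mentsr_io_error")
  }
  invisible(path)
}

default_metadata <- function(extra = list()) {
  c(list(tool = paste0("mentsr ",
                       as.character(utils::packageVersion("mentsr")))),
    extra)
}

#' Write case records to CSV
#'
#' @param cases Case-record tibble.
#' @param path Output CSV path (written atomically).
#' @param seed Optional seed recorded in the metadata header.
#' @return The path, invisibly.
#' @export
write_cases <- function(cases, path, seed = NULL) {
  meta <- default_metadata(if (!is.null(seed)) list(seed = seed))
  write_with_metadata(tibble::as_tibble(cases), path, meta)
}

#' Write score sheets to CSV
#'
#' Columns appear in documented order: `case_id`, `rater_id`, `rater_role`,
#' the 16 factor scores in instrument order, the three component subtotals and
#' the total. A metadata comment header records the tool version, the rubric
#' name/version and (optionally) the seed.
#'
#' @param sheets Score-sheet tibble.
#' @param path Output CSV path (written atomically).
#' @param rubric Rubric the sheets were scored under (for the metadata header
#'   and column order).
#' @param seed Optional seed recorded in the metadata header.
#' @return The path, invisibly.
#' @export
write_scoresheets <- function(sheets, path, rubric = default_rubric(),
                              seed = NULL) {
  sheets <- tibble::as_tibble(sheets)
  cols <- c("case_id", "rater_id", "rater_role", rubric_factor_ids(rubric),
            "procedure_subtotal", "disease_subtotal", "patient_subtotal",
            "total")
  missing <- setdiff(cols, names(sheets))
  if (length(missing)) {
    rlang::abort(paste0("score sheets lack column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mentsr_sheet_error")
  }
  meta <- default_metadata(c(
    list(rubric = paste0(rubric$name, " v", rubric$version)),
    if (!is.null(seed)) list(seed = seed)))
  write_with_metadata(sheets[cols], path, meta)
}

#' Read score sheets from CSV
#'
#' @param path CSV path as written by [write_scoresheets()].
#' @return A score-sheet tibble.
#' @export
read_scoresheets <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("score-sheet file not found: ", path),
                 class = "mentsr_io_error")
  }
  df <- suppressWarnings(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE,
                    col_types = readr::cols(
                      case_id = readr::col_character(),
                      rater_id = readr::col_character(),
                      rater_role = readr::col_character(),
                      .default = readr::col_double())))
  abort_parse_problems(df, path)
  df
}
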