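#' Score one factor for a set of cases
#'
#' Looks up, for each case, the unique rubric level whose criterion matches
#' the factor's attribute, and returns its 1-5 score. Missing attributes are
#' an error (`mentsr_missing_attribute`), never a silent default: imputation
#' policy belongs to the caller.
#'
#' @param factor_def A single factor definition taken from a rubric's
#'   `$factors` list.
#' @param cases A case-record data frame (derived attributes are computed if
#'   absent).
#' @return Integer vector of scores in 1-5, one per row of `cases`.
#' @export
score_factor <- function(factor_def, cases) {
  cases <- tibble::as_tibble(cases)
  if (!factor_def$attribute %in% names(cases) || length(factor_def$derived_from)) {
    cases <- derive_attributes(cases)
  }
  attr_name <- factor_def$attribute
  if (!attr_name %in% names(cases)) {
    rlang::abort(paste0("factor '", factor_def$factor_id,
                        "': case records lack attribute '", attr_name, "'"),
                 class = "mentsr_missing_attribute")
  }
  x <- cases[[attr_name]]
  if (is.logical(x)) x <- tolower(as.character(x))
  if (anyNA(x)) {
    bad <- which(is.na(x))[1]
    rlang::abort(paste0(
      "factor '", factor_def$factor_id, "': attribute '", attr_name,
      "' is missing for case ",
      if ("case_id" %in% names(cases)) cases$case_id[bad] else bad,
      if (length(factor_def$derived_from)) {
        paste0(" (derived from ",
               paste(factor_def$derived_from, collapse = ", "), ")")
      } else ""),
      class = "mentsr_missing_attribute")
  }
  levels <- factor_def$levels[order(vapply(factor_def$levels, `[[`, 1L, "score"))]
  if (identical(factor_def$type, "numeric")) {
    x <- as.numeric(x)
    lo <- vapply(levels, `[[`, 0, "lower")
    top <- levels[[5]]$upper
    out_of_domain <- x < lo[1] | x > top
    if (any(out_of_domain)) {
      bad <- which(out_of_domain)[1]
      rlang::abort(paste0(
        "factor '", factor_def$factor_id, "': value ", x[bad],
        " of attribute '", attr_name, "' lies outside the declared domain [",
        lo[1], ", ", top, "]"), class = "mentsr_domain_error")
    }
    # left-closed bands [lower, upper); top level also includes its upper bound
    score <- findInterval(x, c(lo, top), rightmost.closed = TRUE)
  } else {
    lookup <- integer(0)
    for (l in levels) {
      lookup[l$values] <- l$score
    }
    score <- unname(lookup[as.character(x)])
    if (anyNA(score)) {
      bad <- which(is.na(score))[1]
      rlang::abort(paste0(
        "factor '", factor_def$factor_id, "': value '", x[bad],
        "' of attribute '", attr_name, "' matches no rubric level"),
        class = "mentsr_domain_error")
    }
  }
  as.integer(score)
}

#' Score case records under a rubric
#'
#' Applies every factor of the rubric to each case and assembles one score
#' sheet per case: the 16 factor scores, the procedure/disease/patient
#' component subtotals, and the total (their sum). Scoring is deterministic:
#' identical inputs yield identical sheets.
#'
#' @param cases Case-record data frame (one row per surgical candidate), e.g.
#'   from [generate_cohort()] or [read_cases()].
#' @param rubric A `ments_rubric`; defaults to the packaged instrument.
#' @param rater_id,rater_role Identifier and role (`"attending"` or
#'   `"trainee"`) recorded on every sheet.
#' @return A tibble with columns `case_id`, `rater_id`, `rater_role`, one
#'   column per factor id, `procedure_subtotal`, `disease_subtotal`,
#'   `patient_subtotal` and `total`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 5, seed = 1))
#' score_cases(cohort)
score_cases <- function(cases, rubric = default_rubric(),
                        rater_id = "rater_1", rater_role = "attending") {
  cases <- tibble::as_tibble(cases)
  if (!"case_id" %in% names(cases)) {
    rlang::abort("case records need a 'case_id' column",
                 class = "mentsr_missing_attribute")
  }
  if (anyDuplicated(cases$case_id)) {
    rlang::abort("duplicate case_id in case records",
                 class = "mentsr_case_error")
  }
  if (!rater_role %in% c("attending", "trainee")) {
    rlang::abort("rater_role must be 'attending' or 'trainee'")
  }
  cases <- derive_attributes(cases)
  scores <- purrr::map(rubric$factors, score_factor, cases = cases)
  names(scores) <- rubric_factor_ids(rubric)
  sheet <- tibble::tibble(case_id = as.character(cases$case_id),
                          rater_id = rater_id, rater_role = rater_role)
  sheet <- dplyr::bind_cols(sheet, tibble::as_tibble(scores))
  finalize_sheets(sheet, rubric)
}

# recompute subtotals and total from the factor columns
finalize_sheets <- function(sheet, rubric = default_rubric()) {
  comp <- vapply(rubric$factors, `[[`, "", "component")
  ids <- rubric_factor_ids(rubric)
  subtotal <- function(which) {
    cols <- ids[comp == which]
    as.integer(rowSums(sheet[, cols, drop = FALSE]))
  }
  sheet$procedure_subtotal <- subtotal("procedure")
  sheet$disease_subtotal <- subtotal("disease")
  sheet$patient_subtotal <- subtotal("patient")
  sheet$total <- sheet$procedure_subtotal + sheet$disease_subtotal +
    sheet$patient_subtotal
  sheet
}

#' Score a single case
#'
#' Convenience wrapper around [score_cases()] for one record.
#'
#' @inheritParams score_cases
#' @param case A one-row case-record data frame.
#' @return A one-row score-sheet tibble.
#' @export
score_case <- function(case, rubric = default_rubric(),
                       rater_id = "rater_1", rater_role = "attending") {
  case <- tibble::as_tibble(case)
  if (nrow(case) != 1L) {
    rlang::abort("score_case() expects exactly one case; use score_cases()")
  }
  score_cases(case, rubric, rater_id, rater_role)
}

#' Check score-sheet invariants
#'
#' Verifies that each sheet's factor scores are integers in 1-5, that the
#' subtotals equal the sums of their component factor columns, that the total
#' equals the sum of the subtotals, and that all values fall in the
#' instrument's attainable ranges (procedure 5-25, disease 4-20, patient 7-35,
#' total 16-80 for the default 5/4/7 instrument).
#'
#' @param sheets A score-sheet tibble as produced by [score_cases()].
#' @param rubric The rubric the sheets were scored under.
#' @return `sheets`, invisibly; errors of class `mentsr_sheet_error` otherwise.
#' @export
validate_scoresheets <- function(sheets, rubric = default_rubric()) {
  ids <- rubric_factor_ids(rubric)
  missing <- setdiff(c("case_id", "rater_id", "rater_role", ids,
                       "procedure_subtotal", "disease_subtotal",
                       "patient_subtotal", "total"), names(sheets))
  if (length(missing)) {
    rlang::abort(paste0("score sheets lack column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "mentsr_sheet_error")
  }
  fs <- as.matrix(sheets[ids])
  if (nrow(sheets)) {
    if (any(fs < 1 | fs > 5 | fs != round(fs))) {
      rlang::abort("factor scores must be integers in 1-5",
                   class = "mentsr_sheet_error")
    }
    comp <- vapply(rubric$factors, `[[`, "", "component")
    ok <- sheets$procedure_subtotal == rowSums(fs[, comp == "procedure", drop = FALSE]) &
      sheets$disease_subtotal == rowSums(fs[, comp == "disease", drop = FALSE]) &
      sheets$patient_subtotal == rowSums(fs[, comp == "patient", drop = FALSE]) &
      sheets$total == sheets$procedure_subtotal + sheets$disease_subtotal +
        sheets$patient_subtotal
    if (!all(ok)) {
      rlang::abort(paste0("subtotals/total inconsistent with factor scores for case ",
                          sheets$case_id[which(!ok)[1]]),
                   class = "mentsr_sheet_error")
    }
  }
  invisible(sheets)
}
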