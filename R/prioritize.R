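#' Rank scored cases into a surgical queue
#'
#' Orders cases ascending by total score (lower total = more time-sensitive =
#' higher priority, rank 1). Ties are broken deterministically by disease
#' subtotal (ascending, preferring the more time-sensitive disease) and then
#' case id (lexicographic).
#'
#' @param sheets One score sheet per case (aggregate multi-rater sheets first,
#'   e.g. with [aggregate_sheets()]).
#' @return A tibble `case_id`, `procedure_subtotal`, `disease_subtotal`,
#'   `patient_subtotal`, `total`, `rank` sorted by rank; ranks are a
#'   permutation of `1..n` and totals are non-decreasing in rank.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 6, seed = 1))
#' score_cases(cohort) |> rank_cases()
rank_cases <- function(sheets) {
  sheets <- tibble::as_tibble(sheets)
  if (anyDuplicated(sheets$case_id)) {
    rlang::abort(paste0(
      "duplicate case_id in score sheets: ",
      paste(unique(sheets$case_id[duplicated(sheets$case_id)]), collapse = ", "),
      " (aggregate multiple raters before ranking)"),
      class = "mentsr_queue_error")
  }
  keep <- intersect(c("case_id", "procedure_subtotal", "disease_subtotal",
                      "patient_subtotal", "total"), names(sheets))
  queue <- sheets |>
    dplyr::select(dplyr::all_of(keep)) |>
    dplyr::arrange(.data$total, .data$disease_subtotal, .data$case_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  queue
}

#' Aggregate paired rater sheets before ranking
#'
#' The instrument is scored per rater; ranking needs one sheet per case. The
#' default policy keeps the attending sheet; `"mean"` averages the two raters'
#' factor scores (and therefore subtotals and totals, which may then be
#' non-integer).
#'
#' @param attending,trainee Score-sheet tibbles covering the same cases.
#' @param method `"attending"` (default) or `"mean"`.
#' @param rubric Rubric the sheets were scored under.
#' @return A score-sheet tibble with one row per case.
#' @export
aggregate_sheets <- function(attending, trainee,
                             method = c("attending", "mean"),
                             rubric = default_rubric()) {
  method <- rlang::arg_match(method)
  if (method == "attending") return(tibble::as_tibble(attending))
  ids <- rubric_factor_ids(rubric)
  num_cols <- c(ids, "procedure_subtotal", "disease_subtotal",
                "patient_subtotal", "total")
  both <- dplyr::inner_join(
    tibble::as_tibble(attending), tibble::as_tibble(trainee),
    by = "case_id", suffix = c("_a", "_t"))
  out <- tibble::tibble(case_id = both$case_id,
                        rater_id = "mean_of_pair", rater_role = "attending")
  for (col in num_cols) {
    out[[col]] <- (both[[paste0(col, "_a")]] + both[[paste0(col, "_t")]]) / 2
  }
  out
}

#' Summarise score distributions, optionally by group
#'
#' Produces, per group and for the whole input (`"all"` row), the case count
#' and the median / min / max of the total and of each component subtotal -
#' the form in which cohort score distributions are usually tabulated.
#' Medians use the midpoint of the two central values for even group sizes.
#'
#' @param sheets Score sheets, one per case.
#' @param by Optional name of a grouping column. If it is not a sheet column,
#'   supply `cases` and it is joined in by `case_id` (e.g. `"indication"`,
#'   `"planned_procedure_class"`, `"acuity_tier"`, `"site_id"`).
#' @param cases Optional case-record tibble used to resolve `by`.
#' @return A tibble with columns `group`, `n`, and `<measure>_median`,
#'   `<measure>_min`, `<measure>_max` for total and the three subtotals.
#' @export
summarize_scores <- function(sheets, by = NULL, cases = NULL) {
  sheets <- tibble::as_tibble(sheets)
  measures <- c("total", "procedure_subtotal", "disease_subtotal",
                "patient_subtotal")
  if (!is.null(by)) {
    if (!by %in% names(sheets)) {
      if (is.null(cases) || !by %in% names(cases)) {
        rlang::abort(paste0("grouping attribute '", by,
                            "' found neither in sheets nor in cases"),
                     class = "mentsr_group_error")
      }
      sheets <- dplyr::left_join(
        sheets, dplyr::select(tibble::as_tibble(cases),
                              dplyr::all_of(c("case_id", by))),
        by = "case_id")
    }
    if (anyNA(sheets[[by]])) {
      rlang::abort(paste0("grouping attribute '", by,
                          "' is missing for some cases"),
                   class = "mentsr_group_error")
    }
  }
  one <- function(df, label) {
    row <- tibble::tibble(group = label, n = nrow(df))
    for (m in measures) {
      row[[paste0(m, "_median")]] <- stats::median(df[[m]])
      row[[paste0(m, "_min")]] <- min(df[[m]])
      row[[paste0(m, "_max")]] <- max(df[[m]])
    }
    row
  }
  if (!nrow(sheets)) {
    rlang::abort("no score sheets to summarise", class = "mentsr_group_error")
  }
  groups <- if (is.null(by)) list() else split(sheets, sheets[[by]])
  rows <- purrr::imap(groups, one)
  dplyr::bind_rows(c(unname(rows), list(one(sheets, "all"))))
}

#' Histogram of total scores over the attainable range
#'
#' Bins totals over the instrument's possible range (16-80 for the default
#' rubric) with integer bin edges; counts always sum to the number of sheets.
#' Totals outside the range signal an upstream invariant breach and are an
#' error.
#'
#' @param sheets Score sheets.
#' @param binwidth Integer bin width (default 1, one bin per attainable total).
#' @param range Attainable total range, default `c(16, 80)`.
#' @return Tibble `bin_lower`, `bin_upper`, `count`; bins are `[lower, upper)`
#'   with the final bin closed.
#' @export
score_histogram <- function(sheets, binwidth = 1L, range = c(16L, 80L)) {
  totals <- tibble::as_tibble(sheets)$total
  if (length(totals) && (any(totals < range[1]) || any(totals > range[2]))) {
    rlang::abort(paste0("total score outside [", range[1], ", ", range[2],
                        "]: upstream score-sheet invariant breached"),
                 class = "mentsr_sheet_error")
  }
  edges <- unique(c(seq(range[1], range[2], by = binwidth), range[2]))
  idx <- findInterval(totals, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  tibble::tibble(bin_lower = edges[-length(edges)],
                 bin_upper = edges[-1],
                 count = counts)
}

#' Crosswalk total scores against a three-tier acuity schema
#'
#' Summarises scores within each diagnosis-driven acuity tier (high /
#' intermediate / low) and flags whether the medians are monotone - i.e.
#' whether median(high) <= median(intermediate) <= median(low), the pattern
#' expected when lower totals track higher acuity.
#'
#' @param sheets Score sheets, one per case.
#' @param cases Case records supplying `acuity_tier` (ignored if the sheets
#'   already carry an `acuity_tier` column).
#' @return A `ments_crosswalk` object; see [tidy.ments_crosswalk()] for the
#'   per-tier table and [glance.ments_crosswalk()] for the monotonicity flag.
#' @export
tier_crosswalk <- function(sheets, cases = NULL) {
  sheets <- tibble::as_tibble(sheets)
  if (!"acuity_tier" %in% names(sheets)) {
    if (is.null(cases) || !"acuity_tier" %in% names(cases)) {
      rlang::abort("acuity_tier not found in sheets or cases",
                   class = "mentsr_group_error")
    }
    sheets <- dplyr::left_join(
      sheets, dplyr::select(tibble::as_tibble(cases), "case_id", "acuity_tier"),
      by = "case_id")
  }
  if (anyNA(sheets$acuity_tier)) {
    rlang::abort("acuity_tier is missing for some cases",
                 class = "mentsr_group_error")
  }
  bad <- setdiff(unique(sheets$acuity_tier), c("high", "intermediate", "low"))
  if (length(bad)) {
    rlang::abort(paste0("unknown acuity tier(s): ", paste(bad, collapse = ", ")),
                 class = "mentsr_group_error")
  }
  summary <- summarize_scores(sheets, by = "acuity_tier") |>
    dplyr::filter(.data$group != "all") |>
    dplyr::mutate(group = factor(.data$group, c("high", "intermediate", "low"))) |>
    dplyr::arrange(.data$group) |>
    dplyr::mutate(group = as.character(.data$group))
  med <- summary$total_median[match(c("high", "intermediate", "low"),
                                    summary$group)]
  med <- med[!is.na(med)]
  structure(list(summary = summary,
                 monotone = !is.unsorted(med),
                 n = nrow(sheets)),
            class = "ments_crosswalk")
}

#' @export
print.ments_crosswalk <- function(x, ...) {
  cat("<ments_crosswalk> ", x$n, " cases; tier medians ",
      if (x$monotone) "monotone" else "NOT monotone",
      " (high <= intermediate <= low)\n", sep = "")
  print(x$summary[, c("group", "n", "total_median", "total_min", "total_max")])
  invisible(x)
}

#' Per-tier score summaries of a tier crosswalk
#' @param x A `ments_crosswalk`.
#' @param ... Unused.
#' @return The per-tier summary tibble (see [summarize_scores()]).
#' @export
tidy.ments_crosswalk <- function(x, ...) x$summary

#' One-row summary of a tier crosswalk
#' @param x A `ments_crosswalk`.
#' @param ... Unused.
#' @return Tibble with `n_cases`, `n_tiers` and the `monotone` flag.
#' @export
glance.ments_crosswalk <- function(x, ...) {
  tibble::tibble(n_cases = x$n, n_tiers = nrow(x$summary),
                 monotone = x$monotone)
}
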