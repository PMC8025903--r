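#' Read a scoring rubric from a JSON or YAML document
#'
#' A rubric document defines the instrument: an ordered set of factors, each
#' belonging to one of the three components (procedure, disease, patient) and
#' carrying exactly five scoring levels (scores 1-5, each used once). Numeric
#' factors partition a declared `[min, max]` domain into left-closed intervals
#' `[lower, upper)` (the top level also includes its upper bound); categorical
#' factors partition a declared, risk-ordered category list. The document is
#' validated on load: non-exhaustive or overlapping criteria are rejected with
#' a message naming the factor and the offending attribute values.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` rubric document.
#' @return A validated `ments_rubric` object.
#' @seealso [default_rubric()] for the packaged modified-MeNTS instrument,
#'   [validate_rubric()] for the checks applied.
#' @export
#' @examples
#' rub <- default_rubric()
#' rub
read_rubric <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("rubric document not found: ", path),
                 class = "mentsr_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  doc <- tryCatch(
    switch(ext,
      json = jsonlite::read_json(path, simplifyVector = FALSE),
      yaml = ,
      yml  = yaml::read_yaml(path),
      rlang::abort(paste0("unsupported rubric format '.", ext,
                          "' (expected .json, .yaml or .yml)"),
                   class = "mentsr_rubric_error")
    ),
    error = function(e) {
      rlang::abort(paste0("malformed rubric document: ", conditionMessage(e)),
                   class = "mentsr_rubric_error")
    }
  )
  as_rubric(doc)
}

#' The packaged modified-MeNTS rubric
#'
#' Sixteen factors (5 procedure, 4 disease, 7 patient) scored 1-5, giving a
#' total range of 16 (strongest argument to proceed) to 80 (strongest argument
#' to defer). Cut-points that are not fully published are reconstructed and
#' labelled as such in the document, which ships at
#' `system.file("extdata", "modified_ments_rubric.json", package = "mentsr")`
#' so every cut-point is configuration, not code.
#'
#' @return A validated `ments_rubric` with 16 factors.
#' @export
default_rubric <- function() {
  read_rubric(system.file("extdata", "modified_ments_rubric.json",
                          package = "mentsr", mustWork = TRUE))
}

#' Build a rubric from a parsed document (list)
#'
#' @param doc A list with elements `name`, `version` and `factors`, as parsed
#'   from a rubric JSON/YAML document.
#' @return A validated `ments_rubric`.
#' @export
as_rubric <- function(doc) {
  for (field in c("name", "version", "factors")) {
    if (is.null(doc[[field]])) {
      rlang::abort(paste0("rubric document lacks required field '", field, "'"),
                   class = "mentsr_rubric_error")
    }
  }
  factors <- purrr::map(doc$factors, new_factor_definition)
  rubric <- structure(
    list(name = doc$name, version = doc$version,
         description = doc$description %||% "", factors = factors),
    class = "ments_rubric"
  )
  validate_rubric(rubric)
}

# normalise one factor entry of the document
new_factor_definition <- function(f) {
  for (field in c("factor_id", "component", "attribute", "type", "levels",
                  "domain")) {
    if (is.null(f[[field]])) {
      rlang::abort(paste0("factor '", f$factor_id %||% "<unnamed>",
                          "' lacks required field '", field, "'"),
                   class = "mentsr_rubric_error")
    }
  }
  levels <- purrr::map(f$levels, function(l) {
    list(score = as.integer(l$score),
         label = l$label %||% "",
         lower = if (!is.null(l$lower)) as.numeric(l$lower),
         upper = if (!is.null(l$upper)) as.numeric(l$upper),
         values = as.character(unlist(l$values)))
  })
  list(
    factor_id = f$factor_id,
    component = f$component,
    label = f$label %||% f$factor_id,
    attribute = f$attribute,
    type = f$type,
    derived_from = as.character(unlist(f$derived_from)),
    domain = if (identical(f$type, "numeric")) {
      list(min = as.numeric(f$domain$min), max = as.numeric(f$domain$max))
    } else {
      as.character(unlist(f$domain))
    },
    levels = levels
  )
}

#' Validate a rubric
#'
#' Checks the structural invariants of the instrument: component counts
#' (procedure 5, disease 4, patient 7), five levels per factor with scores
#' exactly `{1,2,3,4,5}`, and - the substantive check - that every factor's
#' criteria are exhaustive and mutually exclusive over its declared attribute
#' domain, so any complete case matches exactly one level of every factor.
#' Gaps and overlaps are reported with the factor id and the uncovered or
#' ambiguous attribute values.
#'
#' @param rubric A `ments_rubric`.
#' @return The rubric, invisibly, if valid; otherwise an error of class
#'   `mentsr_rubric_error`.
#' @export
validate_rubric <- function(rubric) {
  stopifnot(inherits(rubric, "ments_rubric"))
  comp <- vapply(rubric$factors, `[[`, "", "component")
  bad_comp <- setdiff(unique(comp), c("procedure", "disease", "patient"))
  if (length(bad_comp)) {
    rlang::abort(paste0("unknown component(s): ",
                        paste(bad_comp, collapse = ", ")),
                 class = "mentsr_rubric_error")
  }
  counts <- table(factor(comp, c("procedure", "disease", "patient")))
  expected <- c(procedure = 5L, disease = 4L, patient = 7L)
  if (!identical(as.integer(counts), unname(expected))) {
    rlang::abort(paste0(
      "component factor counts must be procedure=5, disease=4, patient=7; got ",
      paste(names(counts), as.integer(counts), sep = "=", collapse = ", ")),
      class = "mentsr_rubric_error")
  }
  ids <- vapply(rubric$factors, `[[`, "", "factor_id")
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("duplicate factor_id: ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 class = "mentsr_rubric_error")
  }
  for (f in rubric$factors) validate_factor(f)
  invisible(rubric)
}

validate_factor <- function(f) {
  abort_f <- function(...) {
    rlang::abort(paste0("factor '", f$factor_id, "': ", ...),
                 class = "mentsr_rubric_error")
  }
  if (length(f$levels) != 5L) {
    abort_f("must declare exactly 5 levels, found ", length(f$levels))
  }
  scores <- vapply(f$levels, `[[`, 1L, "score")
  if (!identical(sort(scores), 1:5)) {
    abort_f("level scores must be exactly {1,2,3,4,5}, found {",
            paste(sort(scores), collapse = ","), "}")
  }
  levels <- f$levels[order(scores)]
  if (identical(f$type, "numeric")) {
    lo <- vapply(levels, function(l) l$lower %||% NA_real_, 0)
    hi <- vapply(levels, function(l) l$upper %||% NA_real_, 0)
    if (anyNA(lo) || anyNA(hi)) abort_f("numeric levels need 'lower' and 'upper'")
    if (any(hi <= lo)) abort_f("each numeric level needs lower < upper")
    if (abs(lo[1] - f$domain$min) > 1e-9) {
      abort_f("criteria not exhaustive: domain starts at ", f$domain$min,
              " but first level starts at ", lo[1])
    }
    if (abs(hi[5] - f$domain$max) > 1e-9) {
      abort_f("criteria not exhaustive: domain ends at ", f$domain$max,
              " but last level ends at ", hi[5])
    }
    for (k in 1:4) {
      if (lo[k + 1] > hi[k] + 1e-9) {
        abort_f("criteria not exhaustive: attribute '", f$attribute,
                "' range [", hi[k], ", ", lo[k + 1], ") is uncovered")
      }
      if (lo[k + 1] < hi[k] - 1e-9) {
        abort_f("criteria overlap: attribute '", f$attribute,
                "' range [", lo[k + 1], ", ", hi[k], ") matches two levels")
      }
    }
  } else if (identical(f$type, "categorical")) {
    vals <- unlist(lapply(levels, `[[`, "values"))
    dup <- unique(vals[duplicated(vals)])
    if (length(dup)) {
      abort_f("criteria overlap: value(s) ", paste(dup, collapse = ", "),
              " of attribute '", f$attribute, "' match more than one level")
    }
    unknown <- setdiff(vals, f$domain)
    if (length(unknown)) {
      abort_f("level value(s) outside declared domain of '", f$attribute,
              "': ", paste(unknown, collapse = ", "))
    }
    missing <- setdiff(f$domain, vals)
    if (length(missing)) {
      abort_f("criteria not exhaustive: value(s) ",
              paste(missing, collapse = ", "), " of attribute '", f$attribute,
              "' match no level")
    }
  } else {
    abort_f("unknown type '", f$type, "' (expected 'numeric' or 'categorical')")
  }
  invisible(f)
}

#' @export
print.ments_rubric <- function(x, ...) {
  comp <- vapply(x$factors, `[[`, "", "component")
  cat("<ments_rubric> ", x$name, " v", x$version, "\n", sep = "")
  cat("  factors: ", length(x$factors),
      " (procedure ", sum(comp == "procedure"),
      ", disease ", sum(comp == "disease"),
      ", patient ", sum(comp == "patient"), ")\n", sep = "")
  cat("  total range: ", length(x$factors), "-", 5L * length(x$factors),
      " (lower = higher priority)\n", sep = "")
  invisible(x)
}

#' Summarise a rubric as a tibble
#'
#' @param x A `ments_rubric`.
#' @param ... Unused.
#' @return One row per factor: id, component, label, scored attribute, type.
#' @export
tidy.ments_rubric <- function(x, ...) {
  tibble::tibble(
    factor_id = vapply(x$factors, `[[`, "", "factor_id"),
    component = vapply(x$factors, `[[`, "", "component"),
    label = vapply(x$factors, `[[`, "", "label"),
    attribute = vapply(x$factors, `[[`, "", "attribute"),
    type = vapply(x$factors, `[[`, "", "type")
  )
}

#' Factor ids of a rubric, in instrument order
#' @param rubric A `ments_rubric`.
#' @return Character vector of factor ids.
#' @export
rubric_factor_ids <- function(rubric) {
  vapply(rubric$factors, `[[`, "", "factor_id")
}

# ---- derived attributes -----------------------------------------------------

# grade ladders feeding the composite pulmonary class
.pulm_lung <- c(none = 1L, controlled_asthma = 2L, uncontrolled_asthma = 3L,
                copd = 4L, severe_copd = 5L)
.pulm_smoking <- c(never = 1L, former = 2L, current = 3L)
.pulm_osa <- c(none = 1L, treated = 2L, untreated = 3L)

#' Compute derived scoring attributes for case records
#'
#' Two rubric factors score composite attributes rather than raw record
#' fields: `pulmonary_class` (worst of the lung-disease grade, smoking grade
#' and OSA-control grade) and `diabetes_class` (diabetes status refined by the
#' HbA1c > 8 threshold and documented end-organ disease). This helper adds
#' both columns; [score_cases()] calls it automatically.
#'
#' @param cases A case-record data frame.
#' @return `cases` with `pulmonary_class` and `diabetes_class` columns added.
#' @export
derive_attributes <- function(cases) {
  cases <- tibble::as_tibble(cases)
  lung <- unname(.pulm_lung[as.character(cases$lung_disease)])
  smok <- unname(.pulm_smoking[as.character(cases$smoking_status)])
  osa <- unname(.pulm_osa[as.character(cases$osa_status)])
  cases$pulmonary_class <- ifelse(
    is.na(lung) | is.na(smok) | is.na(osa), NA_character_,
    paste0("pulm_", pmax(lung, smok, osa)))

  status <- as.character(cases$diabetes_status)
  end_organ <- if ("diabetes_end_organ" %in% names(cases)) {
    as.character(cases$diabetes_end_organ)
  } else {
    rep("unknown", nrow(cases))
  }
  hba1c <- if ("hba1c" %in% names(cases)) cases$hba1c else rep(NA_real_, nrow(cases))
  medicated <- !is.na(status) & status == "medicated"
  if (any(medicated & is.na(hba1c))) {
    bad <- which(medicated & is.na(hba1c))[1]
    rlang::abort(paste0(
      "missing attribute 'hba1c' for medicated diabetes (e.g. case ",
      if ("case_id" %in% names(cases)) cases$case_id[bad] else bad,
      "); hba1c is required whenever diabetes_status = medicated"),
      class = "mentsr_missing_attribute")
  }
  cases$diabetes_class <- dplyr::case_when(
    is.na(status) ~ NA_character_,
    status == "none" ~ "none",
    status == "diet_controlled" ~ "diet_controlled",
    medicated & hba1c <= 8 ~ "medicated_controlled",
    medicated & hba1c > 8 & end_organ == "none" ~ "hba1c_gt8_no_end_organ",
    medicated & hba1c > 8 ~ "hba1c_gt8",
    TRUE ~ NA_character_
  )
  cases
}

`%||%` <- rlang::`%||%`
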