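#' Build an n x k rating matrix from paired score sheets
#'
#' Assembles the subjects-by-raters matrix of totals used by the reliability
#' analysis: one row per case, one column per rater. Cases missing from any
#' rater are dropped listwise, with the dropped count reported via a message.
#'
#' @param ... Two or more score-sheet tibbles, one per rater. Column names of
#'   the result are taken from each sheet's `rater_id`.
#' @return Numeric matrix with case ids as row names and an attribute
#'   `n_dropped` (cases without a complete set of ratings).
#' @export
rating_matrix <- function(...) {
  sheets <- list(...)
  if (length(sheets) == 1L && is.list(sheets[[1]]) &&
      !is.data.frame(sheets[[1]])) {
    sheets <- sheets[[1]]
  }
  if (length(sheets) < 2L) {
    rlang::abort("rating_matrix() needs at least two raters' sheets",
                 class = "mentsr_icc_error")
  }
  sheets <- purrr::map(sheets, tibble::as_tibble)
  ids <- purrr::reduce(purrr::map(sheets, ~ unique(.x$case_id)), intersect)
  all_ids <- unique(unlist(purrr::map(sheets, "case_id")))
  n_dropped <- length(all_ids) - length(ids)
  if (n_dropped > 0) {
    rlang::inform(paste0("rating_matrix: dropped ", n_dropped,
                         " case(s) without a complete rater pair"))
  }
  cols <- purrr::map(sheets, function(s) s$total[match(ids, s$case_id)])
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  colnames(m) <- purrr::map_chr(sheets, ~ as.character(.x$rater_id[1]))
  attr(m, "n_dropped") <- n_dropped
  m
}

#' Two-way crossed ANOVA decomposition of a rating matrix
#'
#' Decomposes an n subjects x k raters matrix (no replication) into
#' between-subject, between-rater and residual mean squares - the components
#' of the Shrout-Fleiss two-way random-effects reliability model.
#'
#' @param x Numeric matrix or data frame, rows = subjects (cases), columns =
#'   raters; no missing cells.
#' @return A `ments_anova` list: `ms_rows`, `ms_cols`, `ms_error`, the
#'   corresponding degrees of freedom (`n-1`, `k-1`, `(n-1)(k-1)`), `n`, `k`
#'   and the grand mean.
#' @export
anova_decompose <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    rlang::abort("rating matrix must be numeric", class = "mentsr_icc_error")
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) {
    rlang::abort(paste0("rating matrix must be at least 2 x 2, got ",
                        n, " x ", k), class = "mentsr_icc_error")
  }
  if (anyNA(x)) {
    rlang::abort("rating matrix has missing cells; drop incomplete cases first",
                 class = "mentsr_icc_error")
  }
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  resid <- x - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  ss_error <- sum(resid^2)
  structure(list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = ss_error / ((n - 1) * (k - 1)),
    df_rows = n - 1L, df_cols = k - 1L, df_error = (n - 1L) * (k - 1L),
    n = n, k = k, grand_mean = grand
  ), class = "ments_anova")
}

#' @export
print.ments_anova <- function(x, ...) {
  cat("<ments_anova> two-way crossed, no replication: ",
      x$n, " subjects x ", x$k, " raters\n", sep = "")
  cat(sprintf("  MS subjects %.6g (df %d); MS raters %.6g (df %d); MS error %.6g (df %d)\n",
              x$ms_rows, x$df_rows, x$ms_cols, x$df_cols,
              x$ms_error, x$df_error))
  invisible(x)
}

#' Intraclass correlation for absolute agreement
#'
#' Two-way random-effects, absolute-agreement ICC (Shrout-Fleiss ICC(2,1) /
#' McGraw-Wong ICC(A,1)) estimated from the two-way ANOVA mean squares:
#'
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#'
#' The absolute-agreement form counts systematic rater offsets as
#' disagreement, making it more conservative than the consistency form. The
#' single-rater estimate is the default because a case in practice is scored
#' by one clinician; `measure = "average"` gives the k-rater-average form
#' ICC(A,k).
#'
#' @param x Rating matrix (subjects x raters), e.g. from [rating_matrix()].
#' @param measure `"single"` (default) or `"average"`.
#' @return A `ments_icc` object with the estimate, interpretation band, and
#'   the underlying `ments_anova` decomposition. Fully constant matrices have
#'   no defined ICC and raise an error rather than returning a silent zero.
#' @export
#' @examples
#' m <- cbind(a = c(30, 41, 25, 33, 38, 29), b = c(32, 40, 28, 33, 35, 30))
#' icc_absolute_agreement(m)
icc_absolute_agreement <- function(x, measure = c("single", "average")) {
  measure <- rlang::arg_match(measure)
  dec <- if (inherits(x, "ments_anova")) x else anova_decompose(x)
  n <- dec$n; k <- dec$k
  num <- dec$ms_rows - dec$ms_error
  denom <- if (measure == "single") {
    dec$ms_rows + (k - 1) * dec$ms_error + (k / n) * (dec$ms_cols - dec$ms_error)
  } else {
    dec$ms_rows + (dec$ms_cols - dec$ms_error) / n
  }
  if (abs(denom) < 1e-12) {
    rlang::abort("ICC undefined: no variance in the rating matrix",
                 class = "mentsr_icc_error")
  }
  estimate <- num / denom
  structure(list(
    estimate = estimate,
    measure = measure,
    form = paste0("two-way random, absolute agreement, ",
                  if (measure == "single") "single rater" else "average of raters"),
    band = interpret_icc(estimate),
    decomposition = dec,
    n = n, k = k
  ), class = "ments_icc")
}

#' @export
print.ments_icc <- function(x, ...) {
  cat("<ments_icc> ", x$form, "\n", sep = "")
  cat(sprintf("  estimate %.4f (%s); %d subjects x %d raters\n",
              x$estimate, x$band, x$n, x$k))
  invisible(x)
}

#' Tidy an ICC fit
#' @param x A `ments_icc`.
#' @param ... Unused.
#' @return One-row tibble with the estimate, band, measure and mean squares.
#' @export
tidy.ments_icc <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, band = x$band, measure = x$measure,
    n_subjects = x$n, n_raters = x$k,
    ms_rows = x$decomposition$ms_rows,
    ms_cols = x$decomposition$ms_cols,
    ms_error = x$decomposition$ms_error
  )
}

#' One-row summary of an ICC fit
#' @param x A `ments_icc`.
#' @param ... Unused.
#' @return Tibble with estimate, band and dimensions.
#' @export
glance.ments_icc <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, band = x$band,
                 n_subjects = x$n, n_raters = x$k)
}

#' Interpret ICC estimates on the Cicchetti bands
#'
#' Conventional clinical-reliability interpretation: poor below 0.40, fair
#' 0.40-0.59, good 0.60-0.74, excellent 0.75 and above.
#'
#' @param estimate Numeric vector of finite ICC estimates.
#' @return Character vector of bands (`"poor"`, `"fair"`, `"good"`,
#'   `"excellent"`).
#' @export
#' @examples
#' interpret_icc(c(0.72, 0.77, 0.10))
interpret_icc <- function(estimate) {
  if (any(!is.finite(estimate))) {
    rlang::abort("ICC estimate must be finite", class = "mentsr_icc_error")
  }
  as.character(cut(estimate, c(-Inf, 0.40, 0.60, 0.75, Inf),
                   labels = c("poor", "fair", "good", "excellent"),
                   right = FALSE))
}

#' Per-site and pooled inter-rater reliability
#'
#' Computes the absolute-agreement ICC between two raters' totals within each
#' site and pooled across sites (all sites stacked into one ANOVA). Cases
#' without a complete rater pair are dropped listwise and counted. Sites with
#' fewer than two complete pairs are reported as insufficient rather than
#' estimated.
#'
#' @param attending,trainee Score-sheet tibbles for the two raters.
#' @param cases Case records supplying `site_id` (joined by `case_id`).
#' @param measure Passed to [icc_absolute_agreement()].
#' @return A tibble with one row per site plus a `"pooled"` row: `site`,
#'   `n_pairs`, `n_dropped`, `estimate`, `band`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `status` (`"ok"` or `"insufficient"`).
#' @export
per_site_icc <- function(attending, trainee, cases,
                         measure = c("single", "average")) {
  measure <- rlang::arg_match(measure)
  cases <- tibble::as_tibble(cases)
  if (!all(c("case_id", "site_id") %in% names(cases))) {
    rlang::abort("cases must carry case_id and site_id",
                 class = "mentsr_icc_error")
  }
  att <- tibble::as_tibble(attending)
  tra <- tibble::as_tibble(trainee)
  pairs <- dplyr::inner_join(
    dplyr::select(att, "case_id", a_total = "total"),
    dplyr::select(tra, "case_id", t_total = "total"),
    by = "case_id") |>
    dplyr::left_join(dplyr::select(cases, "case_id", "site_id"), by = "case_id")
  if (anyNA(pairs$site_id)) {
    rlang::abort("some scored cases have no site_id in the case records",
                 class = "mentsr_icc_error")
  }
  n_all <- length(union(att$case_id, tra$case_id))
  drop_total <- n_all - nrow(pairs)
  if (drop_total > 0) {
    rlang::inform(paste0("per_site_icc: dropped ", drop_total,
                         " case(s) without a complete rater pair"))
  }
  one <- function(df, label, n_dropped) {
    if (nrow(df) < 2L) {
      return(tibble::tibble(site = label, n_pairs = nrow(df),
                            n_dropped = n_dropped,
                            estimate = NA_real_, band = NA_character_,
                            ms_rows = NA_real_, ms_cols = NA_real_,
                            ms_error = NA_real_, status = "insufficient"))
    }
    fit <- icc_absolute_agreement(cbind(df$a_total, df$t_total),
                                  measure = measure)
    tibble::tibble(site = label, n_pairs = nrow(df), n_dropped = n_dropped,
                   estimate = fit$estimate, band = fit$band,
                   ms_rows = fit$decomposition$ms_rows,
                   ms_cols = fit$decomposition$ms_cols,
                   ms_error = fit$decomposition$ms_error, status = "ok")
  }
  by_site <- split(pairs, pairs$site_id)
  rows <- purrr::imap(by_site, function(df, s) one(df, s, 0L))
  dplyr::bind_rows(c(unname(rows), list(one(pairs, "pooled", drop_total))))
}

#' Tolerance-based rank consistency between two raters
#'
#' Fraction of items whose rank positions under two raters differ by no more
#' than `tolerance` places (inclusive: a difference of exactly `tolerance`
#' counts as consistent). With the default tolerance of 2, this is the
#' "differed by 2 points or less" rank-consistency statistic used to compare
#' instrument rankings against expert review.
#'
#' @param rank_a,rank_b Integer vectors, each a permutation of `1..n`, aligned
#'   by item (element i is item i's rank under each rater).
#' @param tolerance Non-negative integer, default 2.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' rank_agreement(1:10, 10:1) # only the two middle items stay within 2 places
rank_agreement <- function(rank_a, rank_b, tolerance = 2L) {
  if (length(rank_a) != length(rank_b)) {
    rlang::abort("rank vectors must have the same length",
                 class = "mentsr_rank_error")
  }
  n <- length(rank_a)
  if (n == 0L) {
    rlang::abort("rank vectors are empty", class = "mentsr_rank_error")
  }
  for (r in list(rank_a, rank_b)) {
    if (!identical(sort(as.integer(r)), seq_len(n))) {
      rlang::abort("rank vectors must each be a permutation of 1..n",
                   class = "mentsr_rank_error")
    }
  }
  if (tolerance < 0) {
    rlang::abort("tolerance must be non-negative", class = "mentsr_rank_error")
  }
  mean(abs(as.integer(rank_a) - as.integer(rank_b)) <= tolerance)
}
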