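# 6 cases x 2 raters fixture; oracle values computed with the double-loop
# sum-of-squares oracle and cross-checked against an independent ICC
# implementation before being frozen here
fixture_matrix <- function() {
  cbind(attending = c(30, 41, 25, 33, 38, 29),
        trainee = c(32, 40, 28, 33, 35, 30))
}

test_that("two-way decomposition matches the frozen fixture and loop oracle", {
  x <- fixture_matrix()
  dec <- anova_decompose(x)
  expect_equal(dec$ms_rows, 50.733333333333334, tolerance = 1e-12)
  expect_equal(dec$ms_cols, 1 / 3, tolerance = 1e-12)
  expect_equal(dec$ms_error, 7 / 3, tolerance = 1e-12)
  expect_equal(dec$df_rows, 5L)
  expect_equal(dec$df_cols, 1L)
  expect_equal(dec$df_error, 5L)
  oracle <- ss_oracle(x)
  expect_equal(dec$ms_rows, oracle$ms_rows, tolerance = 1e-12)
  expect_equal(dec$ms_cols, oracle$ms_cols, tolerance = 1e-12)
  expect_equal(dec$ms_error, oracle$ms_error, tolerance = 1e-12)
})

test_that("degenerate matrices decompose as expected", {
  # identical columns, varying rows: no rater or residual variance
  x <- cbind(c(10, 20, 30), c(10, 20, 30))
  dec <- anova_decompose(x)
  expect_equal(dec$ms_cols, 0)
  expect_equal(dec$ms_error, 0)
  expect_gt(dec$ms_rows, 0)
  const <- anova_decompose(matrix(7, 4, 2))
  expect_equal(const$ms_rows, 0)
  expect_equal(const$ms_cols, 0)
  expect_equal(const$ms_error, 0)
  expect_error(anova_decompose(matrix(1:2, 1, 2)), "at least 2 x 2",
               class = "mentsr_icc_error")
  expect_error(anova_decompose(cbind(c(1, NA), c(2, 3))), "missing",
               class = "mentsr_icc_error")
})

test_that("absolute-agreement ICC matches the fixture and the oracle formula", {
  fit <- icc_absolute_agreement(fixture_matrix())
  expect_equal(fit$estimate, 0.9236641221374045, tolerance = 1e-12)
  expect_equal(fit$estimate, icc_oracle(fixture_matrix()), tolerance = 1e-12)
  expect_equal(fit$band, "excellent")
  expect_equal(fit$form, "two-way random, absolute agreement, single rater")
  avg <- icc_absolute_agreement(fixture_matrix(), measure = "average")
  expect_equal(avg$estimate, 0.9603174603174605, tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$ms_error, 7 / 3, tolerance = 1e-12)
  expect_equal(glance(fit)$n_subjects, 6L)
})

test_that("perfect agreement gives 1, systematic offsets erode the estimate", {
  x <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_equal(icc_absolute_agreement(x)$estimate, 1)
  est_at_offset <- vapply(c(0, 5, 20, 60), function(c0) {
    icc_absolute_agreement(cbind(x[, 1], x[, 1] + c0))$estimate
  }, 0)
  expect_false(is.unsorted(rev(est_at_offset)))
  expect_lt(est_at_offset[4], est_at_offset[1])
  expect_error(icc_absolute_agreement(matrix(7, 4, 2)), "undefined",
               class = "mentsr_icc_error")
})

test_that("ICC is invariant to shift and positive scaling and capped at 1", {
  withr::with_seed(42, {
    for (i in 1:25) {
      x <- random_rating_matrix(sample(3:10, 1), sample(2:4, 1))
      if (abs(stats::var(as.vector(x))) < 1e-12) next
      est <- icc_absolute_agreement(x)$estimate
      expect_equal(icc_absolute_agreement(x + 13.7)$estimate, est,
                   tolerance = 1e-9)
      expect_equal(icc_absolute_agreement(x * 2.5)$estimate, est,
                   tolerance = 1e-9)
      expect_lte(est, 1)
    }
  })
})

test_that("Cicchetti bands follow the published thresholds", {
  expect_equal(interpret_icc(0.72), "good")
  expect_equal(interpret_icc(0.77), "excellent")
  expect_equal(interpret_icc(0.10), "poor")
  expect_equal(interpret_icc(c(0.399, 0.40, 0.599, 0.60, 0.749, 0.75)),
               c("poor", "fair", "fair", "good", "good", "excellent"))
  expect_equal(interpret_icc(c(0.65, 0.73)), c("good", "good"))
  expect_error(interpret_icc(NaN), class = "mentsr_icc_error")
})

test_that("per-site ICC handles perfect sites, pooling, and thin sites", {
  cohort <- generate_cohort(cohort_config(n = 60, seed = 21))
  att <- score_cases(cohort, rater_id = "attending_1")
  tra <- att
  tra$rater_id <- "trainee_1"
  tra$rater_role <- "trainee"
  out <- per_site_icc(att, tra, cohort)
  expect_true(all(out$estimate[out$status == "ok"] == 1))
  # pooled row equals the ICC of the stacked matrix
  pair <- simulate_rater_pair(cohort, noise = rater_noise(0.4, seed = 22))
  out2 <- per_site_icc(pair$attending, pair$trainee, cohort)
  stacked <- icc_absolute_agreement(
    rating_matrix(pair$attending, pair$trainee))$estimate
  expect_equal(out2$estimate[out2$site == "pooled"], stacked, tolerance = 1e-12)
  # a site with fewer than two complete pairs is reported, not estimated
  solo <- cohort
  solo$site_id[1] <- "site_solo"
  out3 <- per_site_icc(pair$attending[1:10, ], pair$trainee[1:10, ], solo)
  expect_equal(out3$status[out3$site == "site_solo"], "insufficient")
  expect_true(is.na(out3$estimate[out3$site == "site_solo"]))
})

test_that("incomplete rater pairs are dropped listwise with a reported count", {
  cohort <- generate_cohort(cohort_config(n = 20, seed = 23))
  pair <- simulate_rater_pair(cohort, noise = rater_noise(0.4, seed = 23))
  expect_message(m <- rating_matrix(pair$attending[-(1:3), ], pair$trainee),
                 "dropped 3")
  expect_equal(nrow(m), 17L)
  expect_equal(attr(m, "n_dropped"), 3L)
  expect_message(out <- per_site_icc(pair$attending[-(1:3), ], pair$trainee,
                                     cohort), "dropped 3")
  expect_equal(out$n_dropped[out$site == "pooled"], 3L)
})

test_that("noisier sites order their reliability estimates accordingly", {
  cohort <- generate_cohort(cohort_config(n = 300, seed = 31))
  att <- score_cases(cohort)
  noise_by_site <- c(site_a = 0.05, site_b = 0.45, site_c = 0.95)
  ids <- rubric_factor_ids(default_rubric())
  tra <- att
  withr::with_seed(32, {
    fs <- as.matrix(att[ids])
    p <- noise_by_site[cohort$site_id[match(att$case_id, cohort$case_id)]]
    flip <- matrix(stats::runif(length(fs)), nrow(fs)) < p
    dir <- matrix(sample(c(-1L, 1L), length(fs), TRUE), nrow(fs))
    tra[ids] <- tibble::as_tibble(pmin(pmax(fs + flip * dir, 1L), 5L))
  })
  tra$rater_id <- "trainee_1"
  tra$rater_role <- "trainee"
  tra <- mentsr:::finalize_sheets(tra)
  out <- per_site_icc(att, tra, cohort)
  est <- out$estimate[match(c("site_a", "site_b", "site_c"), out$site)]
  expect_false(is.unsorted(rev(est)))
})

test_that("rank agreement counts positions within the inclusive tolerance", {
  expect_equal(rank_agreement(1:10, 1:10), 1.0)
  # reversal of 10: only positions 5 and 6 move by <= 2 places
  expect_equal(rank_agreement(1:10, 10:1), 0.2)
  # a uniform shift of exactly 2 counts as consistent ("2 points or less")
  a <- 1:8
  b <- c(3:8, 1:2) # every non-wrapping item differs by exactly 2
  diffs <- abs(a - b)
  expect_true(all(diffs[1:6] == 2))
  expect_equal(rank_agreement(a, b), 6 / 8)
  expect_equal(rank_agreement(a, b, tolerance = 7), 1.0)
})

test_that("rank agreement is symmetric and validates its inputs", {
  withr::with_seed(5, {
    for (i in 1:10) {
      n <- sample(3:12, 1)
      a <- sample.int(n)
      b <- sample.int(n)
      expect_equal(rank_agreement(a, b), rank_agreement(b, a))
      expect_equal(rank_agreement(a, b, tolerance = n - 1), 1.0)
    }
  })
  expect_error(rank_agreement(1:5, 1:4), "length", class = "mentsr_rank_error")
  expect_error(rank_agreement(c(1, 2, 2), 1:3), "permutation",
               class = "mentsr_rank_error")
})
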