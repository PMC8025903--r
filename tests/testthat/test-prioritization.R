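make_sheets <- function(case_id, total, disease = 0L, procedure = 0L,
                        patient = NULL) {
  if (is.null(patient)) patient <- total - disease - procedure
  tibble::tibble(case_id = case_id, rater_id = "r", rater_role = "attending",
                 procedure_subtotal = procedure, disease_subtotal = disease,
                 patient_subtotal = patient, total = total)
}

test_that("queue sorts ascending by total with deterministic tie-breaks", {
  q <- rank_cases(make_sheets(c("A", "B", "C"), c(33L, 18L, 52L)))
  expect_equal(q$case_id, c("B", "A", "C"))
  expect_equal(q$rank, 1:3)
  # tie on total broken by disease subtotal (more time-sensitive first)
  q2 <- rank_cases(make_sheets(c("A", "B"), c(30L, 30L), disease = c(12L, 9L)))
  expect_equal(q2$case_id, c("B", "A"))
  # tie on total and disease broken lexicographically by case id
  q3 <- rank_cases(make_sheets(c("b", "a"), c(30L, 30L), disease = c(9L, 9L)))
  expect_equal(q3$case_id, c("a", "b"))
})

test_that("queue is empty on empty input and rejects duplicate cases", {
  empty <- make_sheets(character(), integer())
  expect_equal(nrow(rank_cases(empty)), 0L)
  expect_error(rank_cases(make_sheets(c("A", "A"), c(20L, 30L))),
               "duplicate", class = "mentsr_queue_error")
})

test_that("queue ranks are a permutation and invariant to input order", {
  cohort <- generate_cohort(cohort_config(n = 80, seed = 5))
  sheets <- score_cases(cohort)
  q <- rank_cases(sheets)
  expect_equal(sort(q$rank), 1:80)
  expect_false(is.unsorted(q$total))
  shuffled <- sheets[withr::with_seed(9, sample.int(nrow(sheets))), ]
  expect_equal(rank_cases(shuffled), q)
})

test_that("group summaries use midpoint medians and hand-sorted ranges", {
  s <- make_sheets(paste0("c", 1:4), c(24L, 43L, 33L, 34L))
  out <- summarize_scores(s)
  expect_equal(out$group, "all")
  expect_equal(out$total_median, 33.5)
  expect_equal(out$total_min, 24L)
  expect_equal(out$total_max, 43L)
  one <- summarize_scores(make_sheets("c1", 37L))
  expect_equal(one$total_median, 37)
  expect_equal(one$total_min, one$total_max)
})

test_that("grouped summaries match a brute-force sort/median oracle", {
  s <- make_sheets(paste0("c", 1:5), c(40L, 22L, 31L, 28L, 35L))
  s$approach <- c("mis", "mis", "mis", "open", "open")
  out <- summarize_scores(s, by = "approach")
  mis <- sort(c(40, 22, 31))
  expect_equal(out$total_median[out$group == "mis"], mis[2])
  expect_equal(out$total_min[out$group == "mis"], mis[1])
  expect_equal(out$total_max[out$group == "mis"], mis[3])
  expect_equal(out$total_median[out$group == "open"], (28 + 35) / 2)
  # the "all" row equals the summary of the concatenated groups
  expect_equal(out[out$group == "all", -1], summarize_scores(s)[, -1])
})

test_that("grouping joins case attributes and fails on unresolvable ones", {
  cohort <- generate_cohort(cohort_config(n = 40, seed = 8))
  sheets <- score_cases(cohort)
  out <- summarize_scores(sheets, by = "planned_procedure_class", cases = cohort)
  expect_setequal(setdiff(out$group, "all"),
                  unique(cohort$planned_procedure_class))
  expect_equal(out$n[out$group == "all"], 40L)
  expect_error(summarize_scores(sheets, by = "nonexistent", cases = cohort),
               "nonexistent", class = "mentsr_group_error")
})

test_that("histogram conserves counts and flags out-of-range totals", {
  ends <- make_sheets(c("lo", "hi"), c(16L, 80L))
  h <- score_histogram(ends)
  expect_equal(h$count[1], 1L)
  expect_equal(h$count[nrow(h)], 1L)
  expect_equal(sum(h$count), 2L)
  empty <- score_histogram(make_sheets(character(), integer()))
  expect_true(all(empty$count == 0L))
  cohort <- generate_cohort(cohort_config(n = 100, seed = 2))
  expect_equal(sum(score_histogram(score_cases(cohort))$count), 100L)
  expect_error(score_histogram(make_sheets("x", 81L)),
               class = "mentsr_sheet_error")
})

test_that("tier crosswalk flags median monotonicity across acuity tiers", {
  tiers <- rep(c("high", "intermediate", "low"), each = 3)
  mono <- make_sheets(paste0("c", 1:9), c(19L, 20L, 21L, 23L, 24L, 25L,
                                          27L, 28L, 29L))
  mono$acuity_tier <- tiers
  cw <- tier_crosswalk(mono)
  expect_true(glance(cw)$monotone)
  expect_equal(tidy(cw)$group, c("high", "intermediate", "low"))
  expect_equal(tidy(cw)$total_median, c(20, 24, 28))
  broken <- mono
  broken$total <- c(23L, 24L, 25L, 19L, 20L, 21L, 27L, 28L, 29L)
  broken$patient_subtotal <- broken$total
  expect_false(glance(tier_crosswalk(broken))$monotone)
  missing <- mono
  missing$acuity_tier[1] <- NA
  expect_error(tier_crosswalk(missing), class = "mentsr_group_error")
})

test_that("disease-dominant high-acuity cases outrank identical low-acuity ones", {
  urgent <- complete_case(case_id = "urgent",
                          nonoperative_effectiveness = "none_available",
                          nonoperative_resource_use = "very_high",
                          delay_impact_3_6mo = "life_threatening",
                          delay_impact_gt6mo = "life_threatening",
                          acuity_tier = "high")
  middling <- complete_case(case_id = "middling", acuity_tier = "intermediate")
  deferrable <- complete_case(case_id = "deferrable",
                              nonoperative_effectiveness = "highly_effective",
                              nonoperative_resource_use = "minimal",
                              delay_impact_3_6mo = "none",
                              delay_impact_gt6mo = "none",
                              acuity_tier = "low")
  cases <- dplyr::bind_rows(urgent, middling, deferrable)
  sheets <- score_cases(cases)
  expect_lt(sheets$total[1], sheets$total[3])
  cw <- tier_crosswalk(sheets, cases)
  expect_true(glance(cw)$monotone)
  q <- rank_cases(sheets)
  expect_equal(q$case_id[1], "urgent")
  expect_equal(q$case_id[3], "deferrable")
})

test_that("mean aggregation averages the paired sheets", {
  cohort <- generate_cohort(cohort_config(n = 20, seed = 4))
  pair <- simulate_rater_pair(cohort, noise = rater_noise(0.5, seed = 4))
  agg <- aggregate_sheets(pair$attending, pair$trainee, method = "mean")
  expect_equal(agg$total, (pair$attending$total + pair$trainee$total) / 2)
  att <- aggregate_sheets(pair$attending, pair$trainee)
  expect_equal(att, pair$attending)
})
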