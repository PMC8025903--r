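#' Largest-remainder apportionment of n units to categories
#'
#' Deterministically converts fractional proportions into integer counts that
#' sum exactly to `n`: floor each `n * p`, then hand the remaining units to
#' categories in order of descending fractional remainder (ties broken by
#' declared category order). This is how the default cohort configuration
#' turns published percentage marginals into exact per-category counts.
#'
#' @param n Total units (non-negative integer).
#' @param proportions Named numeric vector of non-negative proportions summing
#'   to 1 (tolerance 1e-9).
#' @return Named integer vector of counts summing to `n`.
#' @export
#' @examples
#' allocate_counts(7, c(a = 0.5, b = 0.3, c = 0.2))
allocate_counts <- function(n, proportions) {
  p <- unlist(proportions)
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    rlang::abort("proportions must be named", class = "mentsr_config_error")
  }
  if (any(p < 0)) {
    rlang::abort("proportions must be non-negative",
                 class = "mentsr_config_error")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    rlang::abort(paste0("proportions must sum to 1, got ", sum(p)),
                 class = "mentsr_config_error")
  }
  raw <- n * p
  counts <- floor(raw)
  remainder <- n - sum(counts)
  if (remainder > 0) {
    frac <- raw - counts
    extra <- order(-frac, seq_along(p))[seq_len(remainder)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

# Table-1 categorical marginals as exact count/392 fractions. Severity splits
# within the lung/CV/diabetes totals, smoking and OSA are not published and
# are package defaults (see the methods vignette).
table1_marginals <- function() {
  list(
    race_ethnicity = c(latina = 293, black = 19, asian_pi = 15, white = 12,
                       other = 53) / 392,
    menopausal_status = c(pre = 263, post = 129) / 392,
    lung_disease = c(none = 349, controlled_asthma = 25,
                     uncontrolled_asthma = 10, copd = 6, severe_copd = 2) / 392,
    smoking_status = c(never = 0.70, former = 0.18, current = 0.12),
    osa_status = c(none = 0.85, treated = 0.09, untreated = 0.06),
    cardiovascular_disease = c(none = 187, controlled_htn = 140,
                               uncontrolled_htn = 40, stable_cad_or_chf = 20,
                               multiple_uncontrolled_cv = 5) / 392,
    diabetes_status = c(none = 338, diet_controlled = 20, medicated = 34) / 392,
    immunocompromised = c(false = 373, true = 19) / 392,
    covid_status = c(negative = 6, unknown = 386, positive = 0) / 392,
    indication = c(aub = 130, prolapse_incontinence = 77, adnexal_mass = 56,
                   precancer = 29, contraception = 26, cancer = 7,
                   other = 67) / 392,
    planned_procedure_class = c(open_abdominal = 56, mis = 215,
                                other = 121) / 392
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The defaults transcribe the published characteristics of a 392-patient
#' gynecologic surgical waitlist cohort: exact categorical counts for
#' race/ethnicity, menopausal status, lung/cardiovascular disease, diabetes,
#' immunocompromise, COVID status, surgical indication and planned approach,
#' and median/range anchors for age (46, 20-86), BMI (30.7, 17.8-67.3) and
#' parity (2, 0-8). Attributes the source table does not report (smoking, OSA
#' control, severity splits, HbA1c, site split) carry fixed package defaults.
#'
#' @param n Cohort size (default 392).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   config.
#' @param categorical_marginals Named list of named proportion vectors; each
#'   must sum to 1.
#' @param continuous_anchors Named list of `c(min, median, max)` anchors for
#'   `age`, `bmi`, `parity` and `hba1c`.
#' @param site_split Named proportions of cases across sites.
#' @param template_jitter Probability that a template-derived disease-factor
#'   level is shifted one step (either direction, clipped to the domain).
#' @return A validated `ments_cohort_config`.
#' @export
cohort_config <- function(n = 392L,
                          seed = 1L,
                          categorical_marginals = table1_marginals(),
                          continuous_anchors = list(
                            age = c(min = 20, median = 46, max = 86),
                            bmi = c(min = 17.8, median = 30.7, max = 67.3),
                            parity = c(min = 0, median = 2, max = 8),
                            hba1c = c(min = 5.8, median = 7.6, max = 11.2)
                          ),
                          site_split = c(site_a = 1, site_b = 1, site_c = 1) / 3,
                          template_jitter = 0.15) {
  if (n < 1) rlang::abort("n must be >= 1", class = "mentsr_config_error")
  for (attr in names(categorical_marginals)) {
    p <- categorical_marginals[[attr]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      rlang::abort(paste0("marginals for '", attr,
                          "' must be non-negative and sum to 1"),
                   class = "mentsr_config_error")
    }
  }
  for (attr in names(continuous_anchors)) {
    a <- continuous_anchors[[attr]]
    if (!(a[["min"]] <= a[["median"]] && a[["median"]] <= a[["max"]])) {
      rlang::abort(paste0("infeasible anchors for '", attr,
                          "': need min <= median <= max"),
                   class = "mentsr_config_error")
    }
  }
  if (abs(sum(site_split) - 1) > 1e-9 || any(site_split < 0)) {
    rlang::abort("site_split must be non-negative and sum to 1",
                 class = "mentsr_config_error")
  }
  if (template_jitter < 0 || template_jitter > 1) {
    rlang::abort("template_jitter must be in [0, 1]",
                 class = "mentsr_config_error")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 categorical_marginals = categorical_marginals,
                 continuous_anchors = continuous_anchors,
                 site_split = site_split,
                 template_jitter = template_jitter),
            class = "ments_cohort_config")
}

# two-piece sampler anchored at (min, median, max): each half is a triangular
# density peaking at the median, so the sample median concentrates at the
# anchor and all draws stay inside [min, max]
rtwopiece <- function(n, min, median, max) {
  left <- stats::runif(n) < 0.5
  v <- stats::runif(n)
  out <- numeric(n)
  out[left] <- min + (median - min) * sqrt(v[left])
  out[!left] <- max - (max - median) * sqrt(v[!left])
  out
}

# indication-specific templates for procedure and disease attributes, plus the
# diagnosis-driven acuity tier; planned-class overrides applied afterwards
indication_template <- function(indication) {
  switch(indication,
    aub = list(or_time = 25, los = "outpatient", icu = "very_unlikely",
               anesthesia = "general_lma", site = "external_or_intrauterine",
               eff = "partially_effective", resource = "moderate",
               d36 = "moderate", dgt6 = "significant", tier = "intermediate"),
    prolapse_incontinence = list(or_time = 60, los = "outpatient",
               icu = "very_unlikely", anesthesia = "regional", site = "vaginal",
               eff = "moderately_effective", resource = "low",
               d36 = "mild", dgt6 = "moderate", tier = "low"),
    adnexal_mass = list(or_time = 90, los = "lt24h", icu = "very_unlikely",
               anesthesia = "geta", site = "laparoscopic_robotic",
               eff = "minimally_effective", resource = "moderate",
               d36 = "significant", dgt6 = "significant", tier = "high"),
    precancer = list(or_time = 40, los = "outpatient", icu = "very_unlikely",
               anesthesia = "general_lma", site = "external_or_intrauterine",
               eff = "minimally_effective", resource = "moderate",
               d36 = "moderate", dgt6 = "significant", tier = "intermediate"),
    contraception = list(or_time = 45, los = "outpatient",
               icu = "very_unlikely", anesthesia = "geta",
               site = "laparoscopic_robotic", eff = "highly_effective",
               resource = "minimal", d36 = "none", dgt6 = "none", tier = "low"),
    cancer = list(or_time = 240, los = "d2_3", icu = "possible",
               anesthesia = "geta", site = "open_abdominal",
               eff = "none_available", resource = "very_high",
               d36 = "life_threatening", dgt6 = "life_threatening",
               tier = "high"),
    other = list(or_time = 60, los = "outpatient", icu = "very_unlikely",
               anesthesia = "mac", site = "external_or_intrauterine",
               eff = "moderately_effective", resource = "low",
               d36 = "mild", dgt6 = "mild", tier = "low"),
    rlang::abort(paste0("no template for indication '", indication, "'"),
                 class = "mentsr_config_error")
  )
}

los_order <- c("outpatient", "lt24h", "h24_48", "d2_3", "gt3d")

apply_class_override <- function(tmpl, class, indication) {
  worst_los <- function(a, b) {
    los_order[max(match(a, los_order), match(b, los_order))]
  }
  if (class == "open_abdominal") {
    tmpl$site <- "open_abdominal"
    tmpl$anesthesia <- "geta"
    tmpl$or_time <- max(tmpl$or_time, 160)
    tmpl$los <- worst_los(tmpl$los, "d2_3")
    tmpl$icu <- if (tmpl$icu == "very_unlikely") "unlikely" else tmpl$icu
  } else if (class == "mis") {
    tmpl$site <- if (indication == "prolapse_incontinence") "vaginal"
                 else "laparoscopic_robotic"
    tmpl$anesthesia <- "geta"
    tmpl$or_time <- max(tmpl$or_time, 100)
    tmpl$los <- worst_los(tmpl$los, "lt24h")
  }
  tmpl
}

# shift a categorical level one step within its ordered domain with prob p
jitter_level <- function(values, domain, p) {
  idx <- match(values, domain)
  move <- stats::runif(length(idx)) < p
  dir <- sample(c(-1L, 1L), length(idx), replace = TRUE)
  idx <- pmin(pmax(idx + move * dir, 1L), length(domain))
  domain[idx]
}

#' Generate a synthetic surgical-waitlist cohort
#'
#' Draws `config$n` case records whose categorical marginals match the
#' configured proportions *exactly* (largest-remainder allocation followed by
#' a seeded shuffle; attributes are jointly independent), whose continuous
#' attributes come from a two-piece triangular-tail sampler anchored at the
#' configured (min, median, max), and whose procedure/disease attributes are
#' filled from indication- and approach-conditional templates with small
#' seeded jitter on the disease levels. Reproducible: the same config always
#' yields the same records.
#'
#' @param config A [cohort_config()].
#' @return A tibble of case records, one row per surgical candidate, ready for
#'   [score_cases()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 10, seed = 42))
#' dplyr::count(cohort, indication)
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "ments_cohort_config")) {
    rlang::abort("config must be created with cohort_config()",
                 class = "mentsr_config_error")
  }
  n <- config$n
  withr::with_seed(config$seed, {
    draw_categorical <- function(p) {
      counts <- allocate_counts(n, p)
      vals <- rep(names(counts), counts)
      if (n > 1) vals <- vals[sample.int(n)]
      vals
    }
    m <- config$categorical_marginals
    cases <- tibble::tibble(
      case_id = sprintf("case_%04d", seq_len(n)),
      site_id = draw_categorical(config$site_split),
      age = rtwopiece(n, config$continuous_anchors$age[["min"]],
                      config$continuous_anchors$age[["median"]],
                      config$continuous_anchors$age[["max"]]),
      bmi = round(rtwopiece(n, config$continuous_anchors$bmi[["min"]],
                            config$continuous_anchors$bmi[["median"]],
                            config$continuous_anchors$bmi[["max"]]), 1),
      parity = as.integer(round(rtwopiece(
        n, config$continuous_anchors$parity[["min"]],
        config$continuous_anchors$parity[["median"]],
        config$continuous_anchors$parity[["max"]]))),
      menopausal_status = draw_categorical(m$menopausal_status),
      race_ethnicity = draw_categorical(m$race_ethnicity),
      lung_disease = draw_categorical(m$lung_disease),
      smoking_status = draw_categorical(m$smoking_status),
      osa_status = draw_categorical(m$osa_status),
      cardiovascular_disease = draw_categorical(m$cardiovascular_disease),
      diabetes_status = draw_categorical(m$diabetes_status),
      immunocompromised = draw_categorical(m$immunocompromised) == "true",
      covid_status = draw_categorical(m$covid_status),
      indication = draw_categorical(m$indication),
      planned_procedure_class = draw_categorical(m$planned_procedure_class)
    )
    cases$age <- round(cases$age, 1)
    cases$hba1c <- ifelse(
      cases$diabetes_status == "medicated",
      round(rtwopiece(n, config$continuous_anchors$hba1c[["min"]],
                      config$continuous_anchors$hba1c[["median"]],
                      config$continuous_anchors$hba1c[["max"]]), 1),
      NA_real_)
    cases$diabetes_end_organ <- ifelse(cases$diabetes_status == "medicated",
                                       "unknown", "none")

    tmpl <- purrr::map2(cases$indication, cases$planned_procedure_class,
                        function(ind, cls) {
                          apply_class_override(indication_template(ind), cls, ind)
                        })
    pull <- function(field) purrr::map_chr(tmpl, ~ as.character(.x[[field]]))
    cases$expected_or_time <- pmax(
      10, purrr::map_dbl(tmpl, "or_time") + round(stats::rnorm(n, 0, 15)))
    cases$expected_los <- pull("los")
    cases$icu_need <- pull("icu")
    cases$least_invasive_anesthesia <- pull("anesthesia")
    cases$surgical_site_approach <- pull("site")
    j <- config$template_jitter
    eff_dom <- c("none_available", "minimally_effective", "partially_effective",
                 "moderately_effective", "highly_effective")
    res_dom <- c("very_high", "high", "moderate", "low", "minimal")
    delay_dom <- c("life_threatening", "significant", "moderate", "mild", "none")
    cases$nonoperative_effectiveness <- jitter_level(pull("eff"), eff_dom, j)
    cases$nonoperative_resource_use <- jitter_level(pull("resource"), res_dom, j)
    cases$delay_impact_3_6mo <- jitter_level(pull("d36"), delay_dom, j)
    cases$delay_impact_gt6mo <- jitter_level(pull("dgt6"), delay_dom, j)
    cases$acuity_tier <- pull("tier")
    cases
  })
}

#' Rater disagreement model for simulated score-sheet pairs
#'
#' Models a second rater who, independently per factor, shifts the first
#' rater's 1-5 score by one point (either direction with equal probability)
#' with probability `p_disagree`, plus an optional systematic per-factor
#' offset; results are clipped to the 1-5 scale so all sheet invariants hold.
#'
#' @param p_disagree Per-factor disagreement probability in `[0, 1]`.
#' @param systematic_shift Integer added to every factor score before clipping
#'   (a deliberate rater bias; absolute-agreement ICC is sensitive to it).
#' @param seed Optional integer seed for the perturbation; `NULL` uses the
#'   current RNG stream.
#' @return A `ments_rater_noise` list.
#' @export
rater_noise <- function(p_disagree = 0.3, systematic_shift = 0L, seed = NULL) {
  if (p_disagree < 0 || p_disagree > 1) {
    rlang::abort("p_disagree must be in [0, 1]", class = "mentsr_config_error")
  }
  structure(list(p_disagree = p_disagree,
                 systematic_shift = as.integer(systematic_shift),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "ments_rater_noise")
}

#' Simulate a blinded attending/trainee scoring pair
#'
#' The attending sheet is the deterministic rubric score of each case; the
#' trainee sheet perturbs the attending's factor scores under the given noise
#' model. With zero disagreement the two sheets are identical and the
#' downstream ICC is exactly 1.
#'
#' @param cases Case-record tibble.
#' @param rubric Rubric to score under.
#' @param noise A [rater_noise()] model.
#' @return Named list with `attending` and `trainee` score-sheet tibbles.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 8, seed = 7))
#' pair <- simulate_rater_pair(cohort, noise = rater_noise(0.3, seed = 7))
#' rating_matrix(pair$attending, pair$trainee)
simulate_rater_pair <- function(cases, rubric = default_rubric(),
                                noise = rater_noise()) {
  attending <- score_cases(cases, rubric, rater_id = "attending_1",
                           rater_role = "attending")
  ids <- rubric_factor_ids(rubric)
  perturb <- function() {
    fs <- as.matrix(attending[ids])
    disagree <- matrix(stats::runif(length(fs)) < noise$p_disagree, nrow(fs))
    dir <- matrix(sample(c(-1L, 1L), length(fs), replace = TRUE), nrow(fs))
    shifted <- fs + disagree * dir + noise$systematic_shift
    pmin(pmax(shifted, 1L), 5L)
  }
  shifted <- if (is.null(noise$seed)) perturb() else {
    withr::with_seed(noise$seed, perturb())
  }
  trainee <- attending
  trainee$rater_id <- "trainee_1"
  trainee$rater_role <- "trainee"
  trainee[ids] <- tibble::as_tibble(shifted)
  trainee <- finalize_sheets(trainee, rubric)
  list(attending = attending, trainee = trainee)
}
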