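# complete single case records used across tests; defaults are the worked
# example (46-y-old premenopausal never-smoker, BMI 30.7, no comorbidities,
# COVID unknown, hysteroscopy for AUB)
complete_case <- function(...) {
  base <- tibble::tibble(
    case_id = "case_x", site_id = "site_a",
    age = 46, bmi = 30.7, parity = 2,
    menopausal_status = "pre", race_ethnicity = "latina",
    lung_disease = "none", smoking_status = "never", osa_status = "none",
    cardiovascular_disease = "none",
    diabetes_status = "none", hba1c = NA_real_, diabetes_end_organ = "none",
    immunocompromised = FALSE, covid_status = "unknown",
    expected_or_time = 25, expected_los = "outpatient",
    icu_need = "very_unlikely", least_invasive_anesthesia = "general_lma",
    surgical_site_approach = "external_or_intrauterine",
    nonoperative_effectiveness = "moderately_effective",
    nonoperative_resource_use = "low",
    delay_impact_3_6mo = "none", delay_impact_gt6mo = "moderate",
    indication = "aub", planned_procedure_class = "other",
    acuity_tier = "intermediate"
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# a case matching every level-1 criterion of the default rubric
min_case <- function(case_id = "case_min") {
  complete_case(
    case_id = case_id, age = 18, bmi = 25, covid_status = "negative",
    expected_or_time = 20, least_invasive_anesthesia = "local",
    nonoperative_effectiveness = "none_available",
    nonoperative_resource_use = "very_high",
    delay_impact_3_6mo = "life_threatening",
    delay_impact_gt6mo = "life_threatening",
    acuity_tier = "high"
  )
}

# a case matching every level-5 criterion of the default rubric
max_case <- function(case_id = "case_max") {
  complete_case(
    case_id = case_id, age = 70, bmi = 55,
    lung_disease = "severe_copd", smoking_status = "current",
    osa_status = "untreated",
    cardiovascular_disease = "multiple_uncontrolled_cv",
    diabetes_status = "medicated", hba1c = 9.5, diabetes_end_organ = "present",
    immunocompromised = TRUE, covid_status = "positive",
    expected_or_time = 300, expected_los = "gt3d", icu_need = "expected",
    least_invasive_anesthesia = "geta", surgical_site_approach = "open_complex",
    nonoperative_effectiveness = "highly_effective",
    nonoperative_resource_use = "minimal",
    delay_impact_3_6mo = "none", delay_impact_gt6mo = "none",
    acuity_tier = "low"
  )
}

# parsed packaged rubric document, ready for targeted corruption
rubric_doc <- function() {
  jsonlite::read_json(system.file("extdata", "modified_ments_rubric.json",
                                  package = "mentsr"),
                      simplifyVector = FALSE)
}

write_doc_json <- function(doc) {
  path <- withr::local_tempfile(fileext = ".json",
                                .local_envir = parent.frame())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", digits = NA)
  path
}
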