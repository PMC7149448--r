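# Default covariate dictionary and effect configuration.
#
# The covariate dictionary drives both sides of the package: the synthetic
# generator draws each flag at its default prevalence and emits claims/fills
# that encode it, and the covariate engine reconstructs the flag from those
# records via the named codeset. Default prevalences for conditions mirror the
# published cohort's clinical-characteristics table; drug-class prevalences are
# not published and were fixed once at values realistic for an elderly,
# mostly male veteran cohort (see the methods vignette).

#' Covariate dictionary
#'
#' One row per binary baseline covariate assessed over the pre-index year:
#' the covariate name, the record kind it is ascertained from, the codeset
#' that defines it, its default simulation prevalence, and whether it is on
#' the rare-covariate keep list (exempt from the <1% pruning rule).
#'
#' @return a `data.table` with columns `covariate`, `kind`
#'   (`diagnosis`/`procedure`/`drug_class`), `codeset`, `prevalence`, `keep`.
#' @export
covariate_defs <- function() {
  dt <- data.table::rbindlist(list(
    # conditions (diagnosis claims)
    d("hypertension",             "diagnosis", 0.8302),
    d("coronary_artery_disease",  "diagnosis", 0.4154),
    d("diabetes_mellitus",        "diagnosis", 0.3965),
    d("osteoarthritis",           "diagnosis", 0.3696),
    d("congestive_heart_failure", "diagnosis", 0.1698),
    d("chronic_kidney_disease",   "diagnosis", 0.1508),
    d("cerebrovascular_disease",  "diagnosis", 0.1259),
    d("unstable_angina",          "diagnosis", 0.1174),
    d("hemorrhoids",              "diagnosis", 0.0991),
    d("stable_angina",            "diagnosis", 0.0886),
    d("constipation_prior_year",  "diagnosis", 0.0855, codeset = "constipation_dx"),
    d("stroke",                   "diagnosis", 0.0732),
    d("myopathies",               "diagnosis", 0.0484),
    d("migraine_headache",        "diagnosis", 0.0434),
    d("diabetic_neuropathy",      "diagnosis", 0.0369),
    d("myocardial_infarction",    "diagnosis", 0.0334),
    d("hyperkalemia",             "diagnosis", 0.0316, keep = TRUE),
    d("fibromyalgia",             "diagnosis", 0.0264),
    d("parkinsons_disease",       "diagnosis", 0.0230),
    d("rheumatoid_arthritis",     "diagnosis", 0.0207),
    d("irritable_bowel_syndrome", "diagnosis", 0.0081, keep = TRUE),
    d("colitis",                  "diagnosis", 0.0068),
    d("gastroparesis",            "diagnosis", 0.0059),
    d("hyperparathyroidism",      "diagnosis", 0.0056),
    d("hypercalcemia",            "diagnosis", 0.0049),
    d("multiple_sclerosis",       "diagnosis", 0.0023),
    # GI anatomical trauma members; OR-combined into one covariate at pruning
    d("gi_perforation",           "diagnosis", 0.0008),
    d("rectal_prolapse",          "diagnosis", 0.0008),
    d("rectocele",                "diagnosis", 0.0006),
    d("megacolon",                "diagnosis", 0.0004),
    d("impaction",                "diagnosis", 0.0002),
    d("anal_fissure",             "diagnosis", 0.0008),
    # procedures
    d("revascularization_cabg",   "procedure", 0.1214),
    # VA drug-class medication exposures (pre-index year)
    d("anticoagulants_bl110",     "drug_class", 0.150),
    d("antilipemic_cv350",        "drug_class", 0.500),
    d("beta_blockers_cv100",      "drug_class", 0.400),
    d("quinolones_am400",         "drug_class", 0.080),
    d("erythromycins_am200",      "drug_class", 0.050),
    d("antihistamines_ah000",     "drug_class", 0.100),
    d("genitourinary_gu000",      "drug_class", 0.100),
    d("insulin_hs501",            "drug_class", 0.120),
    d("androgens_hs100",          "drug_class", 0.015),
    d("antipsychotics_cn700",     "drug_class", 0.030),
    d("nsaid_ms102",              "drug_class", 0.150),
    d("topical_analgesics_de650", "drug_class", 0.080),
    d("antigout_ms400",           "drug_class", 0.050)
  ))
  dt
}

d <- function(covariate, kind, prevalence, codeset = covariate, keep = FALSE) {
  data.table::data.table(covariate = covariate, kind = kind, codeset = codeset,
                         prevalence = prevalence, keep = keep)
}

#' GI anatomical trauma member covariates
#'
#' Low-frequency possible sequelae of constipation that are aggregated into a
#' single `gi_anatomical_trauma` covariate before rare-covariate pruning.
#'
#' @return character vector of member covariate names.
#' @export
gi_trauma_members <- function() {
  c("gi_perforation", "rectal_prolapse", "rectocele",
    "megacolon", "impaction", "anal_fissure")
}

#' Default rare-covariate keep list
#'
#' Covariates exempt from the <1% prevalence pruning rule: rare race values,
#' the aggregated GI anatomical trauma flag, hyperkalemia, and irritable
#' bowel syndrome.
#'
#' @return character vector of covariate names.
#' @export
default_keep_list <- function() {
  c("race_asian_pacific", "race_american_indian",
    "gi_anatomical_trauma", "hyperkalemia", "irritable_bowel_syndrome")
}

#' Default true log hazard ratios for the simulator
#'
#' Named vector of log hazard ratios used as the generator's
#' proportional-hazards truth. Values are the natural logs of the adjusted
#' hazard ratios the study reported for its significant covariates; every
#' covariate not named here has true log-HR 0.
#'
#' @return named numeric vector.
#' @export
default_log_hazard_ratios <- function() {
  log(c(
    constipation_prior_year       = 2.25,
    laxative_prevalent            = 2.11,
    laxative_prior_not_prevalent  = 0.84,
    constip_days_365_to_61        = 0.82,
    myocardial_infarction         = 1.30,
    unstable_angina               = 1.13,
    congestive_heart_failure      = 1.18,
    cerebrovascular_disease       = 1.16,
    fibromyalgia                  = 0.87,
    rheumatoid_arthritis          = 0.89,
    revascularization_cabg        = 0.87,
    anticoagulants_bl110          = 1.11,
    antilipemic_cv350             = 0.89,
    beta_blockers_cv100           = 0.88,
    quinolones_am400              = 1.26,
    erythromycins_am200           = 0.77,
    antihistamines_ah000          = 0.90,
    genitourinary_gu000           = 0.86,
    insulin_hs501                 = 0.84,
    androgens_hs100               = 0.77,
    antipsychotics_cn700          = 1.27,
    nsaid_ms102                   = 0.88,
    topical_analgesics_de650      = 0.84,
    antigout_ms400                = 0.80,
    race_african_american         = 1.32,
    race_unknown                  = 0.75
  ))
}

#' Default laboratory test parameters for the simulator
#'
#' Per-test population mean, SD, and marginal missingness probability
#' (missingness is made MAR by tilting on age; see the methods vignette).
#'
#' @return data.table with columns `test`, `mean`, `sd`, `miss`.
#' @export
default_lab_params <- function() {
  data.table::data.table(
    test = c("bicarbonate_co2", "hemoglobin", "creatinine", "magnesium"),
    mean = c(26, 14, 1.1, 2.0),
    sd   = c(3, 1.5, 0.35, 0.25),
    miss = c(0.25, 0.30, 0.40, 0.55)
  )
}

#' Default race category probabilities
#' @return named numeric vector summing to 1 (reference category `white`).
#' @export
default_race_probs <- function() {
  c(white = 0.7359, african_american = 0.0960, unknown = 0.1490,
    asian_pacific = 0.0139, american_indian = 0.0052)
}
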