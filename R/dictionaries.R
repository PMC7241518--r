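#' Synthetic drug dictionary
#'
#' A small NDC-like dictionary used by the claims simulator and by the
#' morphine-equivalence (MEQ) calculations. Strengths and conversion factors
#' are plausible values for common agents; they are simulator assumptions,
#' not a published conversion table, and can be replaced wholesale by passing
#' a different dictionary to [sim_config()].
#'
#' `meq_factor` is the oral-morphine-equivalence multiplier per milligram and
#' is present only for opioid classes (`ERLA_opioid`, `IR_opioid`).
#' Buprenorphine-type products are classed `OUD_treatment`, never
#' `ERLA_opioid`, so they cannot qualify a patient's index date.
#'
#' @return data.frame with columns `drug_code`, `drug_class`, `drug_name`,
#'   `mg_per_unit`, `meq_factor`, `high_strength`.
#' @export
default_drug_dictionary <- function() {
  df <- read.csv(text = "
drug_code,drug_class,drug_name,mg_per_unit,meq_factor,high_strength
ERLA001,ERLA_opioid,morphine SR 30mg,30,1,FALSE
ERLA002,ERLA_opioid,morphine SR 60mg,60,1,TRUE
ERLA003,ERLA_opioid,oxycodone ER 20mg,20,1.5,FALSE
ERLA004,ERLA_opioid,oxycodone ER 40mg,40,1.5,TRUE
ERLA005,ERLA_opioid,methadone 10mg,10,3,TRUE
ERLA006,ERLA_opioid,fentanyl TD 25mcg/hr,1.7,7.2,TRUE
IR001,IR_opioid,hydrocodone 5mg,5,1,FALSE
IR002,IR_opioid,oxycodone IR 5mg,5,1.5,FALSE
IR003,IR_opioid,oxycodone IR 10mg,10,1.5,TRUE
IR004,IR_opioid,hydromorphone 2mg,2,4,TRUE
IR005,IR_opioid,tramadol 50mg,50,0.1,FALSE
BZD001,benzodiazepine,diazepam 5mg,5,NA,FALSE
BZD002,benzodiazepine,alprazolam 0.5mg,0.5,NA,FALSE
BZD003,benzodiazepine,lorazepam 1mg,1,NA,FALSE
PSY001,other_psychoactive,amitriptyline 25mg,25,NA,FALSE
PSY002,other_psychoactive,zolpidem 10mg,10,NA,FALSE
PSY003,other_psychoactive,carisoprodol 350mg,350,NA,FALSE
PSY004,other_psychoactive,sertraline 50mg,50,NA,FALSE
OUD001,OUD_treatment,buprenorphine-naloxone 8mg,8,NA,FALSE
OUD002,OUD_treatment,naltrexone 50mg,50,NA,FALSE
OTH001,other,lisinopril 10mg,10,NA,FALSE
OTH002,other,metformin 500mg,500,NA,FALSE
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

#' Diagnosis code groups (ICD-9-style prefixes)
#'
#' Named list of code prefixes used for predictor construction, enrichment
#' strata, and the ICD-9 comparator classifier. Matching is by string prefix
#' (`"304."` matches `"304.01"`). The `oud_comparator` group is the
#' dependence/abuse/poisoning list used for both the enrichment stratum and
#' the comparator algorithm; heroin-specific poisoning codes (965.01, E850.0)
#' are deliberately excluded from it and carried in `heroin` instead. The
#' opioid-abuse family is represented by 305.5x so that non-opioid 305.x
#' codes (e.g. tobacco, 305.1) never enter the comparator.
#'
#' @return named list of character vectors of code prefixes.
#' @export
default_code_groups <- function() {
  list(
    opioid_dependence   = c("304.0", "304.7"),
    opioid_abuse        = c("305.5"),
    opioid_poisoning    = c("965.00", "965.02", "965.09", "E850.1", "E850.2"),
    heroin              = c("965.01", "E850.0"),
    oud_comparator      = c("304.0", "304.7", "305.5",
                            "965.00", "965.02", "965.09", "E850.1", "E850.2"),
    pain_back           = c("724."),
    pain_neck           = c("723."),
    headache            = c("784.0", "346."),
    neuropathic_pain    = c("729.2"),
    fibromyalgia        = c("729.1"),
    arthritis           = c("715."),
    depression          = c("296.2", "296.3", "311."),
    anxiety             = c("300.0"),
    bipolar             = c("296.4", "296.5", "296.6", "296.7"),
    schizophrenia       = c("295."),
    other_mental_health = c("300.4", "309.0"),
    ptsd                = c("309.81"),
    domestic_violence   = c("E967", "V61.1"),
    alcohol_disorder    = c("303."),
    cannabis_dependence = c("304.3"),
    other_drug_dependence = c("304.4", "304.6", "304.8", "304.9"),
    nondependent_abuse  = c("305.2", "305.3", "305.4", "305.6", "305.7", "305.9"),
    tobacco             = c("305.1"),
    sleep_disorder      = c("327.", "780.52"),
    hepatitis_cirrhosis = c("571.", "070."),
    endocarditis        = c("421."),
    adverse_drug_ecodes = c("E935", "E937", "E939"),
    # simplified Charlson categories (representative prefixes)
    charlson_mi         = c("410.", "412."),
    charlson_chf        = c("428."),
    charlson_pvd        = c("443.9"),
    charlson_cvd        = c("430.", "434."),
    charlson_dementia   = c("290."),
    charlson_copd       = c("491.", "492.", "496."),
    charlson_rheum      = c("714.0"),
    charlson_pud        = c("533."),
    charlson_liver_mild = c("571.2", "571.5"),
    charlson_diabetes   = c("250.0"),
    charlson_diabetes_c = c("250.4"),
    charlson_hemiplegia = c("342."),
    charlson_renal      = c("585."),
    charlson_cancer     = c("153.", "162.", "174."),
    charlson_liver_sev  = c("572.2"),
    charlson_mets       = c("196.", "197."),
    charlson_hiv        = c("042.")
  )
}

# Standard Charlson weights for the categories above.
charlson_weights <- function() {
  c(charlson_mi = 1, charlson_chf = 1, charlson_pvd = 1, charlson_cvd = 1,
    charlson_dementia = 1, charlson_copd = 1, charlson_rheum = 1,
    charlson_pud = 1, charlson_liver_mild = 1, charlson_diabetes = 1,
    charlson_diabetes_c = 2, charlson_hemiplegia = 2, charlson_renal = 2,
    charlson_cancer = 2, charlson_liver_sev = 3, charlson_mets = 6,
    charlson_hiv = 6)
}

# TRUE for codes matching any prefix in `prefixes`.
code_matches <- function(codes, prefixes) {
  if (length(codes) == 0) return(logical(0))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}
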