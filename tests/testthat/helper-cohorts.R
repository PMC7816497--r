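# Programmatic fixtures: minimal valid cohorts and stripped-down simulation
# configurations.

# A schema-valid cohort from follow-up times and death indicators; covariates
# default to the reference pattern unless overridden by name.
make_cohort <- function(time, dead, cancer = dead, ...) {
  n <- length(time)
  rec <- data.frame(
    subject_id = sprintf("T%04d", seq_len(n)),
    age_group = "lt65", sex = "male", race = "white",
    marital_status = "married", fnclcc_grade = "I", size_class = "lt5",
    multifocality = "no", histology = "SFT",
    extent_of_resection = "complete",
    radiation = FALSE, chemotherapy = FALSE, chemoradiotherapy = FALSE,
    neoadjuvant_radiation = FALSE, surgery_performed = TRUE,
    primary_tumor = TRUE,
    followup_months = as.integer(time),
    vital_status = ifelse(dead, "dead", "alive"),
    cancer_specific_death = cancer,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  validate_cohort(rec[, rptcs:::rpt_fields])
}

# Simulation config with point-mass covariates except the named binary
# probabilities, one or more hazard intervals, and optional censoring.
simple_config <- function(n, seed = 1, cuts = 0, cancer_rates = 0.01,
                          other_rates = 0, p_age = 0, p_female = 0,
                          p_chemo = 0, loghr_cancer = list(),
                          loghr_other = list(), loss = 0,
                          accrual = 156, admin = 1e6) {
  sim_config(
    n_subjects = n, seed = seed, hazard_cuts = cuts,
    baseline_hazard_cancer = rep_len(cancer_rates, length(cuts)),
    baseline_hazard_other = rep_len(other_rates, length(cuts)),
    covariate_frequencies = list(
      age_group = c(lt65 = 1 - p_age, ge65 = p_age),
      sex = c(male = 1 - p_female, female = p_female),
      race = c(white = 1, black = 0, api = 0, other = 0),
      marital_status = c(married = 1, unmarried = 0, unknown = 0),
      fnclcc_grade = c(I = 1, II = 0, III = 0, unknown = 0),
      size_class = c(lt5 = 1, s5to10 = 0, s10to15 = 0, ge15 = 0, unknown = 0),
      multifocality = c(no = 1, yes = 0),
      histology = c(SFT = 1, MFHC = 0, MPNST = 0, LMS = 0, DDlipo = 0,
                    WDlipo = 0, other = 0),
      extent_of_resection = c(complete = 1, incomplete = 0, unknown = 0),
      treatment = c(neither = 1 - p_chemo, radiation_only = 0,
                    chemotherapy_only = p_chemo, chemoradiotherapy = 0)),
    log_hr_cancer = loghr_cancer, log_hr_other = loghr_other,
    loss_to_followup_rate = loss,
    accrual_window_months = accrual, admin_cutoff_months = admin)
}

# A small cohort with random times/censoring for property checks.
random_small_cohort <- function(n, seed) {
  set.seed(seed)
  time <- sample(0:20, n, replace = TRUE)
  dead <- stats::runif(n) < 0.6
  cancer <- dead & stats::runif(n) < 0.7
  make_cohort(time, dead, cancer)
}
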