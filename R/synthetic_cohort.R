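# Seeded generator of SEER-like cohorts: independent categorical covariates,
# two competing cause-specific piecewise-exponential clocks under proportional
# hazards, uniform accrual with administrative censoring, and random loss to
# follow-up.  Times are floored to whole months to mimic registry granularity.

# Covariate marginals of the emulated cohort.  Marginals reported for the
# registry cohort are used exactly; the remainder of each categorical is a
# documented stand-in split (see the methods vignette).
default_covariate_frequencies <- function() {
  list(
    age_group      = c(lt65 = 0.608, ge65 = 0.392),
    sex            = c(male = 0.457, female = 0.543),
    race           = c(white = 0.795, black = 0.090, api = 0.080, other = 0.035),
    marital_status = c(married = 0.614, unmarried = 0.300, unknown = 0.086),
    fnclcc_grade   = c(I = 0.090, II = 0.060, III = 0.196, unknown = 0.654),
    size_class     = c(lt5 = 0.050, s5to10 = 0.130, s10to15 = 0.200,
                       ge15 = 0.565, unknown = 0.055),
    multifocality  = c(no = 0.861, yes = 0.139),
    histology      = c(SFT = 0.040, MFHC = 0.060, MPNST = 0.030, LMS = 0.240,
                       DDlipo = 0.210, WDlipo = 0.200, other = 0.220),
    extent_of_resection = c(complete = 0.527, incomplete = 0.400, unknown = 0.073),
    # joint adjuvant-treatment cell probabilities, consistent with marginal
    # chemotherapy 13.4%, radiation 24.7%, chemoradiotherapy 4.6%
    treatment      = c(neither = 0.665, radiation_only = 0.201,
                       chemotherapy_only = 0.088, chemoradiotherapy = 0.046)
  )
}

# Log hazard ratios per covariate level (reference levels implicit at 0).
# The cancer-cause clock carries the cause-specific effect estimates; the
# other-cause clock carries the all-cause estimates as a proxy, since no
# other-cause model is available for the emulated cohort.
default_log_hr_cancer <- function() {
  lapply(list(
    age_group     = c(ge65 = 1.698),
    sex           = c(female = 0.814),
    fnclcc_grade  = c(II = 1.942, III = 3.569, unknown = 2.263),
    size_class    = c(s5to10 = 1.048, s10to15 = 1.377, ge15 = 1.843, unknown = 2.366),
    multifocality = c(yes = 0.111),
    histology     = c(MFHC = 2.626, MPNST = 0.727, LMS = 1.496, DDlipo = 1.276,
                      WDlipo = 0.435, other = 1.242),
    chemotherapy  = c(yes = 1.810)
  ), log)
}

default_log_hr_other <- function() {
  lapply(list(
    age_group      = c(ge65 = 1.915),
    sex            = c(female = 0.778),
    marital_status = c(unmarried = 1.078, unknown = 1.282),
    fnclcc_grade   = c(II = 1.846, III = 3.119, unknown = 1.986),
    size_class     = c(s5to10 = 1.105, s10to15 = 1.397, ge15 = 1.832, unknown = 2.623),
    multifocality  = c(yes = 0.588),
    histology      = c(MFHC = 2.942, MPNST = 1.914, LMS = 1.578, DDlipo = 1.404,
                       WDlipo = 0.679, other = 1.361),
    chemotherapy   = c(yes = 1.606)
  ), log)
}

#' Simulation configuration for a synthetic registry cohort
#'
#' The defaults emulate the reference cohort of 1,594 resected primary
#' retroperitoneal tumors: reported covariate marginals, cause-specific
#' proportional-hazards effects, diagnosis accrual uniform over a 156-month
#' (2004-2016) window with administrative censoring at the end of the window,
#' and a small exponential loss-to-follow-up rate.  Baseline cause-specific
#' hazards are piecewise constant per month over the cut points and were
#' calibrated once so that pooled OS/CSS at 1/3/5 years and the
#' cancer-specific share of deaths approximate the reported cohort values.
#'
#' @param n_subjects number of subjects.
#' @param covariate_frequencies named list of per-covariate category
#'   probability vectors (each summing to 1).
#' @param hazard_cuts interval start times (months), first must be 0.
#' @param baseline_hazard_cancer,baseline_hazard_other per-month rates for
#'   each interval of `hazard_cuts` (reference covariate pattern).
#' @param log_hr_cancer,log_hr_other named lists of per-level log hazard
#'   ratios acting on the cancer-specific / other-cause clock.
#' @param accrual_window_months length of the diagnosis-date window.
#' @param admin_cutoff_months months from window start to data cutoff.
#' @param loss_to_followup_rate exponential rate per month for random
#'   censoring (0 disables it).
#' @param seed integer RNG seed used by [generate_cohort()].
#' @return an object of class `rpt_sim_config`.
#' @export
sim_config <- function(n_subjects = 1594,
                       covariate_frequencies = default_covariate_frequencies(),
                       hazard_cuts = c(0, 12, 36, 60, 96),
                       baseline_hazard_cancer = NULL,
                       baseline_hazard_other = NULL,
                       log_hr_cancer = default_log_hr_cancer(),
                       log_hr_other = default_log_hr_other(),
                       accrual_window_months = 156,
                       admin_cutoff_months = 156,
                       loss_to_followup_rate = 0.0015,
                       seed = 1L) {
  if (is.null(baseline_hazard_cancer)) {
    baseline_hazard_cancer <- calibrated_baseline_hazards$cancer
  }
  if (is.null(baseline_hazard_other)) {
    baseline_hazard_other <- calibrated_baseline_hazards$other
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    covariate_frequencies = covariate_frequencies,
    hazard_cuts = hazard_cuts,
    baseline_hazard_cancer = baseline_hazard_cancer,
    baseline_hazard_other = baseline_hazard_other,
    log_hr_cancer = log_hr_cancer,
    log_hr_other = log_hr_other,
    accrual_window_months = accrual_window_months,
    admin_cutoff_months = admin_cutoff_months,
    loss_to_followup_rate = loss_to_followup_rate,
    seed = as.integer(seed)
  ), class = "rpt_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "rpt_sim_config"))
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  for (nm in names(cfg$covariate_frequencies)) {
    p <- cfg$covariate_frequencies[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("covariate '%s': probabilities must be non-negative and sum to 1", nm),
           call. = FALSE)
    }
  }
  cuts <- cfg$hazard_cuts
  if (cuts[1] != 0 || is.unsorted(cuts, strictly = TRUE)) {
    stop("hazard_cuts must start at 0 and increase strictly", call. = FALSE)
  }
  for (nm in c("baseline_hazard_cancer", "baseline_hazard_other")) {
    r <- cfg[[nm]]
    if (length(r) != length(cuts) || any(r < 0)) {
      stop(nm, " must give one non-negative rate per hazard interval", call. = FALSE)
    }
  }
  if (cfg$accrual_window_months <= 0 || cfg$admin_cutoff_months <= 0 ||
      cfg$loss_to_followup_rate < 0) {
    stop("accrual window and cutoff must be positive; loss rate non-negative",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Fields absent from the file fall back to the [sim_config()] defaults.
#'
#' @param path YAML file path.
#' @return an `rpt_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown simulation config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in intersect(names(raw), c("covariate_frequencies", "log_hr_cancer",
                                     "log_hr_other"))) {
    raw[[nm]] <- lapply(raw[[nm]], unlist)
  }
  do.call(sim_config, raw)
}

#' Draw covariates for a synthetic cohort
#'
#' Independent categorical draws per covariate; the adjuvant-treatment flags
#' are drawn jointly so that chemoradiotherapy always implies both
#' chemotherapy and radiation.  Consumes the current RNG stream; use
#' [generate_cohort()] for seeded, reproducible cohorts.
#'
#' @param config an `rpt_sim_config`.
#' @return cohort data frame with survival fields unset (`NA`).
#' @export
sample_covariates <- function(config) {
  validate_sim_config(config)
  n <- config$n_subjects
  fr <- config$covariate_frequencies
  draw <- function(p) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }
  rec <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (fld in c("age_group", "sex", "race", "marital_status", "fnclcc_grade",
                "size_class", "multifocality", "histology",
                "extent_of_resection")) {
    rec[[fld]] <- factor(as.character(draw(fr[[fld]])), levels = rpt_levels[[fld]])
  }
  trt <- draw(fr$treatment)
  rec$radiation <- trt %in% c("radiation_only", "chemoradiotherapy")
  rec$chemotherapy <- trt %in% c("chemotherapy_only", "chemoradiotherapy")
  rec$chemoradiotherapy <- trt == "chemoradiotherapy"
  rec$neoadjuvant_radiation <- rep(FALSE, n)
  rec$surgery_performed <- rep(TRUE, n)
  rec$primary_tumor <- rep(TRUE, n)
  rec$followup_months <- rep(NA_integer_, n)
  rec$vital_status <- factor(rep(NA_character_, n), levels = rpt_levels$vital_status)
  rec$cancer_specific_death <- rep(NA, n)
  rec[, rpt_fields]
}

# Per-subject multiplier exp(sum of log-HRs) for one cause's effect list.
effect_multiplier <- function(records, log_hr) {
  lp <- numeric(nrow(records))
  for (cov in names(log_hr)) {
    vals <- records[[cov]]
    if (is.logical(vals)) vals <- ifelse(vals, "yes", "no")
    b <- log_hr[[cov]][as.character(vals)]
    b[is.na(b)] <- 0
    lp <- lp + unname(b)
  }
  exp(lp)
}

# Inverse-CDF sampling of a piecewise-exponential time: given exponential
# targets (cumulative-hazard draws), cut starts and per-interval rates.
rpexp_inverse <- function(target, cuts, rates) {
  k <- length(cuts)
  H <- c(0, cumsum(rates[-k] * diff(cuts)))
  idx <- findInterval(target, H)
  t <- cuts[idx] + (target - H[idx]) / rates[idx]
  t[target >= H[k] & rates[k] == 0] <- Inf
  t
}

#' Simulate competing-cause survival for drawn covariates
#'
#' Draws latent cancer-specific and other-cause death times from
#' piecewise-exponential laws with rates `baseline * exp(sum log-HR)`, an
#' accrual offset uniform on the accrual window, and an independent
#' exponential loss-to-follow-up time.  Observed follow-up is the minimum of
#' the two death times, the loss time, and the administrative horizon,
#' floored to whole months.
#'
#' @param records cohort with covariates populated.
#' @param config an `rpt_sim_config`.
#' @return completed cohort data frame.
#' @export
simulate_survival <- function(records, config) {
  validate_sim_config(config)
  n <- nrow(records)
  m_c <- effect_multiplier(records, config$log_hr_cancer)
  m_o <- effect_multiplier(records, config$log_hr_other)
  t_cancer <- rpexp_inverse(stats::rexp(n) / m_c, config$hazard_cuts,
                            config$baseline_hazard_cancer)
  t_other <- rpexp_inverse(stats::rexp(n) / m_o, config$hazard_cuts,
                           config$baseline_hazard_other)
  accrual <- stats::runif(n, 0, config$accrual_window_months)
  t_admin <- pmax(config$admin_cutoff_months - accrual, 0)
  t_loss <- if (config$loss_to_followup_rate > 0) {
    stats::rexp(n, config$loss_to_followup_rate)
  } else rep(Inf, n)
  t_death <- pmin(t_cancer, t_other)
  t_cens <- pmin(t_loss, t_admin)
  dead <- t_death <= t_cens
  records$followup_months <- as.integer(floor(pmin(t_death, t_cens)))
  records$vital_status <- factor(ifelse(dead, "dead", "alive"),
                                 levels = rpt_levels$vital_status)
  records$cancer_specific_death <- dead & t_cancer <= t_other
  validate_cohort(records)
}

#' Generate a complete seeded synthetic cohort
#'
#' Seeds the RNG from `config$seed`, draws covariates, then survival;
#' identical configurations give identical cohorts.
#'
#' @param config an `rpt_sim_config`.
#' @return completed cohort data frame.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  simulate_survival(sample_covariates(config), config)
}
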