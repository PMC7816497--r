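test_that("conditional survival reproduces the published worked ratios", {
  # printed actual rates -> printed 3-year conditional rates, 1 decimal
  expect_equal(round(conditional_from_rates(89.8, 65.5), 1), 72.9)
  expect_equal(round(conditional_from_rates(60.8, 48.2), 1), 79.3)
  expect_equal(round(conditional_from_rates(91.9, 71.8), 1), 78.1)
  expect_equal(round(conditional_from_rates(67.8, 58.2), 1), 85.8)
  expect_error(conditional_from_rates(0, 50), "positive")
})

test_that("definitional identities hold on fitted curves", {
  coh <- random_small_cohort(60, 901)
  k <- km_curve(coh, "os")
  expect_equal(conditional_survival(k, x = 1, y = 0), 100)
  expect_equal(conditional_survival(k, x = 0, y = 1),
               100 * survival_at(k, 12)$estimate)
  expect_error(conditional_survival(k, x = -1, y = 1), "non-negative")
  expect_error(conditional_survival(k, x = 0, y = 99), "beyond")
})

test_that("conditioning on an exhausted curve is an explicit error", {
  coh <- make_cohort(c(12, 14, 20, 26), dead = c(TRUE, TRUE, TRUE, TRUE))
  k <- km_curve(coh, "os")  # S hits 0 at 26 months
  expect_error(conditional_survival(k, x = 26 / 12, y = 0), "undefined")
})

test_that("telescoping identity holds to numerical precision", {
  for (seed in c(911, 912, 913)) {
    coh <- generate_cohort(simple_config(400, seed = seed, cuts = c(0, 24, 60),
                                         cancer_rates = c(0.02, 0.01, 0.006),
                                         loss = 0.004, admin = 150))
    k <- km_curve(coh, "os")
    max_y <- floor(attr(k, "max_time") / 12)
    for (x in 0:2) {
      for (y1 in 1:2) {
        for (y2 in 1:2) {
          if (x + y1 + y2 > max_y) next
          lhs <- conditional_survival(k, x, y1 + y2)
          rhs <- conditional_survival(k, x, y1) *
            conditional_survival(k, x + y1, y2) / 100
          expect_equal(lhs, rhs, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("cs3 series starts at the actual 3-year rate and pairs actual survival", {
  coh <- generate_cohort(sim_config(n_subjects = 1000, seed = 93))
  k <- km_curve(coh, "css")
  s <- cs3_series(k, x_max = 5)
  expect_equal(s$cs3[s$x == 0], 100 * survival_at(k, 36)$estimate)
  expect_equal(s$actual, 100 * survival_at(k, 12 * (s$x + 3))$estimate)
  expect_equal(attr(s, "endpoint"), "CSS")
})

test_that("insufficient follow-up truncates the series with a warning", {
  coh <- generate_cohort(simple_config(300, seed = 95, cancer_rates = 0.01,
                                       accrual = 60, admin = 60))
  k <- km_curve(coh, "os")  # follow-up < 60 months
  expect_warning(s <- cs3_series(k, x_max = 8), "truncated")
  expect_lt(max(s$x), 8)
})

test_that("cs3 is flat under constant hazard and rises under decreasing hazard", {
  # memorylessness: exponential clock, administrative censoring only
  cfg <- simple_config(30000, seed = 97, cancer_rates = 0.01,
                       accrual = 156, admin = 156)
  s_flat <- cs3_series(km_curve(generate_cohort(cfg), "os"), x_max = 5)
  expect_equal(nrow(s_flat), 6L)
  expect_lt(max(s_flat$cs3) - min(s_flat$cs3), 3)

  cfg_dec <- simple_config(30000, seed = 98, cuts = c(0, 12, 36, 60, 96),
                           cancer_rates = c(0.03, 0.015, 0.008, 0.004, 0.002),
                           accrual = 156, admin = 156)
  s_rise <- cs3_series(km_curve(generate_cohort(cfg_dec), "os"), x_max = 5)
  expect_true(all(diff(s_rise$cs3) > 0))
})

test_that("conditional matrix satisfies its structural invariants", {
  coh <- generate_cohort(sim_config(n_subjects = 2000, seed = 99))
  k <- km_curve(coh, "os")
  m <- conditional_matrix(k, max_total_years = 8)
  for (tot in 1:8) {
    expect_equal(unname(m[as.character(tot), as.character(tot)]), 100)
    row <- m[as.character(tot), as.character(0:tot)]
    row <- row[!is.na(row)]
    expect_true(all(diff(row) >= -1e-9))      # non-decreasing left to right
    expect_true(all(row > 0 & row <= 100 + 1e-9))
  }
  # column x = 0 is the unconditional curve
  expect_equal(unname(m[, "1"][1:8]),
               100 * survival_at(k, 12 * (1:8))$estimate /
                 survival_at(k, 12)$estimate)
  expect_equal(unname(m[, "0"]), 100 * survival_at(k, 12 * (1:8))$estimate)
})

test_that("a no-event cohort gives a matrix of 100s", {
  coh <- make_cohort(rep(120, 30), dead = rep(FALSE, 30))
  m <- conditional_matrix(km_curve(coh, "os"), max_total_years = 5)
  expect_true(all(m[!is.na(m)] == 100))
})

test_that("conditional rates equal the survivor-subset curve when no one censors early", {
  # everyone followed at least 5 years: conditioning = re-estimating on survivors
  set.seed(123)
  time <- 60 + sample(0:60, 80, replace = TRUE)
  dead <- stats::runif(80) < 0.7
  coh <- make_cohort(time, dead)
  k <- km_curve(coh, "os")
  x <- 4
  survivors <- coh[coh$followup_months >= 12 * x, ]
  survivors$followup_months <- survivors$followup_months - as.integer(12 * x)
  k_sub <- km_curve(survivors, "os")
  expect_equal(conditional_survival(k, x, 1),
               100 * survival_at(k_sub, 12)$estimate, tolerance = 1e-10)
})

test_that("standardized difference follows its formula, sign and bands", {
  sd <- standardized_difference(0.905, 0.538, 0.718)
  expect_equal(sd$d, (0.905 - 0.538) / sqrt(0.718 * 0.282), tolerance = 1e-15)
  expect_equal(round(sd$d, 2), 0.82)
  expect_equal(sd$band, "significant")
  # equal rates: exactly zero, band none
  expect_equal(standardized_difference(0.6, 0.6, 0.5)$d, 0)
  expect_equal(standardized_difference(0.6, 0.6, 0.5)$band, "none")
  # sign flips with the order of the pair
  expect_equal(standardized_difference(0.5, 0.7, 0.6)$d,
               -standardized_difference(0.7, 0.5, 0.6)$d)
  expect_error(standardized_difference(0.6, 0.5, 1), "between 0 and 1")
  expect_error(standardized_difference(0, 0.5, 0.5), "group rates")
})

test_that("band classification is exhaustive and mutually exclusive", {
  d <- c(0, 0.05, 0.0999, 0.1, 0.2999, 0.3, 0.4999, 0.5, 2, -0.25, -0.7)
  bands <- d_band(d)
  expect_false(anyNA(bands))
  expect_equal(bands, c("none", "none", "none", "small", "small", "moderate",
                        "moderate", "significant", "significant", "small",
                        "significant"))
})

test_that("stratified series and d-series behave under null and planted effects", {
  # two levels drawn from an identical law: |d| small everywhere
  cfg <- simple_config(20000, seed = 201, cuts = c(0, 36),
                       cancer_rates = c(0.012, 0.007), p_female = 0.5,
                       accrual = 156, admin = 156)
  coh <- generate_cohort(cfg)
  strata <- stratified_cs3(coh, "sex", "os", x_max = 4)
  pooled <- cs3_series(km_curve(coh, "os"), x_max = 4)
  dt <- d_series(strata, pooled, list(c("male", "female")))
  expect_true(all(abs(dt$d) < 0.1))

  # planted grade effect: the worse stratum's cs3 rises more over x
  cfg2 <- simple_config(20000, seed = 202, cuts = c(0, 12, 36, 60),
                        cancer_rates = c(0.02, 0.012, 0.006, 0.003),
                        accrual = 156, admin = 156)
  cfg2$covariate_frequencies$fnclcc_grade <- c(I = 0.5, II = 0, III = 0.5,
                                               unknown = 0)
  cfg2$log_hr_cancer <- list(fnclcc_grade = c(III = log(3.5)))
  coh2 <- generate_cohort(cfg2)
  st2 <- stratified_cs3(coh2, "fnclcc_grade", "os", x_max = 5)
  rise <- function(s) s$cs3[nrow(s)] - s$cs3[1]
  expect_gt(rise(st2$III), rise(st2$I))
  expect_error(stratified_cs3(coh2, "size_class", "os", 3,
                              levels = c("lt5", "ge15")), "empty stratum")

  # a factor with a single observed level reproduces the pooled series
  one <- stratified_cs3(coh2, "size_class", "os", x_max = 3)
  expect_equal(names(one), "lt5")
  expect_equal(one$lt5$cs3, cs3_series(km_curve(coh2, "os"), x_max = 3)$cs3)
})

test_that("d-series of a stratum against itself vanishes", {
  coh <- generate_cohort(sim_config(n_subjects = 1500, seed = 203))
  pooled <- cs3_series(km_curve(coh, "os"), x_max = 3)
  strata <- stratified_cs3(coh, "sex", "os", x_max = 3)
  dt <- d_series(strata, pooled, list(c("male", "male")))
  expect_true(all(dt$d == 0))
  expect_error(d_series(strata, pooled, list(c("male", "nonesuch"))), "nonesuch")
})
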