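test_that("hand-worked five-record example is reproduced for OS and CSS", {
  # times {2 censored, 3 death, 3 death, 5 censored, 7 death}
  coh <- make_cohort(c(2, 3, 3, 5, 7),
                     dead = c(FALSE, TRUE, TRUE, FALSE, TRUE))
  k <- km_curve(coh, "os")
  expect_equal(survival_at(k, 2.9)$estimate, 1)
  expect_equal(survival_at(k, 3)$estimate, 0.5)   # 4 at risk, 2 events
  expect_equal(survival_at(k, 4)$estimate, 0.5)   # step function between events
  expect_equal(survival_at(k, 7)$estimate, 0)     # 1 at risk, 1 event

  # same records, the two t=3 deaths from other causes, the t=7 death cancer
  coh2 <- make_cohort(c(2, 3, 3, 5, 7),
                      dead = c(FALSE, TRUE, TRUE, FALSE, TRUE),
                      cancer = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  kc <- km_curve(coh2, "css")
  expect_equal(survival_at(kc, 6.9)$estimate, 1)
  expect_equal(survival_at(kc, 7)$estimate, 0)
})

test_that("survival_at obeys the step convention and refuses extrapolation", {
  coh <- make_cohort(c(2, 3, 3, 5, 7), dead = c(FALSE, TRUE, TRUE, FALSE, TRUE))
  k <- km_curve(coh, "os")
  expect_equal(survival_at(k, 0)$estimate, 1)
  expect_equal(survival_at(k, 0)$variance, 0)
  expect_error(survival_at(k, -1), "non-negative")
  expect_error(survival_at(k, 8), "beyond")
  expect_error(km_curve(coh[0, ], "os"), "zero records")
})

test_that("an all-censored cohort yields a curve identically one", {
  coh <- make_cohort(c(4, 9, 15), dead = c(FALSE, FALSE, FALSE))
  k <- km_curve(coh, "os")
  expect_true(all(k$surv == 1))
  expect_true(all(k$greenwood_var == 0))
})

test_that("product-limit estimate equals the brute-force oracle on small inputs", {
  for (seed in 1:40) {
    n <- sample(3:12, 1)
    coh <- random_small_cohort(n, seed)
    for (ep in c("os", "css")) {
      ev <- rptcs:::endpoint_event(coh, ep)
      orc <- km_oracle(ev$time, ev$event)
      k <- km_curve(coh, ep)
      if (nrow(orc) > 0) {
        got <- survival_at(k, orc$time)$estimate
        expect_equal(got, orc$surv, tolerance = 1e-12)
      }
    }
  }
})

test_that("without censoring the estimate is the empirical survival function", {
  set.seed(77)
  time <- sample(1:40, 60, replace = TRUE)
  coh <- make_cohort(time, dead = rep(TRUE, 60))
  k <- km_curve(coh, "os")
  for (t in c(0, 5, 17, 33, 40)) {
    expect_equal(survival_at(k, t)$estimate, mean(time > t), tolerance = 1e-12)
  }
})

test_that("CSS dominates OS pointwise and Greenwood variance is sane", {
  for (seed in 1:15) {
    coh <- random_small_cohort(30, 100 + seed)
    os <- km_curve(coh, "os")
    css <- km_curve(coh, "css")
    grid <- 0:attr(os, "max_time")
    expect_true(all(survival_at(css, grid)$estimate >=
                      survival_at(os, grid)$estimate - 1e-12))
    expect_true(all(os$greenwood_var >= 0))
    expect_true(all(os$greenwood_var[os$surv == 1] == 0))
    expect_true(all(diff(os$n_risk) <= 0))
  }
})

test_that("log-rank matches the two-group score oracle and degenerates correctly", {
  coh <- random_small_cohort(40, 17)
  g <- rep(c("a", "b"), 20)
  coh$marital_status <- factor(ifelse(g == "a", "married", "unmarried"),
                               levels = rptcs_levels("marital_status"))
  lr <- log_rank(coh, "marital_status", "os")
  ev <- rptcs:::endpoint_event(coh, "os")
  expect_equal(lr$statistic,
               logrank_oracle_chisq(ev$time, ev$event,
                                    as.character(coh$marital_status)),
               tolerance = 1e-8)
  expect_equal(lr$df, 1L)

  # identical groups: statistic ~ 0, p ~ 1
  dup <- rbind(coh, coh)
  dup$subject_id <- sprintf("D%04d", seq_len(nrow(dup)))
  dup$marital_status <- factor(rep(c("married", "unmarried"), each = nrow(coh)),
                               levels = rptcs_levels("marital_status"))
  dup$followup_months <- rep(coh$followup_months, 2)
  dup$vital_status <- rep(coh$vital_status, 2)
  lr0 <- log_rank(dup, "marital_status", "os")
  expect_lt(lr0$statistic, 1e-10)
  expect_gt(lr0$p_value, 0.999)

  expect_error(log_rank(coh[coh$marital_status == "married", ],
                        "marital_status", "os"), "zero subjects|two groups")
})

test_that("log-rank detects a strong planted effect", {
  pvals <- vapply(1:5, function(seed) {
    cfg <- simple_config(2000, seed = 300 + seed, cancer_rates = 0.015,
                         p_chemo = 0.5, admin = 156,
                         loghr_cancer = list(chemotherapy = c(yes = log(3))))
    coh <- generate_cohort(cfg)
    log_rank(coh, "chemotherapy", "os")$p_value
  }, numeric(1))
  expect_true(all(pvals < 0.001))
})

test_that("smoothed hazard recovers a constant rate and integrates to the cumulative hazard", {
  lambda <- 0.02
  cfg <- simple_config(20000, seed = 23, cancer_rates = lambda, admin = 1e6)
  coh <- generate_cohort(cfg)
  hz <- smoothed_hazard(coh, "os", bandwidth = 12)
  interior <- hz$time >= 24 & hz$time <= 120
  expect_true(all(abs(hz$hazard[interior] - lambda) < 0.1 * lambda))
  # integral of the smoothed hazard tracks -log S on the interior
  k <- km_curve(coh, "os")
  for (t in c(36, 72, 120)) {
    integral <- sum(hz$hazard[hz$time >= 1 & hz$time <= t])
    expect_equal(integral, -log(survival_at(k, t)$estimate), tolerance = 0.05)
  }
})

test_that("smoothed hazard of an event-free cohort is identically zero", {
  coh <- make_cohort(c(10, 20, 30), dead = c(FALSE, FALSE, FALSE))
  hz <- smoothed_hazard(coh, "os")
  expect_true(all(hz$hazard == 0))
  expect_error(smoothed_hazard(coh, "os", bandwidth = 0), "positive")
})

test_that("reverse-KM median follow-up matches the administrative design", {
  cfg <- simple_config(5000, seed = 29, cancer_rates = 0.01,
                       accrual = 156, admin = 156)
  coh <- generate_cohort(cfg)
  mf <- median_followup(coh)
  # potential follow-up uniform on (0, 156): median 78 months
  expect_lt(abs(mf - 78), 6)
})
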