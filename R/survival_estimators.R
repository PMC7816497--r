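# Product-limit estimation of OS and cause-specific CSS, log-rank tests, and
# kernel-smoothed hazard curves.  The product-limit and score computations
# are delegated to the survival package; CSS uses the cause-specific
# convention (other-cause deaths censored at their death time).

endpoint_event <- function(records, endpoint) {
  endpoint <- match.arg(tolower(endpoint), c("os", "css"))
  dead <- records$vital_status == "dead"
  if (endpoint == "os") {
    ev <- dead
  } else {
    ev <- dead & records$cancer_specific_death %in% TRUE
  }
  list(time = records$followup_months, event = as.integer(ev),
       endpoint = toupper(endpoint))
}

#' Kaplan-Meier survival curve for an endpoint
#'
#' Overall survival (`"os"`) treats any death as the event; cancer-specific
#' survival (`"css"`) treats cancer deaths as events and censors alive
#' subjects and other-cause deaths at their follow-up time.  Variance is the
#' Greenwood estimate.
#'
#' @param records validated cohort data frame.
#' @param endpoint `"os"` or `"css"`.
#' @return an `rpt_surv_curve`: a data frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `greenwood_var`, and attributes
#'   `endpoint`, `n_total`, `max_time`.
#' @export
km_curve <- function(records, endpoint = c("os", "css")) {
  endpoint <- match.arg(endpoint)
  records <- validate_cohort(records)
  if (nrow(records) == 0L) stop("cannot estimate survival from zero records", call. = FALSE)
  ev <- endpoint_event(records, endpoint)
  fit <- survival::survfit(survival::Surv(ev$time, ev$event) ~ 1, conf.type = "log-log")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, surv = fit$surv,
                    greenwood_var = fit$surv^2 * fit$std.err^2)
  out$greenwood_var[out$surv == 1] <- 0
  out$greenwood_var[out$surv == 0] <- 0  # estimate degenerate once S hits 0
  structure(out, endpoint = ev$endpoint, n_total = nrow(records),
            max_time = max(ev$time), class = c("rpt_surv_curve", "data.frame"))
}

#' @export
print.rpt_surv_curve <- function(x, ...) {
  cat(sprintf("%s Kaplan-Meier curve: %d subjects, %d events, follow-up to %d months\n",
              attr(x, "endpoint"), attr(x, "n_total"), sum(x$n_event),
              attr(x, "max_time")))
  invisible(x)
}

#' Survival probability at given times
#'
#' Right-continuous step-function lookup: the value at the largest observed
#' time not exceeding `t`.  Times beyond the last observed follow-up raise an
#' error rather than extrapolating.
#'
#' @param curve an `rpt_surv_curve`.
#' @param t times in months (vectorised).
#' @return data frame with `time`, `estimate`, `variance`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "rpt_surv_curve"))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  if (any(t > attr(curve, "max_time"))) {
    stop(sprintf("time %g months is beyond the observed follow-up (%d months)",
                 max(t), attr(curve, "max_time")), call. = FALSE)
  }
  idx <- findInterval(t, curve$time)
  est <- ifelse(idx == 0, 1, curve$surv[pmax(idx, 1L)])
  v <- ifelse(idx == 0, 0, curve$greenwood_var[pmax(idx, 1L)])
  data.frame(time = t, estimate = est, variance = v)
}

#' k-group log-rank test
#'
#' @param records validated cohort data frame.
#' @param by name of the grouping covariate.
#' @param endpoint `"os"` or `"css"`.
#' @return an `rpt_log_rank` list with `statistic`, `df`, `p_value`.
#' @export
log_rank <- function(records, by, endpoint = c("os", "css")) {
  endpoint <- match.arg(endpoint)
  records <- validate_cohort(records)
  g <- factor(records[[by]])
  counts <- table(g)
  if (any(counts == 0L)) {
    stop("group(s) with zero subjects: ",
         paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
  }
  if (nlevels(g) < 2L) stop("log-rank needs at least two groups", call. = FALSE)
  ev <- endpoint_event(records, endpoint)
  sd <- survival::survdiff(survival::Surv(ev$time, ev$event) ~ g)
  df <- nlevels(g) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 by = by, endpoint = ev$endpoint),
            class = "rpt_log_rank")
}

#' @export
print.rpt_log_rank <- function(x, ...) {
  cat(sprintf("Log-rank (%s by %s): chi-square = %.3f on %d df, p = %.4g\n",
              x$endpoint, x$by, x$statistic, x$df, x$p_value))
  invisible(x)
}

# Integral of the Epanechnikov kernel from -1 to x, clamped to [0, 1].
epan_cdf <- function(x) {
  x <- pmin(pmax(x, -1), 1)
  0.5 + 0.75 * x - 0.25 * x^3
}

#' Kernel-smoothed hazard curve
#'
#' Epanechnikov smoothing of the Nelson-Aalen increments d/n over a monthly
#' grid, with boundary correction by kernel renormalisation near time 0 and
#' the end of follow-up.
#'
#' @param records validated cohort data frame.
#' @param endpoint `"os"` or `"css"`.
#' @param bandwidth kernel bandwidth in months.
#' @param grid evaluation times in months; defaults to every month of
#'   observed follow-up.
#' @return an `rpt_hazard_curve`: data frame with `time` and `hazard`
#'   (deaths per subject-month), attributes `bandwidth` and `endpoint`.
#' @export
smoothed_hazard <- function(records, endpoint = c("os", "css"), bandwidth = 12,
                            grid = NULL) {
  endpoint <- match.arg(endpoint)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  curve <- km_curve(records, endpoint)
  tmax <- attr(curve, "max_time")
  if (is.null(grid)) grid <- seq(0, tmax, by = 1)
  events <- curve[curve$n_event > 0, , drop = FALSE]
  if (nrow(events) == 0L) {
    haz <- numeric(length(grid))
  } else {
    inc <- events$n_event / events$n_risk
    haz <- vapply(grid, function(t) {
      u <- (t - events$time) / bandwidth
      w <- ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0) / bandwidth
      # renormalise over the part of the kernel support inside [0, tmax]
      mass <- epan_cdf(t / bandwidth) - epan_cdf((t - tmax) / bandwidth)
      if (mass <= 0) return(0)
      sum(w * inc) / mass
    }, numeric(1))
  }
  structure(data.frame(time = grid, hazard = haz),
            bandwidth = bandwidth, endpoint = attr(curve, "endpoint"),
            class = c("rpt_hazard_curve", "data.frame"))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Median of the censoring distribution (events and censorings swapped);
#' a descriptive diagnostic of follow-up maturity.
#'
#' @param records validated cohort data frame.
#' @return median potential follow-up in months (`NA` if not reached).
#' @export
median_followup <- function(records) {
  records <- validate_cohort(records)
  cens <- as.integer(records$vital_status != "dead")
  fit <- survival::survfit(survival::Surv(records$followup_months, cens) ~ 1)
  unname(stats::quantile(fit, probs = 0.5)$quantile)
}
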