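# Conditional survival CS(y|x) = S(x+y)/S(x), the 3-year conditional series
# (COS3 / CCSS3), the conditional survival matrix, stratified series, and
# standardized-difference comparisons between prognostic subgroups.

#' Conditional survival from a fitted curve
#'
#' Probability (as a percent) of surviving an additional `y` years given
#' survival to year `x`: `CS(y|x) = S(x+y)/S(x)`.  Years are exact multiples
#' of 12 months through the right-continuous step lookup of [survival_at()];
#' at `x = 0` the denominator is 1 (conditioning on cohort membership), so
#' registry deaths recorded in month 0 do not inflate the baseline
#' conditional rate above the actual one.  The value is returned unrounded;
#' rounding to one decimal happens only at presentation.
#'
#' @param curve an `rpt_surv_curve`.
#' @param x years already survived (vectorised).
#' @param y additional years.
#' @return conditional survival percent(s).
#' @export
conditional_survival <- function(curve, x, y) {
  stopifnot(inherits(curve, "rpt_surv_curve"))
  if (any(x < 0) || any(y < 0)) stop("x and y must be non-negative", call. = FALSE)
  s_x <- ifelse(x == 0, 1, survival_at(curve, 12 * x)$estimate)
  if (any(s_x == 0)) {
    stop(sprintf("conditional survival undefined: S(%g years) = 0",
                 x[s_x == 0][1]), call. = FALSE)
  }
  s_xy <- survival_at(curve, 12 * (x + y))$estimate
  100 * s_xy / s_x
}

#' Conditional survival from printed rates
#'
#' The same ratio taken directly on reported survival percentages, e.g.
#' published 1- and 4-year rates giving the 3-year conditional rate at one
#' year survived.
#'
#' @param rate_start survival percent at the conditioning time x.
#' @param rate_end survival percent at the horizon x + y.
#' @return conditional survival percent (unrounded).
#' @export
conditional_from_rates <- function(rate_start, rate_end) {
  if (any(rate_start <= 0)) stop("conditioning rate must be positive", call. = FALSE)
  100 * rate_end / rate_start
}

#' Three-year conditional survival series
#'
#' `CS3(x) = 100 * S(x + window)/S(x)` for `x = 0 .. x_max` years, paired
#' with the actual survival `S(x + window)` for gap displays.  Entries whose
#' horizon exceeds the observed follow-up (or where `S(x) = 0`) are dropped
#' with a warning rather than extrapolated.
#'
#' @param curve an `rpt_surv_curve`.
#' @param x_max largest number of years survived.
#' @param window conditional window in years (default 3).
#' @return an `rpt_cs3_series` data frame with `x`, `cs3`, `actual`.
#' @export
cs3_series <- function(curve, x_max = 5, window = 3) {
  stopifnot(inherits(curve, "rpt_surv_curve"), x_max >= 0, window >= 1)
  max_years <- attr(curve, "max_time") / 12
  xs <- 0:x_max
  ok <- (xs + window) <= max_years &
    (xs == 0 |
       survival_at(curve, pmin(12 * xs, attr(curve, "max_time")))$estimate > 0)
  if (!all(ok)) {
    warning(sprintf("series truncated at x = %d years (follow-up ends at %.1f years)",
                    max(c(-1L, xs[ok])), max_years), call. = FALSE)
  }
  xs <- xs[ok]
  out <- data.frame(
    x = xs,
    cs3 = if (length(xs)) conditional_survival(curve, xs, window) else numeric(),
    actual = if (length(xs)) 100 * survival_at(curve, 12 * (xs + window))$estimate
             else numeric())
  structure(out, endpoint = attr(curve, "endpoint"), window = window,
            class = c("rpt_cs3_series", "data.frame"))
}

#' Conditional survival matrix
#'
#' The grid `CS(total - x | x)` for total survival times `1 .. max_total`
#' years (rows) and years already survived `x = 0 .. max_total` (columns).
#' The diagonal is 100; cells with `x > total`, beyond follow-up, or with
#' `S(x) = 0` are `NA`.  Values are unrounded; [render_cs_matrix()] rounds
#' for display.
#'
#' @param curve an `rpt_surv_curve`.
#' @param max_total_years largest total survival time.
#' @return an `rpt_cs_matrix` (numeric matrix of percents) with attribute
#'   `endpoint`.
#' @export
conditional_matrix <- function(curve, max_total_years = 8) {
  stopifnot(inherits(curve, "rpt_surv_curve"), max_total_years >= 1)
  max_years <- attr(curve, "max_time") / 12
  totals <- seq_len(max_total_years)
  xs <- 0:max_total_years
  m <- matrix(NA_real_, nrow = length(totals), ncol = length(xs),
              dimnames = list(total_years = totals, survived_years = xs))
  for (x in xs) {
    if (12 * x > attr(curve, "max_time")) next
    if (x > 0 && survival_at(curve, 12 * x)$estimate == 0) next
    for (tot in totals) {
      if (x > tot || tot > max_years) next
      m[as.character(tot), as.character(x)] <-
        if (x == tot) 100 else conditional_survival(curve, x, tot - x)
    }
  }
  structure(m, endpoint = attr(curve, "endpoint"), class = "rpt_cs_matrix")
}

#' @export
print.rpt_cs_matrix <- function(x, ...) {
  cat(sprintf("%s conditional survival matrix (percent)\n", attr(x, "endpoint")))
  print(round(unclass(x), 1), na.print = "")
  invisible(x)
}

#' Stratified three-year conditional survival series
#'
#' Splits the cohort by a covariate, fits a Kaplan-Meier curve per level,
#' and computes a [cs3_series()] for each; levels truncate individually
#' where their follow-up runs out.
#'
#' @param records validated cohort data frame.
#' @param factor name of the stratification covariate.
#' @param endpoint `"os"` or `"css"`.
#' @param x_max largest number of years survived.
#' @param window conditional window in years.
#' @param levels stratum levels to analyse; defaults to the levels observed
#'   in the cohort.  A requested level with no subjects is an error.
#' @return named list of `rpt_cs3_series`, one per level, class
#'   `rpt_cs3_strata`.
#' @export
stratified_cs3 <- function(records, factor, endpoint = c("os", "css"),
                           x_max = 5, window = 3, levels = NULL) {
  endpoint <- match.arg(endpoint)
  records <- validate_cohort(records)
  vals <- records[[factor]]
  if (is.null(vals)) stop("unknown covariate: ", factor, call. = FALSE)
  if (is.logical(vals)) vals <- base::factor(ifelse(vals, "yes", "no"), c("no", "yes"))
  if (is.null(levels)) levels <- base::levels(droplevels(vals))
  empty <- setdiff(levels, as.character(vals))
  if (length(empty) > 0L) {
    stop("empty stratum level(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- lapply(levels, function(lv) {
    cs3_series(km_curve(records[vals == lv, , drop = FALSE], endpoint),
               x_max = x_max, window = window)
  })
  names(out) <- levels
  structure(out, factor = factor, endpoint = toupper(endpoint), window = window,
            class = "rpt_cs3_strata")
}

#' Standardized difference between two conditional survival rates
#'
#' `d = (P2 - P1) / sqrt(P (1 - P))` with `P` the pooled whole-cohort rate
#' at the same time point.  For a comparison "A vs B", `p2` is group A's
#' rate and `p1` group B's, so `d` is positive when the first-listed group
#' fares better.  Bands on `|d|`: below 0.1 none, 0.1-0.3 small, 0.3-0.5
#' moderate, 0.5 and above significant.
#'
#' @param p2 proportion in the first-listed group, in (0, 1).
#' @param p1 proportion in the second-listed group, in (0, 1).
#' @param p_overall pooled cohort proportion at the same time point.
#' @return an `rpt_std_diff` list: `p1`, `p2`, `p_overall`, `d`, `band`.
#' @export
standardized_difference <- function(p2, p1, p_overall) {
  stopifnot(length(p2) == 1, length(p1) == 1, length(p_overall) == 1)
  if (p_overall <= 0 || p_overall >= 1) {
    stop("pooled rate must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) > 1)) {
    stop("group rates must lie in (0, 1]", call. = FALSE)
  }
  d <- (p2 - p1) / sqrt(p_overall * (1 - p_overall))
  structure(list(p1 = p1, p2 = p2, p_overall = p_overall, d = d,
                 band = d_band(d)), class = "rpt_std_diff")
}

#' Interpretation band of a standardized difference
#'
#' @param d signed standardized difference (vectorised).
#' @return `"none"`, `"small"`, `"moderate"`, or `"significant"`.
#' @export
d_band <- function(d) {
  cut(abs(d), breaks = c(0, 0.1, 0.3, 0.5, Inf), right = FALSE,
      labels = c("none", "small", "moderate", "significant")) |> as.character()
}

#' @export
print.rpt_std_diff <- function(x, ...) {
  cat(sprintf("d = %.2f (%s): P2 = %.3f, P1 = %.3f, pooled P = %.3f\n",
              x$d, x$band, x$p2, x$p1, x$p_overall))
  invisible(x)
}

#' Standardized-difference series over years survived
#'
#' For each requested level pair and each year `x` present in both series,
#' the standardized difference of the pair's conditional rates with the
#' pooled cohort's conditional rate at the same `x` inside the square root.
#'
#' @param strata an `rpt_cs3_strata` from [stratified_cs3()].
#' @param pooled the whole-cohort `rpt_cs3_series` for the same endpoint.
#' @param comparisons list of two-element character vectors `c(A, B)`
#'   meaning "A vs B".
#' @return data frame with `pair`, `x`, `p2`, `p1`, `p_overall`, `d`, `band`.
#' @export
d_series <- function(strata, pooled, comparisons) {
  stopifnot(inherits(strata, "rpt_cs3_strata"), inherits(pooled, "rpt_cs3_series"))
  rows <- lapply(comparisons, function(pr) {
    stopifnot(length(pr) == 2)
    missing <- setdiff(pr, names(strata))
    if (length(missing) > 0L) {
      stop("comparison level(s) not in strata: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    a <- strata[[pr[1]]]; b <- strata[[pr[2]]]
    xs <- intersect(intersect(a$x, b$x), pooled$x)
    do.call(rbind, lapply(xs, function(x) {
      p2 <- a$cs3[a$x == x] / 100
      p1 <- b$cs3[b$x == x] / 100
      po <- pooled$cs3[pooled$x == x] / 100
      # d is undefined when a stratum rate hits 0 or the pooled rate is
      # degenerate; report NA rather than aborting a whole run
      sd <- tryCatch(standardized_difference(p2, p1, po), error = function(e) NULL)
      data.frame(pair = paste(pr[1], "vs", pr[2]), x = x, p2 = p2, p1 = p1,
                 p_overall = po,
                 d = if (is.null(sd)) NA_real_ else sd$d,
                 band = if (is.null(sd)) NA_character_ else sd$band,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
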