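# Univariable screening and multivariable proportional-hazards fitting,
# reported as per-level hazard ratios against stated reference levels.

#' Default multivariable covariate sets per endpoint
#'
#' The overall-survival model carries age, sex, marital status, FNCLCC
#' grade, size, multifocality, histology and chemotherapy; the
#' cancer-specific model drops marital status.  The covariate list is an
#' argument everywhere, so other readings can be run.
#'
#' @param endpoint `"os"` or `"css"`.
#' @return character vector of covariate names.
#' @export
default_covariates <- function(endpoint = c("os", "css")) {
  endpoint <- match.arg(endpoint)
  base <- c("age_group", "sex", "marital_status", "fnclcc_grade", "size_class",
            "multifocality", "histology", "chemotherapy")
  if (endpoint == "css") base <- setdiff(base, "marital_status")
  base
}

cox_frame <- function(records, covariates, endpoint, references = list()) {
  ev <- endpoint_event(records, endpoint)
  d <- data.frame(.time = ev$time, .event = ev$event)
  for (cov in covariates) {
    vals <- records[[cov]]
    if (is.null(vals)) stop("unknown covariate: ", cov, call. = FALSE)
    if (is.logical(vals)) vals <- factor(ifelse(vals, "yes", "no"), c("no", "yes"))
    vals <- droplevels(factor(vals))
    if (!is.null(references[[cov]])) vals <- stats::relevel(vals, references[[cov]])
    if (nlevels(vals) < 2L) {
      stop(sprintf("covariate '%s' has no contrast (a single observed level)", cov),
           call. = FALSE)
    }
    d[[cov]] <- vals
  }
  d
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the partial likelihood (Efron tie correction by default —
#' registry month-granularity data is heavily tied) over dummy-coded
#' categorical covariates, reporting per-level hazard ratios with Wald 95%
#' confidence intervals and p-values against each covariate's reference
#' level.
#'
#' @param records validated cohort data frame.
#' @param covariates covariate names; defaults to [default_covariates()].
#' @param endpoint `"os"` or `"css"`.
#' @param ties `"efron"` or `"breslow"`.
#' @param references named list overriding the default (first canonical)
#'   reference level per covariate.
#' @return an `rpt_cox_fit` with elements `terms` (covariate, level,
#'   reference, coef, se, hr, ci_low, ci_high, p_value), `loglik`,
#'   `loglik_null`, `n_events`, `converged`, `monotone`, `iterations`,
#'   and the underlying `survival::coxph` fit.
#' @export
fit_cox <- function(records, covariates = NULL, endpoint = c("os", "css"),
                    ties = c("efron", "breslow"), references = list()) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  records <- validate_cohort(records)
  if (is.null(covariates)) covariates <- default_covariates(endpoint)
  d <- cox_frame(records, covariates, endpoint, references)
  if (sum(d$.event) < 1L) stop("no events under endpoint ", toupper(endpoint), call. = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(covariates, collapse = " + ")))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties, model = TRUE),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  terms <- do.call(rbind, lapply(covariates, function(cov) {
    levs <- levels(d[[cov]])
    nm <- paste0(cov, levs[-1])
    data.frame(covariate = cov, level = levs[-1], reference = levs[1],
               coef = unname(co[nm]), se = unname(se[nm]),
               stringsAsFactors = FALSE)
  }))
  z <- terms$coef / terms$se
  terms$hr <- exp(terms$coef)
  terms$ci_low <- exp(terms$coef - stats::qnorm(0.975) * terms$se)
  terms$ci_high <- exp(terms$coef + stats::qnorm(0.975) * terms$se)
  terms$p_value <- 2 * stats::pnorm(-abs(z))
  converged <- !monotone && all(is.finite(terms$coef)) &&
    fit$iter < 20L  # coxph default iter.max
  if (!converged && !monotone) {
    stop(sprintf("Cox fit did not converge after %d iterations", fit$iter),
         call. = FALSE)
  }
  structure(list(endpoint = toupper(endpoint), terms = terms, ties = ties,
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 n_events = sum(d$.event), n = nrow(d),
                 converged = converged, monotone = monotone,
                 iterations = fit$iter, fit = fit),
            class = "rpt_cox_fit")
}

#' @export
print.rpt_cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s, %s ties): %d subjects, %d events\n",
              x$endpoint, x$ties, x$n, x$n_events))
  if (x$monotone) cat("  warning: monotone likelihood, some coefficients diverge\n")
  t <- x$terms
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-20s %-10s HR %6.3f (%.3f-%.3f)  p = %.4g\n",
                t$covariate[i], t$level[i], t$hr[i], t$ci_low[i], t$ci_high[i],
                t$p_value[i]))
  }
  invisible(x)
}

#' Univariable proportional-hazards screen
#'
#' Fits one Cox model per covariate and flags those whose overall
#' likelihood-ratio test falls below `alpha` (the carry-forward rule into
#' the multivariable model).
#'
#' @param records validated cohort data frame.
#' @param covariates covariate names; defaults to the OS multivariable set.
#' @param endpoint `"os"` or `"css"`.
#' @param alpha carry-forward significance threshold.
#' @return an `rpt_uni_screen`: data frame with `covariate`, `lrt_chisq`,
#'   `df`, `p_value`, `selected`; fits in attribute `fits`.
#' @export
univariable_screen <- function(records, covariates = NULL,
                               endpoint = c("os", "css"), alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  if (is.null(covariates)) covariates <- default_covariates("os")
  fits <- lapply(covariates, function(cov) fit_cox(records, cov, endpoint))
  names(fits) <- covariates
  tab <- do.call(rbind, lapply(covariates, function(cov) {
    f <- fits[[cov]]
    chisq <- 2 * (f$loglik - f$loglik_null)
    df <- nrow(f$terms)
    data.frame(covariate = cov, lrt_chisq = chisq, df = df,
               p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  tab$selected <- tab$p_value < alpha
  structure(tab, fits = fits, endpoint = toupper(endpoint), alpha = alpha,
            class = c("rpt_uni_screen", "data.frame"))
}

#' Proportional-hazards diagnostic (Schoenfeld residual test)
#'
#' Optional diagnostic on a fitted model; never a gate in the pipeline.
#'
#' @param fit an `rpt_cox_fit`.
#' @return the `survival::cox.zph` table.
#' @export
ph_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "rpt_cox_fit"))
  survival::cox.zph(fit$fit)$table
}

#' Serialise a Cox fit as JSON
#'
#' @param fit an `rpt_cox_fit`.
#' @param path optional output path.
#' @return JSON string, invisibly when written.
#' @export
cox_fit_json <- function(fit, path = NULL) {
  payload <- list(endpoint = fit$endpoint, ties = fit$ties, n = fit$n,
                  n_events = fit$n_events, loglik = fit$loglik,
                  converged = fit$converged, monotone = fit$monotone,
                  iterations = fit$iterations, terms = fit$terms)
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
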