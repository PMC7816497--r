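# End-to-end pipeline: filter -> KM/hazard -> univariable screen ->
# multivariable Cox -> conditional survival -> standardized differences,
# with every table written to disk and a manifest hashing the outputs.

#' Pipeline configuration
#'
#' @param input path to a case-listing CSV, or `NULL` to simulate a cohort
#'   from `sim`.
#' @param sim an [sim_config()] used when `input` is `NULL`; its seed is
#'   overridden by `seed`.
#' @param endpoints endpoints to analyse.
#' @param window conditional window in years.
#' @param x_max largest number of years survived in the CS3 series.
#' @param max_total_years largest total year in the conditional matrix.
#' @param stratify covariates for stratified CS3 series.
#' @param comparisons named list (by covariate) of lists of `c(A, B)` pairs
#'   for standardized differences.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for the whole run.
#' @param percent_decimals,d_decimals rounding used in rendered tables.
#' @return an `rpt_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            endpoints = c("os", "css"), window = 3, x_max = 5,
                            max_total_years = 8,
                            stratify = c("fnclcc_grade", "chemotherapy"),
                            comparisons = list(
                              fnclcc_grade = list(c("I", "III")),
                              chemotherapy = list(c("no", "yes"))),
                            out_dir = "rptcs_run", seed = 1L,
                            percent_decimals = 1, d_decimals = 2) {
  stopifnot(window >= 1, x_max >= 0)
  structure(list(input = input, sim = sim, endpoints = endpoints,
                 window = window, x_max = x_max,
                 max_total_years = max_total_years, stratify = stratify,
                 comparisons = comparisons, out_dir = out_dir,
                 seed = as.integer(seed), percent_decimals = percent_decimals,
                 d_decimals = d_decimals),
            class = "rpt_pipeline_config")
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round(x, digits), format = "f", digits = digits))
}

#' Render a conditional survival matrix in publication layout
#'
#' Rows are total survival years, columns years already survived (from one
#' year on), percents to one decimal, the diagonal rendered as "100",
#' undefined cells blank.
#'
#' @param m an `rpt_cs_matrix`.
#' @param decimals decimals for off-diagonal percents.
#' @return character data frame ready for `write.csv`.
#' @export
render_cs_matrix <- function(m, decimals = 1) {
  stopifnot(inherits(m, "rpt_cs_matrix"))
  mm <- unclass(m)
  cols <- colnames(mm)[colnames(mm) != "0"]
  out <- data.frame(total_years = rownames(mm), stringsAsFactors = FALSE)
  for (x in cols) {
    cell <- mm[, x]
    txt <- fmt_num(cell, decimals)
    txt[!is.na(cell) & cell == 100] <- "100"
    out[[paste0("survived_", x, "y")]] <- txt
  }
  out
}

#' Render the stratified CS3 + standardized-difference table
#'
#' One row for the pooled cohort, one per stratum level, and one signed d
#' row per comparison, columns over years survived; percents to one
#' decimal, d to two decimals.
#'
#' @param pooled pooled `rpt_cs3_series`.
#' @param strata an `rpt_cs3_strata`.
#' @param dtab output of [d_series()] (or `NULL`).
#' @param percent_decimals,d_decimals rounding.
#' @return character data frame.
#' @export
render_cs3_table <- function(pooled, strata, dtab = NULL,
                             percent_decimals = 1, d_decimals = 2) {
  xs <- pooled$x
  col <- function(series, what = "cs3") {
    vapply(xs, function(x) {
      v <- series[[what]][series$x == x]
      if (length(v) == 0) "" else fmt_num(v, percent_decimals)
    }, character(1))
  }
  rows <- list(c(row = "Overall", stats::setNames(col(pooled), paste0("x", xs))))
  for (lv in names(strata)) {
    rows <- c(rows, list(c(row = lv, stats::setNames(col(strata[[lv]]), paste0("x", xs)))))
  }
  if (!is.null(dtab)) {
    for (pr in unique(dtab$pair)) {
      sub <- dtab[dtab$pair == pr, ]
      vals <- vapply(xs, function(x) {
        v <- sub$d[sub$x == x]
        if (length(v) == 0) "" else fmt_num(v, d_decimals)
      }, character(1))
      rows <- c(rows, list(c(row = paste0("d (", pr, ")"),
                             stats::setNames(vals, paste0("x", xs)))))
    }
  }
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}

write_csv_out <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full conditional-survival pipeline
#'
#' Executes filter, Kaplan-Meier and smoothed-hazard estimation, the
#' univariable screen, the multivariable Cox fit, the conditional survival
#' matrix and CS3 series, and stratified standardized differences, writing
#' every table under `config$out_dir` plus a `manifest.json` hashing the
#' outputs.  Identical configuration and seed give byte-identical outputs.
#'
#' @param config an [pipeline_config()].
#' @return the manifest, invisibly (list with files, hashes, counts).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "rpt_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }

  cohort <- stage("cohort", {
    if (is.null(config$input)) {
      sim <- config$sim
      sim$seed <- config$seed
      generate_cohort(sim)
    } else {
      read_case_listing(config$input)
    }
  })
  flt <- stage("filter", apply_inclusion_filters(cohort))
  emit("cohort.csv", function(p) write_case_listing(flt$cohort, p))
  emit("attrition.json", function(p) attrition_json(flt$attrition, p))

  results <- list(attrition = flt$attrition)
  for (ep in config$endpoints) {
    curve <- stage(paste0("km_", ep), km_curve(flt$cohort, ep))
    emit(paste0("km_", ep, ".csv"), function(p) write_csv_out(as.data.frame(curve), p))
    haz <- stage(paste0("hazard_", ep), smoothed_hazard(flt$cohort, ep))
    emit(paste0("hazard_", ep, ".csv"), function(p) write_csv_out(as.data.frame(haz), p))

    screen <- stage(paste0("univariable_", ep),
                    univariable_screen(flt$cohort, endpoint = ep))
    emit(paste0("univariable_", ep, ".csv"),
         function(p) write_csv_out(as.data.frame(screen), p))
    fit <- stage(paste0("cox_", ep), fit_cox(flt$cohort, endpoint = ep))
    emit(paste0("cox_", ep, ".json"), function(p) cox_fit_json(fit, p))
    emit(paste0("cox_", ep, ".csv"), function(p) write_csv_out(fit$terms, p))

    mat <- stage(paste0("cs_matrix_", ep),
                 conditional_matrix(curve, config$max_total_years))
    emit(paste0("cs_matrix_", ep, ".csv"),
         function(p) write_csv_out(render_cs_matrix(mat, config$percent_decimals), p))
    pooled <- stage(paste0("cs3_", ep),
                    cs3_series(curve, config$x_max, config$window))

    strata_out <- list()
    dtab_all <- NULL
    for (fac in config$stratify) {
      st <- stage(paste0("cs3_", ep, "_by_", fac),
                  stratified_cs3(flt$cohort, fac, ep, config$x_max, config$window))
      dt <- if (!is.null(config$comparisons[[fac]])) {
        d_series(st, pooled, config$comparisons[[fac]])
      } else NULL
      emit(paste0("cs3_", ep, "_by_", fac, ".csv"),
           function(p) write_csv_out(
             render_cs3_table(pooled, st, dt, config$percent_decimals,
                              config$d_decimals), p))
      strata_out[[fac]] <- st
      if (!is.null(dt)) dtab_all <- rbind(dtab_all, dt)
    }
    results[[ep]] <- list(curve = curve, hazard = haz, screen = screen,
                          cox = fit, matrix = mat, cs3 = pooled,
                          strata = strata_out, d = dtab_all)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rptcs")),
    seed = config$seed,
    n_input = nrow(cohort),
    n_analysed = nrow(flt$cohort),
    endpoints = config$endpoints,
    files = lapply(stats::setNames(files, basename(files)), function(p) {
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    }))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             manifest_path)
  invisible(c(results, list(manifest = manifest, out_dir = config$out_dir)))
}
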