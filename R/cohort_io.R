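# Reading/writing SEER*Stat-style case listings and the inclusion filter chain.

#' Default column-name dialect for case-listing files
#'
#' A dialect maps each canonical field to the column header used in a
#' particular export; registry export headers vary by software version, so
#' the mapping is data, not code.  The default dialect matches the output of
#' [write_case_listing()].
#'
#' @param columns named character vector, canonical field -> file column.
#' @param route_unrecognised if `TRUE`, a categorical value that does not
#'   match any canonical level is routed to the field's `unknown` (or
#'   `other`) level instead of raising an error.
#' @return an object of class `rpt_dialect`.
#' @export
case_dialect <- function(columns = stats::setNames(rpt_fields, rpt_fields),
                         route_unrecognised = FALSE) {
  stopifnot(is.character(columns), !is.null(names(columns)))
  missing <- setdiff(rpt_fields, names(columns))
  if (length(missing) > 0L) {
    stop("dialect does not map field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(columns = columns, route_unrecognised = isTRUE(route_unrecognised)),
            class = "rpt_dialect")
}

normalise_level <- function(vals, field, route) {
  levs <- rpt_levels[[field]]
  idx <- match(tolower(vals), tolower(levs))
  out <- levs[idx]
  bad <- is.na(out) & !is.na(vals) & nzchar(vals)
  if (any(bad)) {
    if (route) {
      fallback <- intersect(c("unknown", "other"), levs)[1]
      if (is.na(fallback)) {
        stop(sprintf("field '%s' has no unknown/other level to route '%s' to",
                     field, vals[bad][1]), call. = FALSE)
      }
      out[bad] <- fallback
    } else {
      stop(sprintf("row %d: unrecognised value '%s' for field '%s'",
                   which(bad)[1], vals[bad][1], field), call. = FALSE)
    }
  }
  out
}

parse_logical <- function(vals, field) {
  key <- tolower(trimws(vals))
  out <- rep(NA, length(vals))
  out[key %in% c("true", "t", "yes", "1")] <- TRUE
  out[key %in% c("false", "f", "no", "0")] <- FALSE
  bad <- is.na(out) & !is.na(vals) & nzchar(key)
  if (any(bad)) {
    stop(sprintf("row %d: cannot parse '%s' as logical for field '%s'",
                 which(bad)[1], vals[bad][1], field), call. = FALSE)
  }
  out
}

#' Read a case-listing CSV into a validated cohort
#'
#' Reads an RFC-4180 CSV with a header row, renames columns through the
#' dialect, normalises categorical values case-insensitively to the canonical
#' levels, and validates the record invariants.
#'
#' @param path path to the CSV file.
#' @param dialect a [case_dialect()] mapping canonical fields to file columns.
#' @return a validated cohort data frame, one row per subject.
#' @export
read_case_listing <- function(path, dialect = case_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty case listing: ", path, call. = FALSE)
  cols <- dialect$columns
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing) > 0L) {
    stop("case listing is missing mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(subject_id = raw[[cols[["subject_id"]]]],
                    stringsAsFactors = FALSE)
  for (fld in names(rpt_levels)) {
    vals <- raw[[cols[[fld]]]]
    vals[!nzchar(trimws(vals))] <- NA_character_
    out[[fld]] <- normalise_level(trimws(vals), fld, dialect$route_unrecognised)
  }
  for (fld in rpt_logical_fields) {
    out[[fld]] <- parse_logical(raw[[cols[[fld]]]], fld)
  }
  fmv <- trimws(raw[[cols[["followup_months"]]]])
  fm <- suppressWarnings(as.numeric(fmv))
  bad <- is.na(fm) | fm < 0 | fm != floor(fm)
  if (any(bad)) {
    stop(sprintf("row %d: invalid followup_months '%s' (need a non-negative whole number)",
                 which(bad)[1], fmv[bad][1]), call. = FALSE)
  }
  out$followup_months <- as.integer(fm)
  out <- out[, rpt_fields]
  validate_cohort(out)
}

#' Write a cohort as a case-listing CSV
#'
#' Inverse of [read_case_listing()] under the default dialect: a write/read
#' round trip reproduces every field exactly.
#'
#' @param records validated cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_listing <- function(records, path) {
  records <- validate_cohort(records)
  out <- records
  for (fld in names(rpt_levels)) out[[fld]] <- as.character(out[[fld]])
  for (fld in rpt_logical_fields) {
    out[[fld]] <- ifelse(is.na(out[[fld]]), "", ifelse(out[[fld]], "true", "false"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the cohort inclusion chain
#'
#' Applies, in order: (1) primary tumors only, (2) no neoadjuvant radiation,
#' (3) surgery performed, (4) complete data.  Step (4) drops records with
#' truly absent (NA) analysis variables; the explicit `unknown` levels of
#' grade, size, marital status and extent of resection are retained as
#' modelled categories.
#'
#' @param records validated cohort data frame.
#' @return a list with `cohort` (the retained records) and `attrition`, an
#'   `rpt_attrition` data frame with one row per criterion.
#' @export
apply_inclusion_filters <- function(records) {
  records <- validate_cohort(records)
  steps <- list(
    "primary tumor"            = function(d) d$primary_tumor %in% TRUE,
    "no neoadjuvant radiation" = function(d) d$neoadjuvant_radiation %in% FALSE,
    "surgery performed"        = function(d) d$surgery_performed %in% TRUE,
    "complete data"            = function(d) stats::complete.cases(d)
  )
  report <- data.frame(criterion = character(), n_before = integer(),
                       n_excluded = integer(), n_after = integer(),
                       stringsAsFactors = FALSE)
  for (lab in names(steps)) {
    keep <- steps[[lab]](records)
    report <- rbind(report, data.frame(
      criterion = lab, n_before = nrow(records),
      n_excluded = sum(!keep), n_after = sum(keep),
      stringsAsFactors = FALSE))
    records <- records[keep, , drop = FALSE]
  }
  rownames(records) <- NULL
  class(report) <- c("rpt_attrition", "data.frame")
  list(cohort = records, attrition = report)
}

#' @export
print.rpt_attrition <- function(x, ...) {
  cat("Cohort attrition\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-26s %6d -> %6d  (excluded %d)\n",
                x$criterion[i], x$n_before[i], x$n_after[i], x$n_excluded[i]))
  }
  invisible(x)
}

#' Serialise an attrition report as JSON
#'
#' @param report an `rpt_attrition` report.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
attrition_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(unclass(report), stringsAsFactors = FALSE),
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
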