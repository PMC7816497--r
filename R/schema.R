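#' @keywords internal
"_PACKAGE"

# Canonical levels for every categorical field of a case listing.  The first
# level of each vector is the modelling reference level (youngest age band,
# male, white, married, grade I, smallest size, unifocal, solitary fibrous
# tumor, complete resection).
rpt_levels <- list(
  age_group           = c("lt65", "ge65"),
  sex                 = c("male", "female"),
  race                = c("white", "black", "api", "other"),
  marital_status      = c("married", "unmarried", "unknown"),
  fnclcc_grade        = c("I", "II", "III", "unknown"),
  size_class          = c("lt5", "s5to10", "s10to15", "ge15", "unknown"),
  multifocality       = c("no", "yes"),
  histology           = c("SFT", "MFHC", "MPNST", "LMS", "DDlipo", "WDlipo", "other"),
  extent_of_resection = c("complete", "incomplete", "unknown"),
  vital_status        = c("alive", "dead")
)

rpt_logical_fields <- c(
  "radiation", "chemotherapy", "chemoradiotherapy",
  "neoadjuvant_radiation", "surgery_performed", "primary_tumor",
  "cancer_specific_death"
)

rpt_fields <- c(
  "subject_id", names(rpt_levels)[names(rpt_levels) != "vital_status"],
  rpt_logical_fields[rpt_logical_fields != "cancer_specific_death"],
  "followup_months", "vital_status", "cancer_specific_death"
)

#' Canonical levels of a categorical case-listing field
#'
#' @param field field name, e.g. `"fnclcc_grade"`; omit for the full list.
#' @return character vector of levels (reference level first), or the named
#'   list of all level sets.
#' @export
rptcs_levels <- function(field = NULL) {
  if (is.null(field)) return(rpt_levels)
  if (!field %in% names(rpt_levels)) stop("unknown categorical field: ", field,
                                          call. = FALSE)
  rpt_levels[[field]]
}

#' Validate a cohort data frame against the case-listing schema
#'
#' Checks column presence, categorical levels, and the record invariants:
#' non-negative follow-up, `cancer_specific_death` only for dead subjects,
#' and `chemoradiotherapy` implying both chemotherapy and radiation.
#'
#' @param records data frame of subject records.
#' @return `records`, invisibly, with factor columns normalised to the
#'   canonical level order.
#' @export
validate_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(rpt_fields, names(records))
  if (length(missing) > 0L) {
    stop("cohort is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (fld in names(rpt_levels)) {
    vals <- as.character(records[[fld]])
    bad <- !is.na(vals) & !vals %in% rpt_levels[[fld]]
    if (any(bad)) {
      stop(sprintf("field '%s' contains value(s) outside its levels: %s",
                   fld, paste(unique(vals[bad]), collapse = ", ")), call. = FALSE)
    }
    records[[fld]] <- factor(vals, levels = rpt_levels[[fld]])
  }
  for (fld in rpt_logical_fields) {
    if (!is.logical(records[[fld]])) {
      stop(sprintf("field '%s' must be logical", fld), call. = FALSE)
    }
  }
  fm <- records$followup_months
  if (!is.numeric(fm) || any(!is.na(fm) & (fm < 0 | fm != floor(fm)))) {
    stop("followup_months must be non-negative whole months", call. = FALSE)
  }
  records$followup_months <- as.integer(fm)
  csd <- records$cancer_specific_death
  dead <- records$vital_status == "dead"
  if (any(!is.na(csd) & !is.na(dead) & csd & !dead)) {
    stop("cancer_specific_death = TRUE requires vital_status = dead", call. = FALSE)
  }
  crt <- records$chemoradiotherapy
  if (any(!is.na(crt) & crt &
          !(records$chemotherapy %in% TRUE & records$radiation %in% TRUE))) {
    stop("chemoradiotherapy implies both chemotherapy and radiation", call. = FALSE)
  }
  invisible(records)
}
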