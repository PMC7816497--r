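# Published reference values from the motivating population-based cohort of
# 1,594 resected primary retroperitoneal tumors, shipped as plain-text
# tables for worked examples and cross-checks.

#' Reference actual survival rates
#'
#' Reported actual OS and CSS percentages by year for the motivating
#' registry cohort (n = 1,594).
#'
#' @return data frame with `endpoint` ("os"/"css"), `years`, `percent`.
#' @export
reference_actual_rates <- function() {
  utils::read.csv(system.file("extdata", "reference_actual_survival.csv",
                              package = "rptcs"), stringsAsFactors = FALSE)
}

#' Reference three-year conditional survival rates by subgroup
#'
#' Reported COS3/CCSS3 percentages over years survived for the pooled
#' cohort and selected prognostic subgroups (FNCLCC grade, chemotherapy)
#' of the motivating registry cohort.
#'
#' @return data frame with `endpoint`, `variable`, `level`,
#'   `years_survived`, `percent`.
#' @export
reference_cs3_rates <- function() {
  utils::read.csv(system.file("extdata", "reference_cs3_subgroups.csv",
                              package = "rptcs"), stringsAsFactors = FALSE)
}
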