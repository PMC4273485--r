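survey_file <- function(name) {
  system.file("extdata", name, package = "pletools", mustWork = TRUE)
}

#' Field-survey insertion-site matrix
#'
#' Presence/absence of 21 distinct element insertion sites across 12 field
#' populations of the rice stem borer, transcribed from the published
#' transposon-display survey (check marks mapped to 1, crosses to 0).
#'
#' @return A `presence_matrix` of 21 sites x 12 populations, with the
#'   observed target-duplication and ITR sequence of each site attached as
#'   site metadata.
#' @export
#' @examples
#' pm <- load_site_matrix()
#' site_prevalence(pm)[c("site_1", "site_7")]
load_site_matrix <- function() {
  read_presence_matrix(survey_file("field_survey_insertion_sites.tsv"),
                       sites = load_site_variants())
}

#' Field-survey site-level TSD and ITR sequences
#'
#' The observed 5' target-site duplication and 5' ITR of each of the 21
#' insertion sites. Four sites carry variant duplications (CTAT, ATAT x2,
#' CTAA) and two carry variant ITRs.
#'
#' @return Data frame with `site_id`, `tsd`, `itr`.
#' @export
load_site_variants <- function() {
  utils::read.delim(survey_file("field_survey_site_variants.tsv"),
                    colClasses = "character")
}

#' Field-survey insertion frequencies
#'
#' Published per-population insertion frequency of the intact element copy
#' (mean over three replicate groups of 15 individuals, with SEM) for 21
#' field populations, with the published rank.
#'
#' @return Data frame with `rank`, `population`, `mean`, `sem`.
#' @export
load_frequency_table <- function() {
  utils::read.delim(survey_file("field_survey_insertion_frequency.tsv"),
                    colClasses = c("integer", "character", "numeric",
                                   "numeric"))
}

#' Field-survey per-region variation summary
#'
#' Published mean and SEM (over 21 populations of 4 aligned copies each) of
#' region length L, variant-position count Nv and variation rate Rv for the
#' three element regions, with the significance letter groups.
#'
#' @return Data frame with `region`, `length_mean`, `length_sem`, `nv_mean`,
#'   `nv_sem`, `rv_mean`, `rv_sem`, `letter`.
#' @export
load_variation_table <- function() {
  utils::read.delim(survey_file("field_survey_variation_rates.tsv"))
}
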