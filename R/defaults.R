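# Shipped default configuration tables: the simple-repeat exclusion
# interval, the recurrently-miscalled excluded site changes, and the
# rescue list of indel-proximity discards re-admitted after visual
# inspection. All are editable fixtures, not hard-coded constants.

#' Default excluded (position, change) pairs
#'
#' Site changes recurrently miscalled in low-coverage, low-mapping-
#' quality or homopolymer-tract regions of the canine mitochondrial
#' genome, excluded from all analyses.
#'
#' @return Data frame `position`, `ref`, `alt`, `justification`.
#' @export
default_excluded_sites <- function() {
  utils::read.delim(system.file("extdata", "excluded_sites.tsv",
                                package = "mtclade"),
                    stringsAsFactors = FALSE)
}

#' Default rescue list
#'
#' Substitutions discarded by the indel-proximity rule but re-admitted
#' after inspection of their read support.
#'
#' @return Data frame `position`, `ref`, `alt`.
#' @export
default_rescue_list <- function() {
  utils::read.delim(system.file("extdata", "rescue_sites.tsv",
                                package = "mtclade"),
                    stringsAsFactors = FALSE)
}

#' Default excluded regions
#'
#' The simple-repeat interval MT:16129-16430 (1-based inclusive).
#'
#' @return Data frame `start`, `end`.
#' @export
default_excluded_regions <- function() {
  x <- jsonlite::read_json(system.file("extdata", "default_exclusions.json",
                                       package = "mtclade"),
                           simplifyVector = TRUE)
  x$excluded_regions[, c("start", "end")]
}
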