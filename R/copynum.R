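# mtDNA copy number from sequencing coverage, and qPCR standard-curve
# arithmetic for the diagnostic assay.

#' Estimate mtDNA copies per cell
#'
#' `copies = (mtCOV / nuclCOV) * P` with ploidy P (2 by default).
#' Samples whose mtDNA coverage exceeds 300X are flagged excluded and
#' are dropped from cohort averages. Tumour copy numbers are not
#' corrected for host contamination by default; set
#' `purity_correction` to a tumour mtDNA fraction to divide it out.
#'
#' @param cov A [coverage_summary()] (one or more rows).
#' @param purity_correction Optional numeric vector of tumour mtDNA
#'   fractions aligned with `cov` rows; `NULL` (default) leaves copy
#'   numbers uncorrected.
#' @return Data frame: `sample_id`, `mt_cov`, `nucl_cov`, `ploidy`,
#'   `copies_per_cell`, `excluded`.
#' @export
estimate_copy_number <- function(cov, purity_correction = NULL) {
  cov <- as.data.frame(cov)
  if (any(cov$nucl_cov <= 0)) .stopf("nuclear coverage must be > 0")
  copies <- (cov$mt_cov / cov$nucl_cov) * cov$ploidy
  if (!is.null(purity_correction)) {
    stopifnot(length(purity_correction) == nrow(cov))
    copies <- copies / purity_correction
  }
  data.frame(sample_id = cov$sample_id, mt_cov = cov$mt_cov,
             nucl_cov = cov$nucl_cov, ploidy = cov$ploidy,
             copies_per_cell = copies,
             excluded = cov$high_coverage %in% TRUE,
             stringsAsFactors = FALSE)
}

#' qPCR standard curve
#'
#' Threshold cycle as a linear function of log10 input:
#' `Ct = m * log10(iA) + b`.
#'
#' @param m Slope (non-zero; ~ -3.32 for a perfectly efficient assay).
#' @param b Y-intercept.
#' @param target Target name.
#' @return List of class `QpcrStandardCurve`.
#' @export
qpcr_standard_curve <- function(m, b, target = "") {
  if (m == 0) .stopf("standard-curve slope must be non-zero")
  structure(list(m = m, b = b, target = target),
            class = "QpcrStandardCurve")
}

#' Relative DNA input from a qPCR threshold cycle
#'
#' Inverts the standard curve, `iA = 10^((Ct - b) / m)`, and normalises
#' to the input of a reference target.
#'
#' @param ct Threshold cycle(s).
#' @param curve A [qpcr_standard_curve()].
#' @param normalizer_input Relative input of the normaliser target
#'   (e.g. a housekeeping gene); must be > 0.
#' @return Normalised relative input.
#' @export
qpcr_relative_input <- function(ct, curve, normalizer_input = 1) {
  if (normalizer_input <= 0) .stopf("normaliser input must be > 0")
  ia <- 10^((ct - curve$b) / curve$m)
  ia / normalizer_input
}
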