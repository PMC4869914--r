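# Strand-aware 96-class trinucleotide mutation spectrum with
# triplet-frequency normalisation.
#
# Pyrimidine changes with respect to the reference (light) strand are
# light-strand mutations and keep their reference flanks; purine changes
# are complemented into pyrimidine context on the heavy strand, so the
# heavy-strand flanks are the reverse complement of the reference
# context. 6 substitution types x 16 flank pairs x 2 strands = 192
# potential classes, of which the 96 per strand use that strand's
# pyrimidine-centred triplet census for normalisation.

.PYRIMIDINE_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Assign a substitution to its strand-aware spectrum class
#'
#' @param ref An [mt_reference()].
#' @param position 1-based position.
#' @param ref_base,alt_base The change, on the reference (light) strand.
#' @return List with `sub` (pyrimidine substitution type), `five`,
#'   `three` (flanks on the assigned strand), `strand`, `triplet` and
#'   `class` (e.g. `"T[C>T]G"`).
#' @export
assign_class <- function(ref, position, ref_base, alt_base) {
  position <- as.integer(position)
  if (nchar(ref_base) != 1L || nchar(alt_base) != 1L) {
    .stopf("assign_class handles substitutions only")
  }
  chars <- .seq_chars(ref$sequence)
  if (chars[position] != ref_base) {
    .stopf("ref base mismatch at %d: reference has %s, got %s",
           position, chars[position], ref_base)
  }
  five_l <- chars[.circ(position - 1L, ref$length)]
  three_l <- chars[.circ(position + 1L, ref$length)]
  if (ref_base %in% c("C", "T")) {
    strand <- "light"
    sub <- paste0(ref_base, ">", alt_base)
    five <- five_l
    three <- three_l
  } else {
    strand <- "heavy"
    sub <- paste0(.complement(ref_base), ">", .complement(alt_base))
    five <- .complement(three_l)
    three <- .complement(five_l)
  }
  list(sub = sub, five = five, three = three, strand = strand,
       triplet = paste0(five, substr(sub, 1L, 1L), three),
       class = paste0(five, "[", sub, "]", three))
}

# the 96-row class skeleton for one strand
#' @noRd
.class_grid <- function(strand) {
  g <- expand.grid(five = c("A", "C", "G", "T"),
                   sub = .PYRIMIDINE_SUBS,
                   three = c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)
  g <- g[order(g$sub, g$five, g$three), ]
  data.frame(strand = strand, sub = g$sub, five = g$five, three = g$three,
             triplet = paste0(g$five, substr(g$sub, 1L, 1L), g$three),
             class = paste0(g$five, "[", g$sub, "]", g$three),
             stringsAsFactors = FALSE)
}

#' Expected mutation counts per spectrum class
#'
#' For a class on strand s with pyrimidine-centred triplet t,
#' `expected = N_total * freq_s(t) / 3`, where `freq_s(t)` is the
#' triplet count on strand s divided by the genome length (excluded
#' positions are removed from the census but the denominator stays the
#' full genome length, following the published worked example). In
#' presentation mode the frequency is rounded to 3 decimal places
#' before use, reproducing printed values.
#'
#' @param census_heavy,census_light [count_triplets()] results for the
#'   two strands.
#' @param n_total Total number of observed mutations.
#' @param genome_length Reference length in bp.
#' @param presentation Round frequencies to 3 dp before computing.
#' @return Data frame of 192 rows: `strand`, `sub`, `five`, `three`,
#'   `triplet`, `class`, `expected`.
#' @export
expected_counts <- function(census_heavy, census_light, n_total,
                            genome_length, presentation = FALSE) {
  if (n_total < 0) .stopf("n_total must be >= 0")
  if (census_heavy$n_counted == 0L && census_light$n_counted == 0L) {
    .stopf("empty triplet census")
  }
  grid <- rbind(.class_grid("heavy"), .class_grid("light"))
  counts <- ifelse(grid$strand == "heavy",
                   census_heavy$counts[grid$triplet],
                   census_light$counts[grid$triplet])
  freq <- counts / genome_length
  if (presentation) freq <- round(freq, 3)
  grid$expected <- n_total * freq / 3
  rownames(grid) <- NULL
  grid
}

#' Observed/expected normalised spectrum
#'
#' @param observed Data frame with `strand`, `class`, `observed` (or a
#'   vector aligned with `expected`).
#' @param expected Output of [expected_counts()].
#' @param presentation Round expected to 2 dp before the ratio and the
#'   ratio itself to 2 dp, matching printed values; otherwise full
#'   precision.
#' @return `SpectrumResult` data frame: the 192 classes with
#'   `observed`, `expected`, `rate` and an `infinite` flag for classes
#'   observed with zero expectation; total count in attribute
#'   `n_total`.
#' @export
normalized_rates <- function(observed, expected, presentation = FALSE) {
  out <- expected
  if (is.data.frame(observed)) {
    key_o <- paste(observed$strand, observed$class)
    key_e <- paste(out$strand, out$class)
    out$observed <- 0
    m <- match(key_o, key_e)
    if (anyNA(m)) .stopf("observed class not in expected grid")
    out$observed[m] <- observed$observed
  } else {
    stopifnot(length(observed) == nrow(out))
    out$observed <- observed
  }
  exp_use <- if (presentation) round(out$expected, 2) else out$expected
  out$rate <- ifelse(exp_use > 0, out$observed / exp_use,
                     ifelse(out$observed == 0, 0, Inf))
  if (presentation) out$rate <- round(out$rate, 2)
  out$infinite <- is.infinite(out$rate)
  attr(out, "n_total") <- sum(out$observed)
  out
}

#' Compute the full spectrum of a variant list
#'
#' Convenience wrapper: classifies each substitution with
#' [assign_class()], tallies observed counts, computes expectations
#' from the two strand censuses and returns the normalised spectrum.
#'
#' @param ref An [mt_reference()].
#' @param variants Data frame with `position`, `ref`, `alt`
#'   (substitutions only; excluded positions must already be removed).
#' @param presentation Presentation-rounding mode.
#' @return A `SpectrumResult` (see [normalized_rates()]).
#' @export
compute_spectrum <- function(ref, variants, presentation = FALSE) {
  ch <- count_triplets(ref, "heavy")
  cl <- count_triplets(ref, "light")
  n <- nrow(variants)
  exp_df <- expected_counts(ch, cl, n, ref$length,
                            presentation = presentation)
  obs <- integer(nrow(exp_df))
  key_e <- paste(exp_df$strand, exp_df$class)
  if (n) {
    for (i in seq_len(n)) {
      cls <- assign_class(ref, variants$position[i], variants$ref[i],
                          variants$alt[i])
      j <- match(paste(cls$strand, cls$class), key_e)
      obs[j] <- obs[j] + 1L
    }
  }
  normalized_rates(obs, exp_df, presentation = presentation)
}
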