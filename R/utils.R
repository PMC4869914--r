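# Internal helpers shared across modules.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' @noRd
.complement <- function(bases) {
  unname(COMPLEMENT[bases])
}

#' @noRd
.revcomp <- function(s) {
  paste(rev(unname(COMPLEMENT[strsplit(s, "")[[1]]])), collapse = "")
}

# 1-based circular position wrap
#' @noRd
.circ <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

#' @noRd
.seq_chars <- function(sequence) {
  strsplit(sequence, "")[[1]]
}

# variant key "pos ref>alt", the canonical identity used for set operations
#' @noRd
.variant_key <- function(position, ref, alt) {
  paste0(position, " ", ref, ">", alt)
}

#' @noRd
.stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' @noRd
.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == as.integer(x)
}

# all 64 trinucleotides in fixed lexicographic order
#' @noRd
.all_triplets <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
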