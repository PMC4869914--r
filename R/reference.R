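#' Construct a circular mitochondrial reference
#'
#' An `MtReference` bundles the circular mtDNA sequence (light strand, the
#' reference strand), protein-coding gene annotations, and the positions
#' excluded from variant and spectrum analysis: a simple-repeat interval
#' (by default MT:16129-16430 on the canine mitochondrial genome) and a
#' list of recurrently miscalled (position, base-change) pairs.
#'
#' @param sequence Character scalar, the light-strand sequence (A/C/G/T/N).
#' @param genes Data frame with columns `name`, `start`, `end` (1-based
#'   inclusive), `strand` ("heavy" or "light") and optionally `frame`
#'   (0-based offset of the first complete codon, default 0).
#' @param excluded_regions Data frame with columns `start`, `end`
#'   (1-based inclusive intervals excluded from analysis), or `NULL`.
#' @param excluded_sites Data frame with columns `position`, `ref`, `alt`
#'   (specific base changes excluded from analysis), or `NULL`.
#' @param max_n_fraction Maximum tolerated fraction of N characters.
#'
#' @return An object of class `MtReference`.
#' @export
mt_reference <- function(sequence, genes = NULL, excluded_regions = NULL,
                         excluded_sites = NULL, max_n_fraction = 0.01) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len < 3L) .stopf("reference sequence must be at least 3 bp, got %d", len)
  chars <- .seq_chars(sequence)
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    .stopf("non-ACGTN character(s) in sequence at position(s) %s",
           paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (mean(chars == "N") > max_n_fraction) {
    .stopf("N fraction %.3f exceeds allowed maximum %.3f",
           mean(chars == "N"), max_n_fraction)
  }

  genes <- .validate_genes(genes, len)
  excluded_regions <- .validate_regions(excluded_regions, len)
  excluded_sites <- .validate_sites(excluded_sites, len, chars)

  structure(
    list(sequence = sequence, length = len, genes = genes,
         excluded_regions = excluded_regions, excluded_sites = excluded_sites),
    class = "MtReference"
  )
}

.validate_genes <- function(genes, len) {
  if (is.null(genes) || nrow(genes) == 0L) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("name", "start", "end", "strand") %in% names(genes)))
  if (is.null(genes$frame)) genes$frame <- 0L
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$frame <- as.integer(genes$frame)
  if (any(genes$start < 1L) || any(genes$end > len)) {
    .stopf("gene coordinates outside [1, %d]", len)
  }
  if (any(genes$start > genes$end)) {
    .stopf("gene start > end (origin-spanning genes are not supported)")
  }
  if (!all(genes$strand %in% c("heavy", "light"))) {
    .stopf("gene strand must be 'heavy' or 'light'")
  }
  if (sum(genes$strand == "light") > 1L) {
    .stopf("at most one light-strand-transcribed gene is supported")
  }
  # overlaps are reported, not silently resolved
  if (nrow(genes) > 1L) {
    o <- order(genes$start)
    gs <- genes[o, ]
    overlap <- which(gs$start[-1L] <= gs$end[-nrow(gs)])
    if (length(overlap)) {
      .stopf("overlapping gene annotations: %s and %s",
             gs$name[overlap[1L]], gs$name[overlap[1L] + 1L])
    }
  }
  genes
}

.validate_regions <- function(regions, len) {
  if (is.null(regions) || nrow(regions) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  stopifnot(all(c("start", "end") %in% names(regions)))
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$start < 1L) || any(regions$end > len) ||
      any(regions$start > regions$end)) {
    .stopf("excluded region outside [1, %d] or inverted", len)
  }
  regions[, c("start", "end")]
}

.validate_sites <- function(sites, len, chars) {
  if (is.null(sites) || nrow(sites) == 0L) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("position", "ref", "alt") %in% names(sites)))
  sites$position <- as.integer(sites$position)
  if (any(sites$position < 1L) || any(sites$position > len)) {
    .stopf("excluded site outside [1, %d]", len)
  }
  sites[, c("position", "ref", "alt")]
}

#' @export
print.MtReference <- function(x, ...) {
  cat(sprintf("MtReference: %d bp circular genome, %d gene(s), %d excluded region(s), %d excluded site(s)\n",
              x$length, nrow(x$genes), nrow(x$excluded_regions),
              nrow(x$excluded_sites)))
  invisible(x)
}

#' Load a mitochondrial reference from FASTA and a gene table
#'
#' @param fasta_path Path to a single-record FASTA file (light strand).
#' @param gene_table_path Path to a tab-separated gene table with header
#'   columns `name`, `start`, `end`, `strand`, `frame` (frame optional).
#'   `NULL` for a gene-less reference.
#' @param exclusions Either `NULL`, or a list with elements
#'   `excluded_regions` (data frame `start`, `end`) and `excluded_sites`
#'   (data frame `position`, `ref`, `alt`), or a path to a JSON file with
#'   keys `excluded_regions` and `excluded_sites`.
#' @inheritParams mt_reference
#' @return An [mt_reference()] object.
#' @export
load_reference <- function(fasta_path, gene_table_path = NULL,
                           exclusions = NULL, max_n_fraction = 0.01) {
  if (!file.exists(fasta_path)) .stopf("FASTA file not found: %s", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    .stopf("expected exactly one FASTA record, found %d", length(seqs))
  }
  sequence <- as.character(seqs[[1L]])

  genes <- NULL
  if (!is.null(gene_table_path)) {
    if (!file.exists(gene_table_path)) {
      .stopf("gene table not found: %s", gene_table_path)
    }
    genes <- utils::read.delim(gene_table_path, stringsAsFactors = FALSE)
  }

  if (is.character(exclusions)) {
    exclusions <- jsonlite::read_json(exclusions, simplifyVector = TRUE)
  }
  mt_reference(sequence, genes,
               excluded_regions = exclusions$excluded_regions,
               excluded_sites = exclusions$excluded_sites,
               max_n_fraction = max_n_fraction)
}

#' Positions excluded from analysis
#'
#' Union of all positions inside excluded regions. Excluded (position,
#' change) pairs are position-specific for variant filtering but their
#' positions are also omitted from triplet counting.
#'
#' @param ref An [mt_reference()] object.
#' @param include_sites Also include positions of excluded site pairs.
#' @return Sorted integer vector of 1-based positions.
#' @export
excluded_positions <- function(ref, include_sites = TRUE) {
  pos <- integer()
  if (nrow(ref$excluded_regions)) {
    pos <- unlist(Map(seq.int, ref$excluded_regions$start,
                      ref$excluded_regions$end))
  }
  if (include_sites && nrow(ref$excluded_sites)) {
    pos <- c(pos, ref$excluded_sites$position)
  }
  sort(unique(as.integer(pos)))
}

#' Count trinucleotides on a strand of a circular genome
#'
#' Every non-excluded position contributes one centred triplet; the genome
#' is circular, so triplets at the origin wrap around. Heavy-strand
#' triplets are the reverse complements of the light-strand (reference)
#' triplets at the same positions.
#'
#' @param ref An [mt_reference()] object.
#' @param strand `"heavy"` or `"light"`.
#' @return A `TripletCensus`: list with `strand`, `counts` (named integer
#'   vector over the 64 triplets) and `n_counted`.
#' @export
count_triplets <- function(ref, strand = c("heavy", "light")) {
  strand <- match.arg(strand)
  chars <- .seq_chars(ref$sequence)
  len <- ref$length
  excl <- excluded_positions(ref, include_sites = TRUE)
  pos <- setdiff(seq_len(len), excl)

  five <- chars[.circ(pos - 1L, len)]
  mid <- chars[pos]
  three <- chars[.circ(pos + 1L, len)]
  if (strand == "light") {
    trip <- paste0(five, mid, three)
  } else {
    trip <- paste0(.complement(three), .complement(mid), .complement(five))
  }
  counts <- integer(64L)
  names(counts) <- .all_triplets()
  tab <- table(trip[!grepl("N", trip, fixed = TRUE)])
  counts[names(tab)] <- as.integer(tab)

  structure(list(strand = strand, counts = counts,
                 n_counted = sum(counts)),
            class = "TripletCensus")
}

# gene containing a position, or NULL
#' @noRd
.gene_at <- function(ref, position) {
  g <- ref$genes
  hit <- which(g$start <= position & g$end >= position)
  if (!length(hit)) return(NULL)
  g[hit[1L], ]
}

#' Annotate the coding consequence of a point substitution
#'
#' Classifies a substitution as `synonymous`, `missense`, `nonsense` or
#' `non_coding` using the codon on the gene's coding strand and the
#' vertebrate mitochondrial genetic code (NCBI translation table 2, where
#' TGA encodes Trp and AGA/AGG are stops).
#'
#' @param ref An [mt_reference()] object.
#' @param position 1-based position on the reference (light) strand.
#' @param ref_base,alt_base Reference and alternate bases, given on the
#'   reference strand.
#' @param genetic_code Named character vector mapping codons to amino
#'   acids; defaults to translation table 2.
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`,
#'   `"non_coding"`.
#' @export
annotate_consequence <- function(ref, position, ref_base, alt_base,
                                 genetic_code = mito_genetic_code()) {
  position <- as.integer(position)
  if (position < 1L || position > ref$length) {
    .stopf("position %d outside [1, %d]", position, ref$length)
  }
  chars <- .seq_chars(ref$sequence)
  if (chars[position] != ref_base) {
    .stopf("ref base mismatch at %d: reference has %s, got %s",
           position, chars[position], ref_base)
  }
  if (!(alt_base %in% c("A", "C", "G", "T")) || alt_base == ref_base) {
    .stopf("invalid alt base %s at position %d", alt_base, position)
  }
  gene <- .gene_at(ref, position)
  if (is.null(gene)) return("non_coding")

  # offset within gene on the coding strand, after the frame adjustment
  if (gene$strand == "heavy") {
    # heavy-strand gene: coding sequence is the reverse complement of the
    # reference interval, read from 'end' towards 'start'
    off <- gene$end - position - gene$frame
  } else {
    off <- position - gene$start - gene$frame
  }
  if (off < 0L) return("non_coding")        # inside the frame-skipped prefix
  codon_i <- off %/% 3L
  within <- off %% 3L
  # reference-strand positions of the codon, coding-strand 5'->3'
  if (gene$strand == "heavy") {
    codon_pos <- gene$end - gene$frame - (codon_i * 3L) - (0:2)
    if (min(codon_pos) < gene$start) return("non_coding")  # incomplete terminal codon
    codon_ref <- .complement(chars[codon_pos])
    sub_base <- .complement(ref_base); sub_alt <- .complement(alt_base)
  } else {
    codon_pos <- gene$start + gene$frame + (codon_i * 3L) + (0:2)
    if (max(codon_pos) > gene$end) return("non_coding")
    codon_ref <- chars[codon_pos]
    sub_base <- ref_base; sub_alt <- alt_base
  }
  stopifnot(codon_ref[within + 1L] == sub_base)
  codon_alt <- codon_ref
  codon_alt[within + 1L] <- sub_alt
  aa_ref <- genetic_code[[paste(codon_ref, collapse = "")]]
  aa_alt <- genetic_code[[paste(codon_alt, collapse = "")]]
  if (is.null(aa_ref) || is.null(aa_alt)) return("non_coding")  # N in codon
  if (aa_alt == aa_ref) return("synonymous")
  if (aa_alt == "*") return("nonsense")
  "missense"
}

#' Vertebrate mitochondrial genetic code (translation table 2)
#'
#' @return Named character vector of 64 codons to one-letter amino acids,
#'   with `"*"` for stop.
#' @export
mito_genetic_code <- function() {
  gc <- Biostrings::getGeneticCode("2")
  out <- as.character(gc)
  names(out) <- names(gc)
  out
}
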