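# Fixtures built in code and independent oracles used across tests.

# deterministic random sequence
rand_seq <- function(n, seed = 1, bases = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# small reference with one heavy-strand and one light-strand gene
tiny_ref <- function(seed = 11, len = 300L) {
  sequence <- rand_seq(len, seed)
  h_len <- (floor(len * 0.45) %/% 3L) * 3L
  l_len <- (floor(len * 0.2) %/% 3L) * 3L
  l_start <- 10L + h_len + 10L
  genes <- data.frame(
    name = c("H1", "L1"),
    start = c(10L, l_start), end = c(10L + h_len - 1L, l_start + l_len - 1L),
    strand = c("heavy", "light"), frame = 0L, stringsAsFactors = FALSE)
  mt_reference(sequence, genes)
}

# --- oracle: consequence by whole-protein translate-and-compare -------
# Independent path: rebuild the full coding sequence as a string, apply
# the substitution, translate both with Biostrings::translate, diff the
# proteins.
oracle_consequence <- function(ref, position, ref_base, alt_base) {
  chars <- strsplit(ref$sequence, "")[[1]]
  g <- ref$genes
  hit <- which(g$start <= position & g$end >= position)
  if (!length(hit)) return("non_coding")
  gene <- g[hit[1], ]
  region <- paste(chars[gene$start:gene$end], collapse = "")
  mut_chars <- chars
  mut_chars[position] <- alt_base
  region_mut <- paste(mut_chars[gene$start:gene$end], collapse = "")
  if (gene$strand == "heavy") {
    region <- revcomp_chr(region)
    region_mut <- revcomp_chr(region_mut)
  }
  if (gene$frame > 0) {
    region <- substr(region, gene$frame + 1L, nchar(region))
    region_mut <- substr(region_mut, gene$frame + 1L, nchar(region_mut))
  }
  usable <- (nchar(region) %/% 3L) * 3L
  if (usable == 0L) return("non_coding")
  cds <- substr(region, 1L, usable)
  cds_mut <- substr(region_mut, 1L, usable)
  tr <- function(x) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(x),
      genetic.code = Biostrings::getGeneticCode("2"),
      no.init.codon = TRUE, if.fuzzy.codon = "X"))
  }
  p0 <- tr(cds)
  p1 <- tr(cds_mut)
  if (identical(p0, p1)) {
    # position may fall in an incomplete terminal codon
    cs <- if (gene$strand == "heavy") gene$end - position else
      position - gene$start
    if (cs < gene$frame || cs - gene$frame >= usable) return("non_coding")
    return("synonymous")
  }
  d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
  aa_new <- substr(p1, d, d)
  if (aa_new == "*") "nonsense" else "missense"
}

# --- oracle: triplet census by per-position walk ----------------------
oracle_triplet_count <- function(sequence, strand, excluded = integer()) {
  chars <- strsplit(sequence, "")[[1]]
  len <- length(chars)
  counts <- integer()
  for (p in setdiff(seq_len(len), excluded)) {
    i5 <- ((p - 2) %% len) + 1
    i3 <- (p %% len) + 1
    trip <- paste0(chars[i5], chars[p], chars[i3])
    if (strand == "heavy") trip <- revcomp_chr(trip)
    counts[trip] <- (if (is.na(counts[trip])) 0L else counts[trip]) + 1L
  }
  counts
}

# --- oracle: exact two-sample KS p by enumeration ---------------------
# Exact null distribution over all C(n+m, n) assignments of the pooled
# (tie-free) values; p = P(D >= observed D).
oracle_ks_exact_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  d_stat <- function(x, y) {
    grid <- sort(c(x, y))
    max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
  }
  d_obs <- d_stat(a, b)
  idx <- utils::combn(length(pooled), length(a))
  ds <- apply(idx, 2, function(i) d_stat(pooled[i], pooled[-i]))
  mean(ds >= d_obs - 1e-12)
}

# substitution call row with sensible defaults, overridable
make_sub <- function(sample_id = "T1", position = 100L, ref = "C",
                     alt = "T", mutant_reads = 35L, total_depth = 70L,
                     fwd_mut = NULL, rev_mut = NULL,
                     fwd_ref = NULL, rev_ref = NULL,
                     bq25_count = NULL, mean_mq = 60,
                     read_end_only = FALSE, rep_count = 0L) {
  if (is.null(fwd_mut)) fwd_mut <- mutant_reads %/% 2L
  if (is.null(rev_mut)) rev_mut <- mutant_reads - fwd_mut
  ref_reads <- total_depth - mutant_reads
  if (is.null(fwd_ref)) fwd_ref <- ref_reads %/% 2L
  if (is.null(rev_ref)) rev_ref <- ref_reads - fwd_ref
  if (is.null(bq25_count)) bq25_count <- mutant_reads
  data.frame(sample_id = sample_id, position = position, ref = ref,
             alt = alt, kind = "substitution",
             mutant_reads = mutant_reads, total_depth = total_depth,
             fwd_mut = fwd_mut, rev_mut = rev_mut, fwd_ref = fwd_ref,
             rev_ref = rev_ref, bq25_count = bq25_count,
             mean_mq = mean_mq, read_end_only = read_end_only,
             rep_count = rep_count, pindel_reads = NA_integer_,
             bwa_reads = NA_integer_, stringsAsFactors = FALSE)
}

make_indel <- function(sample_id = "T1", position = 100L, ref = "CA",
                       alt = "C", fwd_mut = 3L, rev_mut = 3L,
                       pindel_reads = NULL, bwa_reads = 2L,
                       rep_count = 0L, total_depth = 70L) {
  mutant <- fwd_mut + rev_mut
  if (is.null(pindel_reads)) pindel_reads <- mutant
  kind <- if (nchar(ref) > nchar(alt)) "deletion" else "insertion"
  data.frame(sample_id = sample_id, position = position, ref = ref,
             alt = alt, kind = kind, mutant_reads = mutant,
             total_depth = total_depth, fwd_mut = fwd_mut,
             rev_mut = rev_mut, fwd_ref = 30L,
             rev_ref = total_depth - mutant - 30L,
             bq25_count = mutant, mean_mq = 60, read_end_only = FALSE,
             rep_count = rep_count, pindel_reads = pindel_reads,
             bwa_reads = bwa_reads, stringsAsFactors = FALSE)
}
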