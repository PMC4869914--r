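# Synthetic-data generator.
#
# Emulates the statistical structure the analysis assumes: several
# tumour clades, each founded by the capture of a distinct donor mtDNA
# haplotype; Poisson accumulation of somatic substitutions under a
# strand-biased, C>T/T>C-dominated trinucleotide spectrum; negative
# selection implemented as consequence-specific thinning of candidate
# mutations; Beta-distributed heteroplasmy; host contamination mixing
# host-haplotype alleles into tumour read support; and binomial read
# sampling around ~70X mtDNA coverage. The emitted tables are in the
# calls_io dialect, so simulator output is a drop-in pipeline fixture.

#' Simulation configuration
#'
#' Defaults state the cohort the analysis was designed for, scaled to
#' desk size: five clades with the published age point estimates and
#' the published somatic rate and selection coefficients.
#'
#' @param seed Integer master seed; every stage derives a named
#'   substream from it.
#' @param genome_length Reference length in bp.
#' @param n_clades Number of tumour clades (capture events).
#' @param tumours_per_clade Integer vector of length `n_clades`.
#' @param clade_ages_years Years since each capture event.
#' @param mu Somatic substitutions per year (realised, post-selection).
#' @param donor_divergence Germline substitutions on each donor
#'   haplotype relative to the reference.
#' @param host_divergence Germline substitutions on each host's own
#'   haplotype.
#' @param spectrum_weights Named numeric vector over the 192
#'   strand-by-class spectrum categories, summing to 1; see
#'   [default_spectrum_weights()].
#' @param w_mis,w_non,w_frameshift Selection coefficients: acceptance
#'   probability of a candidate missense / nonsense substitution or
#'   frameshift indel.
#' @param het_prob Probability a somatic variant is heteroplasmic.
#' @param het_beta Beta shape parameters of the heteroplasmic cell
#'   fraction.
#' @param contamination_range Per-tumour host contamination drawn
#'   uniformly from this interval.
#' @param mt_coverage,nucl_coverage Mean mtDNA and nuclear coverage.
#' @param indel_rate Somatic indels per year (pre-selection).
#' @param panel_extra Extra random variants added to the normal-dog
#'   germline panel.
#' @return Named list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2000L,
                       n_clades = 5L,
                       tumours_per_clade = c(8L, 8L, 4L, 3L, 2L),
                       clade_ages_years = c(1097, 460, 244, 1690, 585),
                       mu = 0.0205,
                       donor_divergence = 12L,
                       host_divergence = 10L,
                       spectrum_weights = NULL,
                       w_mis = 0.748, w_non = 0.187, w_frameshift = 0.187,
                       het_prob = 0.15, het_beta = c(8, 2),
                       contamination_range = c(0, 0.3),
                       mt_coverage = 70, nucl_coverage = 0.3,
                       indel_rate = 1e-4,
                       panel_extra = 50L) {
  stopifnot(length(tumours_per_clade) == n_clades,
            length(clade_ages_years) == n_clades,
            mu >= 0, indel_rate >= 0,
            w_mis >= 0, w_non >= 0, w_frameshift >= 0,
            het_prob >= 0, het_prob <= 1,
            all(contamination_range >= 0), all(contamination_range <= 1))
  if (is.null(spectrum_weights)) spectrum_weights <- default_spectrum_weights()
  if (abs(sum(spectrum_weights) - 1) > 1e-8) {
    .stopf("spectrum weights must sum to 1")
  }
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_clades = n_clades, tumours_per_clade = tumours_per_clade,
                 clade_ages_years = clade_ages_years, mu = mu,
                 donor_divergence = donor_divergence,
                 host_divergence = host_divergence,
                 spectrum_weights = spectrum_weights,
                 w_mis = w_mis, w_non = w_non, w_frameshift = w_frameshift,
                 het_prob = het_prob, het_beta = het_beta,
                 contamination_range = contamination_range,
                 mt_coverage = mt_coverage, nucl_coverage = nucl_coverage,
                 indel_rate = indel_rate, panel_extra = panel_extra),
            class = "SimulationConfig")
}

#' Default strand-biased spectrum weights
#'
#' C>T on the heavy strand and T>C on the light strand dominate, with
#' the opposite-strand counterparts depressed, mimicking the
#' replication-coupled somatic mtDNA mutational process.
#'
#' @return Named numeric vector of length 192 summing to 1; names are
#'   `"<strand> <class>"` (e.g. `"heavy T[C>T]G"`).
#' @export
default_spectrum_weights <- function() {
  grid <- rbind(.class_grid("heavy"), .class_grid("light"))
  w <- rep(1, nrow(grid))
  w[grid$sub == "C>T" & grid$strand == "heavy"] <- 30
  w[grid$sub == "T>C" & grid$strand == "light"] <- 30
  w[grid$sub == "C>T" & grid$strand == "light"] <- 5
  w[grid$sub == "T>C" & grid$strand == "heavy"] <- 5
  stats::setNames(w / sum(w), paste(grid$strand, grid$class))
}

# named substream: every stage reseeds deterministically from the
# master seed so stages are individually reproducible
#' @noRd
.substream <- function(seed, name) {
  offset <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  set.seed((as.integer(seed) * 7919L + offset) %% 2147483647L)
}

#' Simulate a circular mitochondrial reference
#'
#' Random circular genome with one long heavy-strand gene and
#' (optionally) one short light-strand gene standing in for the single
#' light-strand-transcribed gene of vertebrate mtDNA.
#'
#' @param length Genome length in bp (>= 60).
#' @param gc GC weight in (0, 1); 0 gives an A/T-only genome.
#' @param light_gene Include a light-strand gene.
#' @param seed Integer seed.
#' @return An [mt_reference()].
#' @export
simulate_reference <- function(length = 2000L, gc = 0.4,
                               light_gene = TRUE, seed = 1L) {
  length <- as.integer(length)
  if (length < 60L) .stopf("genome length must be >= 60, got %d", length)
  .substream(seed, "reference")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequence <- paste(sample(names(probs), length, replace = TRUE,
                           prob = probs), collapse = "")
  # heavy gene over ~55% of the genome, light gene over ~15%
  h_len <- (floor(length * 0.55) %/% 3L) * 3L
  h_start <- 21L
  h_end <- h_start + h_len - 1L
  genes <- data.frame(name = "HG1", start = h_start, end = h_end,
                      strand = "heavy", frame = 0L,
                      stringsAsFactors = FALSE)
  if (light_gene) {
    l_len <- (floor(length * 0.15) %/% 3L) * 3L
    l_start <- h_end + 11L
    l_end <- l_start + l_len - 1L
    if (l_end > length - 5L) .stopf("gene layout infeasible for length %d", length)
    genes <- rbind(genes, data.frame(name = "LG1", start = l_start,
                                     end = l_end, strand = "light",
                                     frame = 0L, stringsAsFactors = FALSE))
  }
  mt_reference(sequence, genes)
}

# map from "strand class" to candidate positions, honouring exclusions
#' @noRd
.class_position_map <- function(ref) {
  chars <- .seq_chars(ref$sequence)
  excl <- excluded_positions(ref)
  pos <- setdiff(seq_len(ref$length), excl)
  five_l <- chars[.circ(pos - 1L, ref$length)]
  mid <- chars[pos]
  three_l <- chars[.circ(pos + 1L, ref$length)]
  is_pyr <- mid %in% c("C", "T")
  strand <- ifelse(is_pyr, "light", "heavy")
  centre <- ifelse(is_pyr, mid, .complement(mid))
  five <- ifelse(is_pyr, five_l, .complement(three_l))
  three <- ifelse(is_pyr, three_l, .complement(five_l))
  key <- paste(strand, paste0(five, centre, three))
  split(pos, key)
}

# draw one accepted somatic substitution; returns position/ref/alt and
# consequence, or NULL after too many rejections
#' @noRd
.draw_substitution <- function(ref, chars, pos_map, weights, w_accept,
                               taken) {
  class_grid <- rbind(.class_grid("heavy"), .class_grid("light"))
  keys <- paste(class_grid$strand, class_grid$triplet)
  for (attempt in seq_len(2000L)) {
    i <- sample.int(nrow(class_grid), 1L, prob = weights)
    cand <- pos_map[[keys[i]]]
    cand <- setdiff(cand, taken)
    if (!length(cand)) next
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    to <- substr(class_grid$sub[i], 3L, 3L)
    if (class_grid$strand[i] == "light") {
      ref_b <- chars[p]; alt_b <- to
    } else {
      ref_b <- chars[p]; alt_b <- .complement(to)
    }
    cons <- annotate_consequence(ref, p, ref_b, alt_b)
    w <- switch(cons, missense = w_accept[["mis"]],
                nonsense = w_accept[["non"]], 1)
    if (stats::runif(1L) <= w) {
      return(list(position = p, ref = ref_b, alt = alt_b,
                  consequence = cons))
    }
  }
  NULL
}

# binomially sampled read support row in the calls_io dialect
#' @noRd
.support_row <- function(sample_id, position, ref, alt, kind, true_vaf,
                         mt_coverage, indel = FALSE, rep_count = 0L) {
  depth <- max(stats::rpois(1L, mt_coverage), 1L)
  mutant <- stats::rbinom(1L, depth, min(true_vaf, 1))
  if (mutant == 0L) return(NULL)   # variant not called in this sample
  fwd_mut <- stats::rbinom(1L, mutant, 0.5)
  ref_reads <- depth - mutant
  fwd_ref <- stats::rbinom(1L, ref_reads, 0.5)
  data.frame(
    sample_id = sample_id, position = position, ref = ref, alt = alt,
    kind = kind, mutant_reads = mutant, total_depth = depth,
    fwd_mut = fwd_mut, rev_mut = mutant - fwd_mut,
    fwd_ref = fwd_ref, rev_ref = ref_reads - fwd_ref,
    bq25_count = stats::rbinom(1L, mutant, 0.95),
    mean_mq = 60, read_end_only = FALSE, rep_count = rep_count,
    pindel_reads = if (indel) mutant else NA_integer_,
    bwa_reads = if (indel) stats::rbinom(1L, mutant, 0.8) else NA_integer_,
    stringsAsFactors = FALSE)
}

#' Simulate a tumour/host cohort
#'
#' @param config A [sim_config()].
#' @param ref An [mt_reference()]; defaults to
#'   [simulate_reference()] under the config seed.
#' @return List of class `SimulatedCohort`:
#'   `variants` (a [variant_table()] over all tumour and host samples),
#'   `coverage` (a [coverage_summary()]),
#'   `truth` (list: `variant_truth` data frame with per-variant labels,
#'   `tumour_meta` with true clade / contamination / tumour fraction,
#'   `donor_haplotypes`, `host_haplotypes`, `dog_panel`, `clades`),
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), ref = NULL) {
  if (is.null(ref)) {
    ref <- simulate_reference(config$genome_length, seed = config$seed)
  }
  chars <- .seq_chars(ref$sequence)
  pos_map <- .class_position_map(ref)
  excl <- excluded_positions(ref)
  free_pos <- setdiff(seq_len(ref$length), excl)

  # --- donor and host haplotypes -------------------------------------
  .substream(config$seed, "haplotypes")
  n_tumours <- sum(config$tumours_per_clade)
  n_hap_vars <- config$n_clades * config$donor_divergence +
    n_tumours * config$host_divergence + config$panel_extra
  hap_pos <- sample(free_pos, n_hap_vars)
  rand_var <- function(p) {
    ref_b <- chars[p]
    alt_b <- vapply(ref_b, function(b) sample(setdiff(.BASES, b), 1L), "")
    data.frame(position = p, ref = ref_b, alt = unname(alt_b),
               stringsAsFactors = FALSE)
  }
  cursor <- 0L
  take <- function(k) {
    out <- hap_pos[(cursor + 1L):(cursor + k)]
    cursor <<- cursor + k
    out
  }
  donor_haps <- lapply(seq_len(config$n_clades), function(cl) {
    rand_var(take(config$donor_divergence))
  })
  names(donor_haps) <- as.character(seq_len(config$n_clades))
  host_haps <- lapply(seq_len(n_tumours), function(i) {
    rand_var(take(config$host_divergence))
  })
  panel_df <- rand_var(take(config$panel_extra))
  dog_panel <- unique(c(
    unlist(lapply(donor_haps, function(d) .variant_key(d$position, d$ref, d$alt))),
    unlist(lapply(host_haps, function(d) .variant_key(d$position, d$ref, d$alt))),
    .variant_key(panel_df$position, panel_df$ref, panel_df$alt)))

  # --- tumours --------------------------------------------------------
  .substream(config$seed, "cohort")
  w_accept <- c(mis = config$w_mis, non = config$w_non)
  rows <- list()
  truth <- list()
  meta <- list()
  cov_rows <- list()
  tum_idx <- 0L

  emit <- function(row, label, consequence = NA_character_,
                   true_vaf = NA_real_) {
    if (is.null(row)) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- row
    truth[[length(truth) + 1L]] <<- data.frame(
      sample_id = row$sample_id,
      key = .variant_key(row$position, row$ref, row$alt),
      kind = row$kind, label = label, consequence = consequence,
      true_vaf = true_vaf, stringsAsFactors = FALSE)
    invisible(NULL)
  }

  for (cl in seq_len(config$n_clades)) {
    donor <- donor_haps[[cl]]
    age <- config$clade_ages_years[cl]
    for (k in seq_len(config$tumours_per_clade[cl])) {
      tum_idx <- tum_idx + 1L
      tum_id <- sprintf("%dT", tum_idx)
      host_id <- sprintf("%dH", tum_idx)
      host <- host_haps[[tum_idx]]
      contamination <- stats::runif(1L, config$contamination_range[1L],
                                    config$contamination_range[2L])
      f <- 1 - contamination

      # germline clade-defining variants, homoplasmic in tumour cells
      for (v in seq_len(nrow(donor))) {
        emit(.support_row(tum_id, donor$position[v], donor$ref[v],
                          donor$alt[v], "substitution", f,
                          config$mt_coverage),
             "germline_clade_defining", true_vaf = f)
      }

      # private somatic substitutions
      taken <- c(donor$position, host$position)
      n_som <- stats::rpois(1L, config$mu * age)
      for (s in seq_len(n_som)) {
        mut <- .draw_substitution(ref, chars, pos_map,
                                  config$spectrum_weights, w_accept, taken)
        if (is.null(mut)) break
        taken <- c(taken, mut$position)
        h <- if (stats::runif(1L) < config$het_prob) {
          stats::rbeta(1L, config$het_beta[1L], config$het_beta[2L])
        } else 1
        emit(.support_row(tum_id, mut$position, mut$ref, mut$alt,
                          "substitution", f * h, config$mt_coverage),
             "somatic", consequence = mut$consequence, true_vaf = f * h)
      }

      # somatic indels, thinned by frameshift selection
      n_ind <- stats::rpois(1L, config$indel_rate * age)
      for (s in seq_len(n_ind)) {
        p <- sample(setdiff(free_pos, taken), 1L)
        len <- sample(1:3, 1L)
        frameshift <- (len %% 3L) != 0L
        in_coding <- !is.null(.gene_at(ref, p))
        if (frameshift && in_coding &&
            stats::runif(1L) > config$w_frameshift) next
        taken <- c(taken, p)
        unit <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
        ins <- stats::runif(1L) < 0.5
        ref_a <- chars[p]
        alt_a <- if (ins) paste0(ref_a, unit) else ref_a
        if (!ins) ref_a <- paste0(ref_a, unit)
        h <- if (stats::runif(1L) < config$het_prob) {
          stats::rbeta(1L, config$het_beta[1L], config$het_beta[2L])
        } else 1
        emit(.support_row(tum_id, p, ref_a, alt_a,
                          if (ins) "insertion" else "deletion",
                          f * h, config$mt_coverage, indel = TRUE),
             "somatic_indel",
             consequence = if (!in_coding) "non_coding" else
               if (frameshift) "frameshift" else "inframe",
             true_vaf = f * h)
      }

      # host contamination leaks the host haplotype into tumour reads
      if (contamination > 0) {
        for (v in seq_len(nrow(host))) {
          emit(.support_row(tum_id, host$position[v], host$ref[v],
                            host$alt[v], "substitution", contamination,
                            config$mt_coverage),
               "contamination", true_vaf = contamination)
        }
      }

      # the matched host sample carries its own haplotype, homoplasmic
      for (v in seq_len(nrow(host))) {
        emit(.support_row(host_id, host$position[v], host$ref[v],
                          host$alt[v], "substitution", 1,
                          config$mt_coverage),
             "host_germline", true_vaf = 1)
      }

      meta[[tum_idx]] <- data.frame(
        tumour_id = tum_id, host_id = host_id, clade = as.character(cl),
        age_years = age, contamination = contamination, f_true = f,
        stringsAsFactors = FALSE)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        sample_id = tum_id, mt_cov = config$mt_coverage,
        nucl_cov = config$nucl_coverage, stringsAsFactors = FALSE)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        sample_id = host_id, mt_cov = config$mt_coverage,
        nucl_cov = config$nucl_coverage, stringsAsFactors = FALSE)
    }
  }

  variants <- variant_table(do.call(rbind, rows))
  truth_df <- do.call(rbind, truth)
  meta_df <- do.call(rbind, meta)
  clades <- stats::setNames(meta_df$clade, meta_df$tumour_id)

  structure(list(
    variants = variants,
    coverage = coverage_summary(do.call(rbind, cov_rows)),
    truth = list(
      variant_truth = truth_df,
      tumour_meta = meta_df,
      donor_haplotypes = lapply(donor_haps, function(d) {
        sort(.variant_key(d$position, d$ref, d$alt))
      }),
      host_haplotypes = lapply(host_haps, function(d) {
        sort(.variant_key(d$position, d$ref, d$alt))
      }),
      dog_panel = dog_panel,
      clades = clades),
    config = config), class = "SimulatedCohort")
}

#' Simulate observed dN/dS counts directly
#'
#' Draws `n_mutations` accepted coding substitutions from the
#' opportunity table (context rates uniform, i.e. a flat mutational
#' landscape) with consequence-specific acceptance `w`, and tallies the
#' observed count matrix. Used for parameter-recovery and calibration
#' experiments without a full cohort.
#'
#' @param L Opportunity matrix from [count_opportunities()].
#' @param n_mutations Number of accepted mutations.
#' @param w_mis,w_non Acceptance probabilities.
#' @return Observed count matrix conformable with `L`.
#' @export
simulate_dnds_counts <- function(L, n_mutations, w_mis = 1, w_non = 1) {
  w <- c(synonymous = 1, missense = w_mis, nonsense = w_non)
  probs <- sweep(L, 2L, w, `*`)
  p <- as.vector(probs)
  idx <- sample.int(length(p), n_mutations, replace = TRUE, prob = p)
  n <- matrix(0L, nrow = nrow(L), ncol = ncol(L), dimnames = dimnames(L))
  tab <- table(idx)
  n[as.integer(names(tab))] <- as.integer(tab)
  n
}
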