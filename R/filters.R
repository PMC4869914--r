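# Post-processing filters for substitution and indel calls.
#
# Filter defaults follow the published pipeline for low-coverage WGS of
# tumour/host pairs: base-quality and mapping-quality support rules, a
# read-end artefact rule, proximity to surviving indel calls, the
# simple-repeat region, a strand-balance rule, a table of recurrently
# miscalled site changes, and a rescue list that can re-admit calls
# discarded only by the indel-proximity rule.

#' Filter thresholds
#'
#' All constants of the substitution/indel filters, each defaulting to
#' the published value, overridable per run.
#'
#' @param bq_threshold Base quality defining a "high-quality" mutant read.
#' @param bq_fraction Minimum fraction of mutant reads that must exceed
#'   `bq_threshold` (at least one third).
#' @param min_mean_mq Minimum mean mapping quality of supporting reads.
#' @param read_end_bp Width of the read-end artefact window (documentation
#'   only; the caller provides the flag).
#' @param indel_proximity_bp Base window around a surviving indel within
#'   which substitutions are discarded; extended by REP when REP > 0.
#' @param min_strand_reads_either,min_strand_reads_both Indel support
#'   rule: kept if >= `min_strand_reads_either` supporting reads on one
#'   strand, or >= `min_strand_reads_both` on both.
#' @param pindel_check_threshold Pindel read count above which BWA-read
#'   corroboration is required.
#' @return Named list of thresholds.
#' @export
filter_config <- function(bq_threshold = 25, bq_fraction = 1 / 3,
                          min_mean_mq = 21, read_end_bp = 15,
                          indel_proximity_bp = 10,
                          min_strand_reads_either = 3,
                          min_strand_reads_both = 2,
                          pindel_check_threshold = 4) {
  list(bq_threshold = bq_threshold, bq_fraction = bq_fraction,
       min_mean_mq = min_mean_mq, read_end_bp = read_end_bp,
       indel_proximity_bp = indel_proximity_bp,
       min_strand_reads_either = min_strand_reads_either,
       min_strand_reads_both = min_strand_reads_both,
       pindel_check_threshold = pindel_check_threshold)
}

#' @noRd
.in_excluded_region <- function(ref, positions) {
  out <- rep(FALSE, length(positions))
  regs <- ref$excluded_regions
  if (nrow(regs)) {
    for (i in seq_len(nrow(regs))) {
      out <- out | (positions >= regs$start[i] & positions <= regs$end[i])
    }
  }
  out
}

#' Filter substitution calls
#'
#' Applies, in a fixed order: (1) at least one third of mutant reads
#' with base quality >25; (2) mean mapping quality >= 21; (3) discard if
#' supported only by the first/last 15 bp of reads; (4) discard within
#' 10 bp (+REP when REP > 0) of an indel that itself passed
#' [filter_indels()] in the same sample; (5) discard inside excluded
#' repeat regions; (6) if the reference allele has at least one read on
#' both strands, the mutant allele must too; (7) discard configured
#' excluded (position, change) pairs; (8) re-admit rescue-list variants
#' whose only discard reason was rule 4.
#'
#' @param calls Substitution [variant_table()].
#' @param ref An [mt_reference()].
#' @param indel_calls Indel [variant_table()] for the same samples, or
#'   `NULL` when no indels were called.
#' @param rescue_list Data frame with columns `position`, `ref`, `alt`
#'   of variants re-admitted when discarded only by indel proximity.
#' @param config A [filter_config()].
#' @return Data frame of verdicts: the call columns plus `kept` and
#'   `reasons` (semicolon-joined names of the rules that fired).
#' @export
filter_substitutions <- function(calls, ref, indel_calls = NULL,
                                 rescue_list = NULL,
                                 config = filter_config()) {
  calls <- as.data.frame(calls)
  if (any(calls$kind != "substitution")) {
    .stopf("filter_substitutions received non-substitution calls")
  }
  n <- nrow(calls)
  reasons <- vector("list", n)
  add_reason <- function(idx, reason) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], reason)
    reasons
  }

  # (1) base-quality rule: count of BQ>25 mutant reads >= n/3 (rational
  # comparison; ties at exactly one third are kept)
  bq_fail <- !is.na(calls$bq25_count) &
    calls$bq25_count < calls$mutant_reads * config$bq_fraction
  reasons <- add_reason(bq_fail, "base_quality")

  # (2) mean mapping quality
  mq_fail <- !is.na(calls$mean_mq) & calls$mean_mq < config$min_mean_mq
  reasons <- add_reason(mq_fail, "mapping_quality")

  # (3) read-end artefacts
  reasons <- add_reason(calls$read_end_only %in% TRUE, "read_end")

  # (4) proximity to a surviving indel in the same sample
  prox_fail <- rep(FALSE, n)
  if (!is.null(indel_calls) && nrow(indel_calls)) {
    kept_indels <- filter_indels(indel_calls, ref, config = config)
    kept_indels <- kept_indels[kept_indels$kept, , drop = FALSE]
    if (nrow(kept_indels)) {
      window <- config$indel_proximity_bp +
        ifelse(kept_indels$rep_count > 0, kept_indels$rep_count, 0)
      for (i in seq_len(n)) {
        same <- kept_indels$sample_id == calls$sample_id[i]
        if (any(same & abs(kept_indels$position - calls$position[i]) <=
                  window)) {
          prox_fail[i] <- TRUE
        }
      }
    }
  }
  reasons <- add_reason(prox_fail, "indel_proximity")

  # (5) repeat-region exclusion
  reasons <- add_reason(.in_excluded_region(ref, calls$position),
                        "repeat_region")

  # (6) strand balance, conditional on reference-strand representation
  have <- !is.na(calls$fwd_ref) & !is.na(calls$rev_ref) &
    !is.na(calls$fwd_mut) & !is.na(calls$rev_mut)
  strand_fail <- have & calls$fwd_ref >= 1 & calls$rev_ref >= 1 &
    (calls$fwd_mut < 1 | calls$rev_mut < 1)
  reasons <- add_reason(strand_fail, "strand_balance")

  # (7) excluded (position, change) pairs
  if (nrow(ref$excluded_sites)) {
    site_keys <- .variant_key(ref$excluded_sites$position,
                              ref$excluded_sites$ref,
                              ref$excluded_sites$alt)
    excl_fail <- .variant_key(calls$position, calls$ref, calls$alt) %in%
      site_keys
    reasons <- add_reason(excl_fail, "excluded_site")
  }

  # (8) rescue overrides rule 4 only
  kept <- lengths(reasons) == 0L
  if (!is.null(rescue_list) && nrow(rescue_list)) {
    rescue_keys <- .variant_key(rescue_list$position, rescue_list$ref,
                                rescue_list$alt)
    rescuable <- vapply(reasons, function(r) {
      length(r) > 0L && all(r == "indel_proximity")
    }, logical(1L))
    rescued <- rescuable &
      .variant_key(calls$position, calls$ref, calls$alt) %in% rescue_keys
    kept[rescued] <- TRUE
    for (i in which(rescued)) reasons[[i]] <- c(reasons[[i]], "rescued")
  }

  out <- calls
  out$kept <- kept
  out$reasons <- vapply(reasons, function(r) paste(r, collapse = ";"),
                        character(1L))
  out
}

#' Filter indel calls
#'
#' Applies the indel support rules: at least 3 supporting reads on one
#' strand or at least 2 on both; calls with >= 4 pindel-mapped reads need
#' at least 1 BWA-mapped read, or (when REP = 0) at least one pindel
#' read on each strand; repeat-region exclusion; and wholesale exclusion
#' of configured very-high-coverage samples.
#'
#' @param indel_calls Indel [variant_table()].
#' @param ref An [mt_reference()].
#' @param excluded_samples Character vector of sample ids excluded
#'   wholesale (e.g. mtDNA coverage > 300X).
#' @param config A [filter_config()].
#' @return Verdict data frame as in [filter_substitutions()].
#' @export
filter_indels <- function(indel_calls, ref, excluded_samples = character(),
                          config = filter_config()) {
  calls <- as.data.frame(indel_calls)
  if (any(!calls$kind %in% c("insertion", "deletion"))) {
    .stopf("filter_indels received non-indel calls")
  }
  if (nrow(calls) &&
      (anyNA(calls$fwd_mut) || anyNA(calls$rev_mut))) {
    .stopf("indel filtering requires per-strand support counts")
  }
  n <- nrow(calls)
  reasons <- vector("list", n)
  add_reason <- function(idx, reason) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], reason)
    reasons
  }

  either_ok <- calls$fwd_mut >= config$min_strand_reads_either |
    calls$rev_mut >= config$min_strand_reads_either
  both_ok <- calls$fwd_mut >= config$min_strand_reads_both &
    calls$rev_mut >= config$min_strand_reads_both
  reasons <- add_reason(!(either_ok | both_ok), "strand_support")

  pr <- calls$pindel_reads
  needs_check <- !is.na(pr) & pr >= config$pindel_check_threshold
  bwa_ok <- !is.na(calls$bwa_reads) & calls$bwa_reads >= 1
  rep0_ok <- calls$rep_count == 0 & calls$fwd_mut >= 1 & calls$rev_mut >= 1
  reasons <- add_reason(needs_check & !(bwa_ok | rep0_ok), "caller_support")

  reasons <- add_reason(.in_excluded_region(ref, calls$position),
                        "repeat_region")
  reasons <- add_reason(calls$sample_id %in% excluded_samples,
                        "high_coverage_sample")

  out <- calls
  out$kept <- lengths(reasons) == 0L
  out$reasons <- vapply(reasons, function(r) paste(r, collapse = ";"),
                        character(1L))
  out
}

#' Flag recurrent mutations and back mutations
#'
#' A somatic variant observed in tumours belonging to more than one
#' clade (and absent from every donor haplotype) is flagged recurrent.
#' A clade-defining variant absent from one tumour of its clade is
#' flagged as a back mutation in that tumour.
#'
#' @param tumour_keys Named list: per tumour, character vector of all
#'   kept variant keys (`"pos ref>alt"`, see [variant_key()]), germline
#'   and somatic alike.
#' @param clades Named character vector mapping tumour id to clade id.
#' @param donor_haplotypes Named list: per clade, character vector of
#'   clade-defining variant keys.
#' @return List with `recurrent` (character vector of variant keys) and
#'   `back_mutations` (data frame `tumour_id`, `clade`, `variant`).
#' @export
flag_recurrence <- function(tumour_keys, clades, donor_haplotypes) {
  stopifnot(all(names(tumour_keys) %in% names(clades)))
  donor_all <- unique(unlist(donor_haplotypes))

  carrier_clades <- list()
  for (tum in names(tumour_keys)) {
    for (key in setdiff(tumour_keys[[tum]], donor_all)) {
      carrier_clades[[key]] <- union(carrier_clades[[key]],
                                     clades[[tum]])
    }
  }
  recurrent <- names(carrier_clades)[lengths(carrier_clades) > 1L]

  back <- list()
  for (tum in names(tumour_keys)) {
    clade <- clades[[tum]]
    defining <- donor_haplotypes[[clade]]
    missing <- setdiff(defining, tumour_keys[[tum]])
    for (key in missing) {
      back[[length(back) + 1L]] <- data.frame(
        tumour_id = tum, clade = clade, variant = key,
        stringsAsFactors = FALSE)
    }
  }
  back_df <- if (length(back)) do.call(rbind, back) else
    data.frame(tumour_id = character(), clade = character(),
               variant = character(), stringsAsFactors = FALSE)
  list(recurrent = sort(recurrent), back_mutations = back_df)
}

#' Canonical variant key
#'
#' @param position,ref,alt Vectors describing variants.
#' @return Character vector `"pos ref>alt"`.
#' @export
variant_key <- function(position, ref, alt) {
  .variant_key(position, ref, alt)
}
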