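# Germline/somatic classification under host contamination, tumour
# mtDNA fraction estimation, VAF normalisation, and the four tumour
# substitution classes used downstream.

#' Classify tumour substitutions against a matched host
#'
#' Variants called in both tumour and matched host with tumour VAF < 0.9
#' are discarded as host contamination; shared variants with VAF > 0.9
#' in both are retained as likely germline; tumour-only variants are
#' somatic. For low-coverage hosts (< 20X) two stricter rules apply:
#' any host read supporting the variant discards it, and all tumour
#' variants with VAF < 0.5 are discarded. Shared variants with high
#' tumour VAF that are known from other tumours are treated as somatic
#' (the host call reflects low-level tumour-in-host contamination).
#'
#' @param tumour_calls Substitution [variant_table()] for one tumour
#'   (post [filter_substitutions()]).
#' @param host_calls Substitution [variant_table()] for the matched
#'   host; for low-coverage hosts it should include sub-threshold
#'   evidence rows (any `mutant_reads >= 1`).
#' @param host_coverage One row of a [coverage_summary()] for the host,
#'   or `NULL` (host assumed adequately covered).
#' @param known_tumour_variants Character vector of variant keys
#'   identified in other tumours, used to recognise tumour-in-host
#'   contamination.
#' @param vaf_germline Shared-variant VAF threshold (default 0.9).
#' @param vaf_lowcov_cutoff Tumour VAF cutoff applied when the host is
#'   low coverage (default 0.5).
#' @return `tumour_calls` with a `label` column:
#'   `"germline"`, `"somatic"` or `"discarded"`.
#' @export
classify_with_host <- function(tumour_calls, host_calls,
                               host_coverage = NULL,
                               known_tumour_variants = character(),
                               vaf_germline = 0.9,
                               vaf_lowcov_cutoff = 0.5) {
  tc <- as.data.frame(tumour_calls)
  hc <- as.data.frame(host_calls)
  if (!is.null(host_coverage)) {
    low_cov <- isTRUE(host_coverage$low_coverage[1L])
  } else {
    low_cov <- FALSE
  }

  t_keys <- .variant_key(tc$position, tc$ref, tc$alt)
  h_keys <- .variant_key(hc$position, hc$ref, hc$alt)
  shared <- t_keys %in% h_keys
  h_vaf <- hc$vaf[match(t_keys, h_keys)]
  h_reads <- hc$mutant_reads[match(t_keys, h_keys)]

  label <- rep("somatic", nrow(tc))
  # shared with matched host
  label[shared & tc$vaf < vaf_germline] <- "discarded"
  is_germ <- shared & tc$vaf >= vaf_germline
  label[is_germ] <- "germline"
  # tumour-in-host contamination: the host call is the artefact
  label[is_germ & !is.na(h_vaf) & h_vaf < vaf_germline &
          t_keys %in% known_tumour_variants] <- "somatic"

  if (low_cov) {
    # any host read supporting the variant discards it
    label[shared & !is.na(h_reads) & h_reads >= 1 &
            label != "germline"] <- "discarded"
    label[tc$vaf < vaf_lowcov_cutoff] <- "discarded"
  }
  tc$label <- label
  tc
}

#' Classify tumour substitutions without a matched host
#'
#' Variants below a per-tumour VAF cutoff are discarded as probable
#' host contamination. When contamination is too high for a VAF cutoff
#' to separate tumour from host (greater than about 40%), variants
#' present in phylogenetically related tumours are kept, variants found
#' in the normal-dog germline panel are discarded, and the remainder
#' are retained labelled `"putative_somatic"`.
#'
#' @param tumour_calls Substitution [variant_table()] for one tumour.
#' @param cutoff Per-tumour VAF cutoff in `[0, 1]` (usually 0.5 or 0.6).
#' @param high_contamination Logical; the >40% contamination regime.
#' @param related_tumour_keys Character vector of variant keys seen in
#'   phylogenetically related tumours.
#' @param dog_panel Character vector of germline-panel variant keys.
#' @return `tumour_calls` with a `label` column: `"somatic"`,
#'   `"putative_somatic"` or `"discarded"`.
#' @export
classify_without_host <- function(tumour_calls, cutoff = 0.5,
                                  high_contamination = FALSE,
                                  related_tumour_keys = character(),
                                  dog_panel = character()) {
  if (cutoff < 0 || cutoff > 1) .stopf("VAF cutoff %.3f outside [0, 1]", cutoff)
  tc <- as.data.frame(tumour_calls)
  keys <- .variant_key(tc$position, tc$ref, tc$alt)
  if (!high_contamination) {
    tc$label <- ifelse(tc$vaf < cutoff, "discarded", "somatic")
  } else {
    label <- rep("putative_somatic", nrow(tc))
    label[keys %in% related_tumour_keys] <- "somatic"
    label[!(keys %in% related_tumour_keys) & keys %in% dog_panel] <-
      "discarded"
    tc$label <- label
  }
  tc
}

#' Estimate the tumour mtDNA fraction of a tumour sample
#'
#' The mean raw VAF of substitutions present in the tumour but not in
#' its matched host estimates the proportion of mtDNA in the sample
#' that is tumour-derived (1 - host contamination).
#'
#' @param tumour_calls Substitution [variant_table()] for the tumour.
#' @param host_calls Substitution [variant_table()] for the matched host.
#' @return List with `f` (fraction in (0, 1]), `n_variants` used, and
#'   `defined` (FALSE with `f = NA` when no tumour-unique variant
#'   exists).
#' @export
estimate_tumour_fraction <- function(tumour_calls, host_calls) {
  tc <- as.data.frame(tumour_calls)
  tc <- tc[tc$kind == "substitution", , drop = FALSE]
  hc <- as.data.frame(host_calls)
  t_keys <- .variant_key(tc$position, tc$ref, tc$alt)
  h_keys <- .variant_key(hc$position, hc$ref, hc$alt)
  unique_idx <- !(t_keys %in% h_keys)
  if (!any(unique_idx)) {
    return(list(f = NA_real_, n_variants = 0L, defined = FALSE))
  }
  f <- mean(tc$vaf[unique_idx])
  f <- min(max(f, .Machine$double.eps), 1)
  list(f = f, n_variants = sum(unique_idx), defined = TRUE)
}

#' Normalise VAF for host contamination
#'
#' Divides the raw VAF by the tumour mtDNA fraction and caps at 1.
#' Normalised values below 1 flag heteroplasmy candidates.
#'
#' @param raw_vaf Numeric vector of raw VAFs.
#' @param f Tumour mtDNA fraction in (0, 1].
#' @return Numeric vector of normalised VAFs in `[0, 1]`.
#' @export
normalize_vaf <- function(raw_vaf, f) {
  if (length(f) != 1L || is.na(f) || f <= 0 || f > 1) {
    .stopf("tumour fraction must be a scalar in (0, 1]")
  }
  pmin(raw_vaf / f, 1)
}

#' Build the four tumour substitution classes
#'
#' Partition labelled tumour variants, per clade, into:
#' \describe{
#'   \item{clade_defining}{shared by every tumour of the clade and
#'     present in the normal-dog germline panel: the donor haplotype.}
#'   \item{potential_somatic}{shared by every tumour of the clade but
#'     absent from the panel; germline or early-somatic status unknown.}
#'   \item{somatic}{variable within the clade, i.e. arising after
#'     mtDNA capture.}
#'   \item{conservative_somatic}{the somatic list minus classes that
#'     could conceivably be germline: recombination-implicated
#'     variants, everything in configured low-confidence clades,
#'     variants defining configured ancestral-trunk haplogroups, and
#'     putative somatic calls from tumours without matched hosts.}
#' }
#'
#' @param labelled_calls Data frame of calls from [classify_with_host()]
#'   / [classify_without_host()] (rows labelled `"discarded"` are
#'   ignored), covering all tumours.
#' @param clade_assignments Named character vector tumour id -> clade.
#' @param dog_panel Character vector of germline-panel variant keys.
#' @param conservative_exclusions List with optional elements
#'   `recombination_keys` (variant keys), `excluded_clades` (clade ids,
#'   e.g. a clade whose tumours carry too few somatic mutations to rule
#'   out multiple captures), `trunk_tumour_sets` (list of tumour-id
#'   vectors; a somatic variant carried by all tumours of a set and no
#'   others is trunk-defining), and putative somatic keys are excluded
#'   automatically via their label.
#' @return Object of class `ClassifiedVariantSet`: per clade, the four
#'   key vectors, plus a per-variant table with raw and normalised VAF.
#' @export
build_variant_classes <- function(labelled_calls, clade_assignments,
                                  dog_panel = character(),
                                  conservative_exclusions = list()) {
  lc <- as.data.frame(labelled_calls)
  lc <- lc[lc$label != "discarded", , drop = FALSE]
  if (!all(lc$sample_id %in% names(clade_assignments))) {
    missing <- setdiff(unique(lc$sample_id), names(clade_assignments))
    .stopf("tumour(s) without clade assignment: %s",
           paste(utils::head(missing, 3L), collapse = ", "))
  }
  lc$key <- .variant_key(lc$position, lc$ref, lc$alt)
  lc$clade <- unname(clade_assignments[lc$sample_id])

  recomb <- conservative_exclusions$recombination_keys %||% character()
  excl_clades <- conservative_exclusions$excluded_clades %||% character()
  trunks <- conservative_exclusions$trunk_tumour_sets %||% list()
  putative_keys <- unique(lc$key[lc$label == "putative_somatic"])

  clades <- sort(unique(unname(clade_assignments)))
  per_clade <- list()
  for (cl in clades) {
    tumours <- names(clade_assignments)[clade_assignments == cl]
    sub <- lc[lc$clade == cl, , drop = FALSE]
    keys_by_tumour <- split(sub$key, factor(sub$sample_id, levels = tumours))
    shared <- Reduce(intersect, keys_by_tumour)
    all_keys <- unique(sub$key)

    clade_defining <- intersect(shared, dog_panel)
    potential_somatic <- setdiff(shared, dog_panel)
    somatic <- setdiff(all_keys, shared)

    conservative <- setdiff(somatic,
                            c(recomb, putative_keys))
    if (cl %in% excl_clades) conservative <- character()
    for (trunk in trunks) {
      trunk <- intersect(trunk, tumours)
      if (!length(trunk)) next
      carriers <- lapply(somatic, function(k) {
        names(keys_by_tumour)[vapply(keys_by_tumour, function(v) k %in% v,
                                     logical(1L))]
      })
      trunk_keys <- somatic[vapply(carriers, function(ca) {
        setequal(ca, trunk)
      }, logical(1L))]
      conservative <- setdiff(conservative, trunk_keys)
    }

    per_clade[[as.character(cl)]] <- list(
      clade_defining = sort(clade_defining),
      potential_somatic = sort(potential_somatic),
      somatic = sort(somatic),
      conservative_somatic = sort(conservative))
  }

  out <- structure(list(clades = per_clade, calls = lc),
                   class = "ClassifiedVariantSet")
  .assert_class_invariants(out)
  out
}

# class disjointness and subset relations, asserted on every build
#' @noRd
.assert_class_invariants <- function(x) {
  for (cl in names(x$clades)) {
    s <- x$clades[[cl]]
    stopifnot(
      length(intersect(s$clade_defining, s$potential_somatic)) == 0L,
      length(intersect(s$clade_defining, s$somatic)) == 0L,
      length(intersect(s$potential_somatic, s$somatic)) == 0L,
      all(s$conservative_somatic %in% s$somatic)
    )
  }
  invisible(TRUE)
}

#' @export
print.ClassifiedVariantSet <- function(x, ...) {
  cat("ClassifiedVariantSet:\n")
  for (cl in names(x$clades)) {
    s <- x$clades[[cl]]
    cat(sprintf("  clade %s: %d clade-defining, %d potential-somatic, %d somatic (%d conservative)\n",
                cl, length(s$clade_defining), length(s$potential_somatic),
                length(s$somatic), length(s$conservative_somatic)))
  }
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
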