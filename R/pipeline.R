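# End-to-end orchestration: filter -> classify -> spectrum ->
# selection -> timing -> copy number -> haplotype naming, with a
# config whose every numeric default is the published constant, a
# per-stage log of counts in/out, and deterministic outputs.

#' Pipeline configuration
#'
#' @param filter A [filter_config()].
#' @param vaf_germline Shared tumour/host VAF above which a variant is
#'   germline (0.9).
#' @param low_cov_threshold Host mean coverage below which the stricter
#'   low-coverage rules apply (20X).
#' @param high_cov_threshold mtDNA coverage above which samples are
#'   excluded from copy-number and indel analysis (300X).
#' @param unmatched_vaf_cutoff Default VAF cutoff for tumours without a
#'   matched host (0.5; 0.6 for more contaminated tumours).
#' @param calibration_clade Clade used for the nuclear-DNA rate
#'   calibration.
#' @param calibration_age_years Age bound of the calibration clade (460).
#' @param generation_days_range Cell generation time bounds (4, 20).
#' @param per_year_rate Human-calibrated rate (0.025).
#' @param ploidy Ploidy for copy-number estimation (2).
#' @param presentation_rounding Reproduce printed (rounded) spectrum
#'   values rather than full precision.
#' @param burden_overrides Optional per-clade burden overrides (e.g.
#'   for a recombination-affected haplogroup).
#' @param conservative_exclusions Passed to [build_variant_classes()].
#' @return Named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            vaf_germline = 0.9,
                            low_cov_threshold = 20,
                            high_cov_threshold = 300,
                            unmatched_vaf_cutoff = 0.5,
                            calibration_clade = "2",
                            calibration_age_years = 460,
                            generation_days_range = c(4, 20),
                            per_year_rate = 0.025,
                            ploidy = 2,
                            presentation_rounding = FALSE,
                            burden_overrides = NULL,
                            conservative_exclusions = list()) {
  structure(list(filter = filter, vaf_germline = vaf_germline,
                 low_cov_threshold = low_cov_threshold,
                 high_cov_threshold = high_cov_threshold,
                 unmatched_vaf_cutoff = unmatched_vaf_cutoff,
                 calibration_clade = calibration_clade,
                 calibration_age_years = calibration_age_years,
                 generation_days_range = generation_days_range,
                 per_year_rate = per_year_rate, ploidy = ploidy,
                 presentation_rounding = presentation_rounding,
                 burden_overrides = burden_overrides,
                 conservative_exclusions = conservative_exclusions),
            class = "PipelineConfig")
}

#' Pipeline inputs from a simulated cohort
#'
#' @param cohort A `SimulatedCohort` from [simulate_cohort()].
#' @param ref The [mt_reference()] the cohort was simulated on; when
#'   `NULL`, re-derived from the cohort's config seed.
#' @return List of pipeline inputs: `ref`, `variants`, `coverage`,
#'   `clades`, `pairs` (tumour id -> host id), `dog_panel`.
#' @export
as_pipeline_inputs <- function(cohort, ref = NULL) {
  if (is.null(ref)) {
    ref <- simulate_reference(cohort$config$genome_length,
                              seed = cohort$config$seed)
  }
  meta <- cohort$truth$tumour_meta
  list(ref = ref, variants = cohort$variants, coverage = cohort$coverage,
       clades = cohort$truth$clades,
       pairs = stats::setNames(meta$host_id, meta$tumour_id),
       dog_panel = cohort$truth$dog_panel)
}

#' Run the full analysis pipeline
#'
#' Executes filtering, germline/somatic classification with tumour
#' fraction estimation and VAF normalisation, variant-class
#' construction, the normalised mutation spectrum, selection inference
#' (VAF KS tests and dN/dS), clade timing, copy-number estimation and
#' tumour haplotype naming. Stage invariants are asserted as the run
#' proceeds; any failure aborts with the stage name.
#'
#' @param inputs As produced by [as_pipeline_inputs()] (or assembled
#'   manually: `ref`, `variants`, `coverage`, `clades`, `pairs`,
#'   `dog_panel`, optional `rescue_list`, `host_definitions`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-stage TSV/JSON
#'   reports, a config echo and a run log are written there.
#' @return List of class `PipelineReport` with per-stage results.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = NULL) {
  required <- c("ref", "variants", "coverage", "clades", "pairs",
                "dog_panel")
  missing <- setdiff(required, names(inputs))
  if (length(missing)) {
    .stopf("pipeline inputs lack: %s", paste(missing, collapse = ", "))
  }
  log_lines <- character()
  log_add <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ref <- inputs$ref
  all_calls <- as.data.frame(inputs$variants)
  subs <- all_calls[all_calls$kind == "substitution", , drop = FALSE]
  indels <- all_calls[all_calls$kind != "substitution", , drop = FALSE]

  # ---- stage: filter -------------------------------------------------
  excluded_samples <- inputs$coverage$sample_id[inputs$coverage$high_coverage]
  verdict_sub <- stage("filter_substitutions", filter_substitutions(
    subs, ref, indel_calls = if (nrow(indels)) indels else NULL,
    rescue_list = inputs$rescue_list, config = config$filter))
  verdict_ind <- stage("filter_indels", if (nrow(indels)) {
    filter_indels(indels, ref, excluded_samples = excluded_samples,
                  config = config$filter)
  } else NULL)
  kept_sub <- verdict_sub[verdict_sub$kept, , drop = FALSE]
  kept_ind <- if (!is.null(verdict_ind)) {
    verdict_ind[verdict_ind$kept, , drop = FALSE]
  } else NULL
  log_add("filter: substitutions %d -> %d kept", nrow(subs), nrow(kept_sub))
  for (reason in unique(unlist(strsplit(
    verdict_sub$reasons[!verdict_sub$kept], ";", fixed = TRUE)))) {
    log_add("filter:   reason %-18s %d", reason,
            sum(grepl(reason, verdict_sub$reasons[!verdict_sub$kept],
                      fixed = TRUE)))
  }
  if (!is.null(verdict_ind)) {
    log_add("filter: indels %d -> %d kept", nrow(indels),
            sum(verdict_ind$kept))
  }

  # ---- stage: classify -----------------------------------------------
  tumours <- names(inputs$pairs)
  known_tumour_variants <- character()
  labelled <- list()
  fractions <- list()
  cov <- as.data.frame(inputs$coverage)
  for (tum in tumours) {
    host <- inputs$pairs[[tum]]
    t_calls <- kept_sub[kept_sub$sample_id == tum, , drop = FALSE]
    if (!is.na(host) && host %in% kept_sub$sample_id) {
      h_calls <- kept_sub[kept_sub$sample_id == host, , drop = FALSE]
      h_cov <- cov[cov$sample_id == host, , drop = FALSE]
      if (!nrow(h_cov)) .stopf("missing coverage summary for host %s", host)
      lab <- stage("classify", classify_with_host(
        t_calls, h_calls, host_coverage = h_cov,
        known_tumour_variants = known_tumour_variants,
        vaf_germline = config$vaf_germline))
      fr <- estimate_tumour_fraction(t_calls, h_calls)
    } else {
      lab <- stage("classify", classify_without_host(
        t_calls, cutoff = config$unmatched_vaf_cutoff,
        dog_panel = inputs$dog_panel))
      fr <- list(f = NA_real_, n_variants = 0L, defined = FALSE)
    }
    f_use <- if (fr$defined) fr$f else 1
    lab$norm_vaf <- normalize_vaf(lab$vaf, f_use)
    labelled[[tum]] <- lab
    fractions[[tum]] <- data.frame(tumour_id = tum, f = fr$f,
                                   n_variants = fr$n_variants,
                                   defined = fr$defined,
                                   stringsAsFactors = FALSE)
  }
  labelled_df <- do.call(rbind, labelled)
  fractions_df <- do.call(rbind, fractions)
  rownames(fractions_df) <- NULL
  log_add("classify: %d tumours, %d calls labelled", length(tumours),
          nrow(labelled_df))

  # ---- stage: classes ------------------------------------------------
  classified <- stage("classes", build_variant_classes(
    labelled_df, inputs$clades, dog_panel = inputs$dog_panel,
    conservative_exclusions = config$conservative_exclusions))

  conservative_keys <- unique(unlist(lapply(classified$clades,
                                            `[[`, "conservative_somatic")))
  cons_calls <- classified$calls[classified$calls$key %in%
                                   conservative_keys, , drop = FALSE]
  cons_unique <- cons_calls[!duplicated(cons_calls$key), , drop = FALSE]
  log_add("classes: %d conservative somatic substitutions",
          nrow(cons_unique))

  # ---- stage: spectrum -----------------------------------------------
  spectrum <- stage("spectrum", compute_spectrum(
    ref, cons_unique[, c("position", "ref", "alt")],
    presentation = config$presentation_rounding))

  # ---- stage: selection ----------------------------------------------
  consequences <- vapply(seq_len(nrow(cons_unique)), function(i) {
    annotate_consequence(ref, cons_unique$position[i],
                         cons_unique$ref[i], cons_unique$alt[i])
  }, character(1L))
  cons_unique$consequence <- consequences
  # per-variant normalised VAF: mean across carrying tumours
  nv <- tapply(cons_calls$norm_vaf, cons_calls$key, mean)
  cons_unique$norm_vaf <- unname(nv[cons_unique$key])

  indel_df <- NULL
  if (!is.null(kept_ind) && nrow(kept_ind)) {
    ind <- kept_ind
    ind$frameshift <- (abs(nchar(ind$ref) - nchar(ind$alt)) %% 3L) != 0L
    f_map <- stats::setNames(fractions_df$f, fractions_df$tumour_id)
    f_ind <- f_map[ind$sample_id]
    f_ind[is.na(f_ind)] <- 1
    ind$norm_vaf <- pmin(ind$vaf / f_ind, 1)
    indel_df <- ind
  }
  ks <- stage("selection", truncating_vs_other_comparisons(
    cons_unique, indels = indel_df))
  dnds <- stage("selection", {
    L <- count_opportunities(ref)
    n_obs <- count_observed(ref, cons_unique)
    if (sum(n_obs) > 0) dnds_fit(n_obs, L) else NULL
  })

  # ---- stage: timing -------------------------------------------------
  burdens <- stage("timing", clade_burden(
    classified, burden_overrides = config$burden_overrides))
  timing <- stage("timing", if (config$calibration_clade %in%
                                  burdens$clade &&
                                burdens$mean_burden[burdens$clade ==
                                  config$calibration_clade] > 0) {
    timing_report(burdens, config$calibration_clade,
                  config$calibration_age_years,
                  config$generation_days_range)
  } else NULL)

  # ---- stage: copy number -------------------------------------------
  copynum <- stage("copy_number", estimate_copy_number(inputs$coverage))

  # ---- stage: haplotypes --------------------------------------------
  tum_sets <- lapply(tumours, function(tum) {
    lab <- labelled[[tum]]
    keep <- lab$label != "discarded"
    .variant_key(lab$position[keep], lab$ref[keep], lab$alt[keep])
  })
  names(tum_sets) <- tumours
  hierarchy <- stage("haplotypes", haplogroup_definitions(
    lapply(names(classified$clades), function(cl) {
      list(name = cl,
           variants = classified$clades[[cl]]$clade_defining)
    })))
  haplotypes <- stage("haplotypes", assign_tumour_haplotype(
    tum_sets, inputs$clades, hierarchy))
  log_add("haplotypes: %d tumours named", nrow(haplotypes))

  report <- structure(list(
    filter = list(substitutions = verdict_sub, indels = verdict_ind),
    fractions = fractions_df,
    classified = classified,
    spectrum = spectrum,
    selection = list(ks = ks, dnds = dnds),
    burdens = burdens,
    timing = timing,
    copy_number = copynum,
    haplotypes = haplotypes,
    log = log_lines,
    config = config), class = "PipelineReport")

  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

#' @noRd
.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$filter$substitutions, "filter_substitutions.tsv")
  if (!is.null(report$filter$indels)) wt(report$filter$indels,
                                         "filter_indels.tsv")
  wt(report$fractions, "tumour_fractions.tsv")
  wt(report$spectrum, "spectrum.tsv")
  wt(report$burdens, "clade_burdens.tsv")
  if (!is.null(report$timing)) wt(report$timing, "clade_timing.tsv")
  wt(report$copy_number, "copy_number.tsv")
  wt(report$haplotypes, "haplotypes.tsv")
  classes <- lapply(report$classified$clades, function(s) {
    lapply(s, as.list)
  })
  jsonlite::write_json(classes, file.path(out_dir, "variant_classes.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  if (!is.null(report$selection$dnds)) {
    d <- report$selection$dnds
    jsonlite::write_json(
      list(w_mis = d$w_mis, w_non = d$w_non,
           lrt_p_mis = d$lrt$missense$p_value,
           lrt_p_non = d$lrt$nonsense$p_value,
           ci = d$ci),
      file.path(out_dir, "dnds.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  cfg <- report$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a simulated cohort as a fixture bundle
#'
#' @param cohort A `SimulatedCohort`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_variant_table(cohort$variants, file.path(out_dir, "variants.tsv"))
  write_coverage_summary(cohort$coverage, file.path(out_dir, "coverage.tsv"))
  utils::write.table(cohort$truth$variant_truth,
                     file.path(out_dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$tumour_meta,
                     file.path(out_dir, "truth_tumours.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a fixture bundle) and `run-all`
#' (simulate under the seed, run the pipeline, write reports).
#' Arguments: `--seed <int>`, `--out <dir>`, `--presentation-rounding`.
#'
#' @param args Character vector of arguments (default: the command
#'   line).
#' @return Exit status, invisibly (0 on success).
#' @export
mtclade_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: mtclade <simulate|run-all> --seed <int> --out <dir> [--presentation-rounding]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- function(name, default = NULL) {
    i <- which(args == name)
    if (!length(i)) return(default)
    args[i[1L] + 1L]
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "mtclade_out")
  pres <- "--presentation-rounding" %in% args

  cohort <- simulate_cohort(sim_config(seed = seed))
  if (cmd == "simulate") {
    write_cohort(cohort, out)
  } else if (cmd == "run-all") {
    write_cohort(cohort, file.path(out, "fixture"))
    run_pipeline(as_pipeline_inputs(cohort),
                 pipeline_config(presentation_rounding = pres),
                 out_dir = file.path(out, "report"))
  } else {
    message(sprintf("unknown subcommand '%s'", cmd))
    return(invisible(1L))
  }
  invisible(0L)
}
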