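# Molecular-clock dating of mtDNA capture events from per-clade somatic
# burden, under three independent rate calibrations:
#   1. nuclear calibration: the youngest clade's burden divided by its
#      nuclear-DNA age bound (460 years) gives a maximum mutations/year;
#   2. cell divisions: one homoplasmic mtDNA mutation per ~1000 cell
#      generations, with generation times between 4 and 20 days;
#   3. a human-tumour per-year rate of ~0.025 mutations/year.
# All three are linear in burden, so clade age ordering is calibration
# invariant.

#' Per-clade somatic mutation burden
#'
#' @param classified A `ClassifiedVariantSet` from
#'   [build_variant_classes()].
#' @param burden_overrides Optional named numeric vector of per-clade
#'   mean-burden overrides (e.g. to adjust a clade whose burden is
#'   distorted by recombination).
#' @return Data frame per clade: `clade`, `n_tumours`, `mean_burden`
#'   (somatic only) and `mean_burden_with_potential` (adding the
#'   clade-level potential-somatic count to every tumour).
#' @export
clade_burden <- function(classified, burden_overrides = NULL) {
  calls <- classified$calls
  out <- list()
  for (cl in names(classified$clades)) {
    s <- classified$clades[[cl]]
    sub <- calls[calls$clade == cl, , drop = FALSE]
    tumours <- unique(sub$sample_id)
    per_tumour <- vapply(tumours, function(t) {
      sum(sub$key[sub$sample_id == t] %in% s$somatic)
    }, numeric(1L))
    mean_burden <- mean(per_tumour)
    if (!is.null(burden_overrides) && cl %in% names(burden_overrides)) {
      mean_burden <- unname(burden_overrides[[cl]])
    }
    out[[cl]] <- data.frame(
      clade = cl, n_tumours = length(tumours),
      mean_burden = mean_burden,
      mean_burden_with_potential = mean_burden + length(s$potential_somatic),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mutation rate from a nuclear-DNA age calibration
#'
#' @param reference_clade_burden Mean somatic burden of the calibration
#'   clade.
#' @param calibration_age_years Maximum age of that clade in years.
#' @return Mutations per year.
#' @export
rate_from_nuclear_calibration <- function(reference_clade_burden,
                                          calibration_age_years = 460) {
  if (reference_clade_burden <= 0) .stopf("calibration burden must be > 0")
  if (calibration_age_years <= 0) .stopf("calibration age must be > 0")
  reference_clade_burden / calibration_age_years
}

#' Time since mtDNA capture
#'
#' @param burden Mean somatic mutation burden of a clade.
#' @param rate Mutations per year.
#' @return Years (full precision; round at presentation).
#' @export
time_since_capture <- function(burden, rate) {
  if (rate <= 0) .stopf("rate must be > 0")
  if (any(burden < 0)) .stopf("burden must be >= 0")
  burden / rate
}

#' Mutation rate from cell-division kinetics
#'
#' One homoplasmic somatic mtDNA mutation arises every ~1000 cell
#' generations; generation times of 20 and 4 days then bound the yearly
#' rate below and above.
#'
#' @param generation_days Cell generation time in days.
#' @param mutations_per_1000_generations Homoplasmic mutations per 1000
#'   generations.
#' @param days_per_year Year length (365.25).
#' @return Mutations per year.
#' @export
rate_from_cell_divisions <- function(generation_days,
                                     mutations_per_1000_generations = 1,
                                     days_per_year = 365.25) {
  if (generation_days <= 0) .stopf("generation time must be > 0")
  (mutations_per_1000_generations / 1000) * (days_per_year / generation_days)
}

#' Human-tumour-calibrated mutation rate
#'
#' @param rate Mutations per year (default 0.025, from the correlation
#'   of somatic mtDNA burden with patient age in human cancers).
#' @return Mutations per year.
#' @export
rate_human_calibrated <- function(rate = 0.025) {
  rate
}

#' Timing report for all clades under all three calibrations
#'
#' @param burdens Output of [clade_burden()].
#' @param calibration_clade Clade id used for the nuclear calibration.
#' @param calibration_age_years Age bound for that clade.
#' @param generation_days_range Min and max generation days.
#' @return Data frame: clade x method x (with/without potential
#'   somatic), with `rate` and `years`.
#' @export
timing_report <- function(burdens, calibration_clade,
                          calibration_age_years = 460,
                          generation_days_range = c(4, 20)) {
  if (!calibration_clade %in% burdens$clade) {
    .stopf("calibration clade %s not in burden table", calibration_clade)
  }
  cal_burden <- burdens$mean_burden[burdens$clade == calibration_clade]
  rates <- c(
    nuclear_calibration = rate_from_nuclear_calibration(
      cal_burden, calibration_age_years),
    cell_divisions_min_rate = rate_from_cell_divisions(
      max(generation_days_range)),
    cell_divisions_max_rate = rate_from_cell_divisions(
      min(generation_days_range)),
    per_year_rate = rate_human_calibrated())

  rows <- list()
  for (i in seq_len(nrow(burdens))) {
    for (m in names(rates)) {
      for (with_pot in c(FALSE, TRUE)) {
        b <- if (with_pot) burdens$mean_burden_with_potential[i] else
          burdens$mean_burden[i]
        rows[[length(rows) + 1L]] <- data.frame(
          clade = burdens$clade[i], method = m,
          with_potential_somatic = with_pot,
          rate = unname(rates[[m]]),
          burden = b,
          years = if (b == 0) 0 else time_since_capture(b, rates[[m]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
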