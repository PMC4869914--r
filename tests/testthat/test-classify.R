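test_that("matched-host classification follows the shared-VAF rules", {
  tum <- variant_table(rbind(
    make_sub(position = 10L, mutant_reads = 66L, total_depth = 70L),  # shared hi
    make_sub(position = 20L, mutant_reads = 28L, total_depth = 70L),  # shared lo
    make_sub(position = 30L, mutant_reads = 60L, total_depth = 70L))) # unique
  host <- variant_table(rbind(
    make_sub(sample_id = "H1", position = 10L, mutant_reads = 66L,
             total_depth = 70L),
    make_sub(sample_id = "H1", position = 20L, mutant_reads = 69L,
             total_depth = 70L)))
  lab <- classify_with_host(tum, host)
  expect_equal(lab$label, c("germline", "discarded", "somatic"))
})

test_that("low-coverage hosts trigger the stricter rules", {
  tum <- variant_table(rbind(
    make_sub(position = 10L, mutant_reads = 60L, total_depth = 70L),  # host read
    make_sub(position = 20L, mutant_reads = 30L, total_depth = 70L),  # VAF<0.5
    make_sub(position = 30L, mutant_reads = 50L, total_depth = 70L)))
  host <- variant_table(
    make_sub(sample_id = "H1", position = 10L, mutant_reads = 1L,
             total_depth = 12L, fwd_mut = 1L, rev_mut = 0L))
  cov <- coverage_summary(data.frame(sample_id = "H1", mt_cov = 12,
                                     nucl_cov = 0.3))
  lab <- classify_with_host(tum, host, host_coverage = cov)
  expect_equal(lab$label, c("discarded", "discarded", "somatic"))
})

test_that("tumour-in-host contamination is recognised via known variants", {
  tum <- variant_table(make_sub(position = 10L, mutant_reads = 66L,
                                total_depth = 70L))
  host <- variant_table(make_sub(sample_id = "H1", position = 10L,
                                 mutant_reads = 5L, total_depth = 70L))
  # without the panel of known tumour variants: germline
  expect_equal(classify_with_host(tum, host)$label, "germline")
  # with it: the host call is contamination; the variant is somatic
  expect_equal(classify_with_host(tum, host,
                                  known_tumour_variants = "10 C>T")$label,
               "somatic")
})

test_that("hostless classification applies cutoffs and the related-tumour rule", {
  tum <- variant_table(rbind(
    make_sub(position = 10L, mutant_reads = 31L, total_depth = 70L),  # 0.443
    make_sub(position = 20L, mutant_reads = 49L, total_depth = 70L))) # 0.7
  lab <- classify_without_host(tum, cutoff = 0.5)
  expect_equal(lab$label, c("discarded", "somatic"))
  expect_error(classify_without_host(tum, cutoff = 1.4), "outside")

  # heavily contaminated: related tumours and the dog panel arbitrate
  lab2 <- classify_without_host(tum, high_contamination = TRUE,
                                related_tumour_keys = "20 C>T",
                                dog_panel = "10 C>T")
  expect_equal(lab2$label, c("discarded", "somatic"))
  lab3 <- classify_without_host(tum, high_contamination = TRUE)
  expect_equal(lab3$label, c("putative_somatic", "putative_somatic"))
})

test_that("tumour fraction estimation averages tumour-unique VAFs", {
  tum <- variant_table(rbind(
    make_sub(position = 10L, mutant_reads = 56L, total_depth = 70L),  # 0.8
    make_sub(position = 20L, mutant_reads = 63L, total_depth = 70L),  # 0.9
    make_sub(position = 30L, mutant_reads = 70L, total_depth = 70L),  # 1.0
    make_sub(position = 40L, mutant_reads = 35L, total_depth = 70L))) # shared
  host <- variant_table(make_sub(sample_id = "H1", position = 40L,
                                 mutant_reads = 70L, total_depth = 70L))
  est <- estimate_tumour_fraction(tum, host)
  expect_equal(est$f, 0.9)
  expect_equal(est$n_variants, 3L)

  single <- variant_table(make_sub(position = 10L, mutant_reads = 70L,
                                   total_depth = 70L))
  expect_equal(estimate_tumour_fraction(single, host)$f, 1)

  all_shared <- variant_table(make_sub(position = 40L, mutant_reads = 70L,
                                       total_depth = 70L))
  est0 <- estimate_tumour_fraction(all_shared, host)
  expect_false(est0$defined)
  expect_true(is.na(est0$f))
})

test_that("VAF normalisation divides by f, caps at 1 and is monotone", {
  expect_equal(normalize_vaf(0.45, 0.9), 0.5)
  expect_equal(normalize_vaf(0.95, 0.9), 1)
  raw <- seq(0, 1, by = 0.05)
  expect_equal(normalize_vaf(raw, 1), raw)
  for (f in c(0.5, 0.7, 0.99)) {
    nv <- normalize_vaf(raw, f)
    expect_true(all(diff(nv) >= 0))
    expect_true(all(nv >= 0 & nv <= 1))
  }
  expect_error(normalize_vaf(0.5, 0), "\\(0, 1\\]")
})

test_that("variant classes partition per clade with conservative exclusions", {
  # two clades, two tumours each; keys chosen to hit every class
  mk <- function(sample, pos) {
    make_sub(sample_id = sample, position = pos, mutant_reads = 63L,
             total_depth = 70L)
  }
  calls <- variant_table(rbind(
    mk("T1", 10L), mk("T1", 20L), mk("T1", 30L),
    mk("T2", 10L), mk("T2", 20L), mk("T2", 40L),
    mk("T3", 50L), mk("T3", 60L),
    mk("T4", 50L), mk("T4", 70L)))
  calls$label <- "somatic"
  clades <- c(T1 = "1", T2 = "1", T3 = "2", T4 = "2")
  panel <- c("10 C>T", "50 C>T")

  cs <- build_variant_classes(calls, clades, dog_panel = panel)
  expect_equal(cs$clades[["1"]]$clade_defining, "10 C>T")
  expect_equal(cs$clades[["1"]]$potential_somatic, "20 C>T")
  expect_setequal(cs$clades[["1"]]$somatic, c("30 C>T", "40 C>T"))
  expect_setequal(cs$clades[["2"]]$somatic, c("60 C>T", "70 C>T"))
  expect_equal(cs$clades[["1"]]$conservative_somatic,
               cs$clades[["1"]]$somatic)

  # clade-level exclusion and recombination keys shrink the conservative list
  cs2 <- build_variant_classes(calls, clades, dog_panel = panel,
                               conservative_exclusions = list(
                                 excluded_clades = "2",
                                 recombination_keys = "30 C>T"))
  expect_equal(cs2$clades[["2"]]$conservative_somatic, character())
  expect_equal(cs2$clades[["1"]]$conservative_somatic, "40 C>T")

  # ancestral-trunk variants (carried by exactly the trunk set) drop out
  cs3 <- build_variant_classes(calls, clades, dog_panel = panel,
                               conservative_exclusions = list(
                                 trunk_tumour_sets = list(c("T1"))))
  expect_false("30 C>T" %in% cs3$clades[["1"]]$conservative_somatic)
  expect_true("40 C>T" %in% cs3$clades[["1"]]$conservative_somatic)

  expect_error(build_variant_classes(calls, clades[-1], dog_panel = panel),
               "without clade")
})

test_that("somatic/germline recovery on simulated cohorts meets targets", {
  cohort <- simulate_cohort(sim_config(seed = 42))
  rep <- run_pipeline(as_pipeline_inputs(cohort))
  truth <- cohort$truth$variant_truth
  truth <- truth[truth$kind == "substitution" &
                   grepl("T$", truth$sample_id), ]

  calls <- rep$classified$calls
  calls <- calls[calls$kind == "substitution", ]
  pred_somatic <- unique(paste(calls$sample_id, calls$key)[
    vapply(seq_len(nrow(calls)), function(i) {
      calls$key[i] %in% rep$classified$clades[[calls$clade[i]]]$somatic
    }, logical(1))])
  true_somatic <- paste(truth$sample_id, truth$key)[truth$label == "somatic"]

  tp <- length(intersect(pred_somatic, true_somatic))
  precision <- tp / length(pred_somatic)
  recall <- tp / length(true_somatic)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)

  # tumour fraction recovery within +/- 0.05 at 70X
  fr <- merge(rep$fractions, cohort$truth$tumour_meta,
              by = "tumour_id")
  expect_true(all(abs(fr$f - fr$f_true) <= 0.05))
})
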