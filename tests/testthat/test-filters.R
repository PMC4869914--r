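# Substitution and indel filter rules, on a full-length synthetic
# reference so the shipped repeat-region coordinates apply as-is.

full_ref <- function() {
  mt_reference(rand_seq(16727, seed = 9),
               excluded_regions = default_excluded_regions(),
               excluded_sites = default_excluded_sites()[, c("position",
                                                             "ref", "alt")])
}

test_that("substitution rules fire with the documented reasons", {
  ref <- full_ref()
  calls <- variant_table(rbind(
    make_sub(position = 16200L),                       # repeat region
    make_sub(position = 100L, bq25_count = 2L,
             mutant_reads = 9L, total_depth = 70L,
             fwd_mut = 4L, rev_mut = 5L),              # 2 < 9/3
    make_sub(position = 200L, mean_mq = 15),           # low MQ
    make_sub(position = 300L, read_end_only = TRUE),   # read ends
    make_sub(position = 400L, fwd_mut = 35L, rev_mut = 0L),  # strand
    make_sub(position = 500L)))                        # clean
  v <- filter_substitutions(calls, ref)
  expect_equal(v$kept, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(v$reasons[1], "repeat_region")
  expect_equal(v$reasons[2], "base_quality")
  expect_equal(v$reasons[3], "mapping_quality")
  expect_equal(v$reasons[4], "read_end")
  expect_equal(v$reasons[5], "strand_balance")

  # exactly one third of mutant reads at BQ>25 is kept ("at least")
  tie <- variant_table(make_sub(position = 600L, bq25_count = 3L,
                                mutant_reads = 9L, total_depth = 70L,
                                fwd_mut = 4L, rev_mut = 5L))
  expect_true(filter_substitutions(tie, ref)$kept)

  # strand rule is conditional: no reverse reference reads -> no demand
  cond <- variant_table(make_sub(position = 700L, fwd_mut = 35L,
                                 rev_mut = 0L, fwd_ref = 35L, rev_ref = 0L))
  expect_true(filter_substitutions(cond, ref)$kept)
})

test_that("excluded sites and the rescue list behave per configuration", {
  ref <- full_ref()
  # shipped excluded change is discarded; same position, other change kept
  chars <- strsplit(ref$sequence, "")[[1]]
  # synthesise calls matching the shipped table's first row (15493 G>A)
  calls <- variant_table(rbind(
    make_sub(position = 15493L, ref = "G", alt = "A"),
    make_sub(position = 15493L, ref = "G", alt = "C")))
  v <- filter_substitutions(calls, ref)
  expect_equal(v$kept, c(FALSE, TRUE))
  expect_equal(v$reasons[1], "excluded_site")

  # indel-proximity discard, then rescue of the listed 381 T>A
  indel <- variant_table(make_indel(position = 385L))
  prox <- variant_table(rbind(
    make_sub(position = 381L, ref = "T", alt = "A"),
    make_sub(position = 390L, ref = "C", alt = "T")))
  v0 <- filter_substitutions(prox, ref, indel_calls = indel)
  expect_equal(v0$kept, c(FALSE, FALSE))
  expect_true(all(grepl("indel_proximity", v0$reasons)))
  v1 <- filter_substitutions(prox, ref, indel_calls = indel,
                             rescue_list = default_rescue_list())
  expect_equal(v1$kept, c(TRUE, FALSE))
  expect_match(v1$reasons[1], "rescued")

  # rescue never overrides other rules
  other <- variant_table(make_sub(position = 381L, ref = "T", alt = "A",
                                  mean_mq = 10))
  v2 <- filter_substitutions(other, ref, indel_calls = indel,
                             rescue_list = default_rescue_list())
  expect_false(v2$kept)

  # proximity window stretches by REP
  indel_rep <- variant_table(make_indel(position = 385L, rep_count = 5L))
  far <- variant_table(make_sub(position = 400L, ref = "C", alt = "T"))
  expect_true(filter_substitutions(far, ref, indel_calls = indel)$kept)
  expect_false(filter_substitutions(far, ref, indel_calls = indel_rep)$kept)
})

test_that("indel rules: strand support, caller corroboration, region, samples", {
  ref <- full_ref()
  indels <- variant_table(rbind(
    make_indel(position = 100L, fwd_mut = 3L, rev_mut = 0L),   # kept
    make_indel(position = 200L, fwd_mut = 1L, rev_mut = 1L),   # weak
    make_indel(position = 16200L),                             # repeat
    make_indel(position = 300L, fwd_mut = 4L, rev_mut = 4L,
               bwa_reads = 0L, rep_count = 2L),                # no bwa, REP>0
    make_indel(position = 400L, fwd_mut = 4L, rev_mut = 4L,
               bwa_reads = 0L, rep_count = 0L),                # saved by REP=0
    make_indel(position = 500L, sample_id = "HIGHCOV")))
  v <- filter_indels(indels, ref, excluded_samples = "HIGHCOV")
  expect_equal(v$kept, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(v$reasons[2], "strand_support")
  expect_equal(v$reasons[3], "repeat_region")
  expect_equal(v$reasons[4], "caller_support")
  expect_equal(v$reasons[6], "high_coverage_sample")

  no_strand <- make_indel()
  no_strand$fwd_mut <- NA_integer_
  expect_error(filter_indels(variant_table(no_strand), ref),
               "per-strand")
})

test_that("filtering is idempotent and reasons reconcile counts", {
  ref <- full_ref()
  set.seed(31)
  calls <- variant_table(do.call(rbind, lapply(1:60, function(i) {
    make_sub(position = sample(16727, 1),
             mutant_reads = sample(5:60, 1), total_depth = 70L,
             fwd_mut = NULL, rev_mut = NULL,
             bq25_count = sample(0:20, 1),
             mean_mq = sample(c(15, 60), 1),
             read_end_only = sample(c(TRUE, FALSE), 1, prob = c(.2, .8)))
  })))
  v <- filter_substitutions(calls, ref)
  # every discarded call carries at least one machine-readable reason
  expect_true(all(nchar(v$reasons[!v$kept]) > 0))
  expect_true(all(v$reasons[v$kept] == ""))
  expect_equal(sum(!v$kept) + sum(v$kept), nrow(calls))
  # idempotence: filtering the kept set changes nothing
  kept <- variant_table(v[v$kept, names(calls)])
  v2 <- filter_substitutions(kept, ref)
  expect_true(all(v2$kept))
})

test_that("recurrence and back-mutation flags from grouped tumours", {
  donors <- list(`1` = c("10 A>G", "20 C>T"), `2` = c("30 G>A"))
  clades <- c(T1 = "1", T2 = "1", T3 = "2")
  keys <- list(
    T1 = c("10 A>G", "20 C>T", "55 C>T"),
    T2 = c("10 A>G", "55 C>T", "70 T>C"),   # missing 20 C>T -> back mutation
    T3 = c("30 G>A", "55 C>T"))             # 55 C>T now spans 2 clades
  fl <- flag_recurrence(keys, clades, donors)
  expect_equal(fl$recurrent, "55 C>T")
  expect_equal(nrow(fl$back_mutations), 1L)
  expect_equal(fl$back_mutations$tumour_id, "T2")
  expect_equal(fl$back_mutations$variant, "20 C>T")

  # a variant private to one tumour is never flagged
  fl2 <- flag_recurrence(list(T1 = c("10 A>G", "20 C>T", "99 A>C"),
                              T2 = c("10 A>G", "20 C>T")),
                         c(T1 = "1", T2 = "1"), donors["1"])
  expect_length(fl2$recurrent, 0L)
})
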