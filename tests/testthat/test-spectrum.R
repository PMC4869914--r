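test_that("class assignment: pyrimidine kept, purine complemented", {
  # sequence ... T C G ... at 10..12: C>T at 11 is light T[C>T]G
  sequence <- paste0(rand_seq(9, seed = 3), "TCG", rand_seq(9, seed = 4))
  ref <- mt_reference(sequence)
  cls <- assign_class(ref, 11, "C", "T")
  expect_equal(cls$strand, "light")
  expect_equal(cls$class, "T[C>T]G")

  # G>A with reference flanks 5'C 3'A complements to T[C>T]G on heavy
  sequence2 <- paste0(rand_seq(9, seed = 5), "CGA", rand_seq(9, seed = 6))
  ref2 <- mt_reference(sequence2)
  cls2 <- assign_class(ref2, 11, "G", "A")
  expect_equal(cls2$strand, "heavy")
  expect_equal(cls2$class, "T[C>T]G")

  expect_error(assign_class(ref, 11, "CA", "C"), "substitutions only")
})

test_that("class assignment agrees with independent re-derivation", {
  len <- 600L
  ref <- mt_reference(rand_seq(len, seed = 17))
  chars <- strsplit(ref$sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seen <- character()
  for (pos in seq_len(len)) {
    rb <- chars[pos]
    for (ab in setdiff(c("A", "C", "G", "T"), rb)) {
      cls <- assign_class(ref, pos, rb, ab)
      i5 <- chars[((pos - 2) %% len) + 1]
      i3 <- chars[(pos %% len) + 1]
      if (rb %in% c("C", "T")) {
        expect_equal(cls$class, paste0(i5, "[", rb, ">", ab, "]", i3))
        expect_equal(cls$strand, "light")
      } else {
        expect_equal(cls$class, paste0(comp[[i3]], "[", comp[[rb]], ">",
                                       comp[[ab]], "]", comp[[i5]]))
        expect_equal(cls$strand, "heavy")
      }
      seen <- union(seen, paste(cls$strand, cls$class))
    }
  }
  # every one of the 2 x 96 strand-classes is reachable on this genome
  expect_length(seen, 192L)
})

test_that("expected counts reproduce the published worked example", {
  # inputs: N = 835 observed mutations, TCG seen 117 times on the heavy
  # strand of a 16,727 bp genome, 22 observed heavy T[C>T]G
  census_h <- structure(list(strand = "heavy",
                             counts = c(TCG = 117L), n_counted = 117L),
                        class = "TripletCensus")
  census_h$counts <- c(stats::setNames(rep(0L, 64),
                                       mtclade:::.all_triplets()))
  census_h$counts[["TCG"]] <- 117L
  census_l <- census_h
  census_l$strand <- "light"

  exp_pres <- expected_counts(census_h, census_l, n_total = 835,
                              genome_length = 16727, presentation = TRUE)
  row <- exp_pres[exp_pres$strand == "heavy" & exp_pres$class == "T[C>T]G", ]
  expect_equal(round(117 / 16727, 3), 0.007)
  expect_equal(round(row$expected, 2), 1.95)

  res <- normalized_rates(data.frame(strand = "heavy", class = "T[C>T]G",
                                     observed = 22),
                          exp_pres, presentation = TRUE)
  rate <- res$rate[res$strand == "heavy" & res$class == "T[C>T]G"]
  expect_equal(rate, 11.28)

  # strict mode reports the full-precision ratio instead
  exp_strict <- expected_counts(census_h, census_l, 835, 16727)
  res_strict <- normalized_rates(data.frame(strand = "heavy",
                                            class = "T[C>T]G",
                                            observed = 22), exp_strict)
  rate_strict <- res_strict$rate[res_strict$strand == "heavy" &
                                   res_strict$class == "T[C>T]G"]
  expect_equal(round(rate_strict, 2), 11.30)
})

test_that("expected-count conservation and degenerate cases", {
  ref <- mt_reference(rand_seq(400, seed = 23))
  ch <- count_triplets(ref, "heavy")
  cl <- count_triplets(ref, "light")
  for (n in c(0, 17, 835)) {
    e <- expected_counts(ch, cl, n, ref$length)
    expect_equal(sum(e$expected), n, tolerance = 1e-12)
  }
  # with exclusions the total drops by the excluded fraction exactly
  ref_x <- mt_reference(ref$sequence,
                        excluded_regions = data.frame(start = 1, end = 100))
  ex <- expected_counts(count_triplets(ref_x, "heavy"),
                        count_triplets(ref_x, "light"), 400, ref_x$length)
  expect_equal(sum(ex$expected), 400 * 300 / 400, tolerance = 1e-12)

  # uniform triplet content gives uniform expectations within a strand
  census_u <- structure(list(strand = "heavy",
                             counts = stats::setNames(rep(10L, 64),
                                                      mtclade:::.all_triplets()),
                             n_counted = 640L), class = "TripletCensus")
  census_u2 <- census_u; census_u2$strand <- "light"
  eu <- expected_counts(census_u, census_u2, 96, 640)
  expect_equal(length(unique(round(eu$expected, 12))), 1L)

  # observed with zero expectation is flagged, not dropped
  zero <- expected_counts(census_u, census_u2, 0, 640)
  res0 <- normalized_rates(rep(0, nrow(zero)), zero)
  expect_true(all(res0$rate == 0))
  obs1 <- rep(0, nrow(zero)); obs1[5] <- 3
  res1 <- normalized_rates(obs1, zero)
  expect_true(res1$infinite[5])
})

test_that("complement symmetry: relabelled strands on the revcomp genome", {
  ref <- mt_reference(rand_seq(300, seed = 29))
  ref_rc <- mt_reference(revcomp_chr(ref$sequence))
  set.seed(7)
  pos <- sample(300, 40)
  chars <- strsplit(ref$sequence, "")[[1]]
  vars <- data.frame(position = pos, ref = chars[pos],
                     alt = vapply(chars[pos], function(b) {
                       sample(setdiff(c("A", "C", "G", "T"), b), 1)
                     }, ""))
  # mirrored variants on the reverse-complement genome
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vars_rc <- data.frame(position = 300 - pos + 1,
                        ref = unname(comp[vars$ref]),
                        alt = unname(comp[vars$alt]))
  s1 <- compute_spectrum(ref, vars)
  s2 <- compute_spectrum(ref_rc, vars_rc)
  # the same classes appear with strands swapped and identical rates
  key1 <- paste(s1$strand, s1$class)
  key2 <- paste(ifelse(s2$strand == "heavy", "light", "heavy"), s2$class)
  expect_equal(s1$rate[order(key1)], s2$rate[order(key2)])
  expect_equal(attr(s1, "n_total"), 40L)
})
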