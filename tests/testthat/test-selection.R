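test_that("KS comparisons: degenerate cases and exact small-n p-values", {
  same <- ks_vaf_test(c(.1, .5, .9), c(.1, .5, .9))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- ks_vaf_test(c(.1, .2), c(.8, .9))
  expect_equal(disjoint$statistic, 1)

  expect_error(ks_vaf_test(numeric(), c(1)), "non-empty")

  # exact p for n=m=3 equals full enumeration over C(6,3) assignments
  set.seed(99)
  for (rep in 1:10) {
    a <- round(runif(3), 6)
    b <- round(runif(3), 6)
    got <- ks_vaf_test(a, b)$p_value
    expect_equal(got, oracle_ks_exact_p(a, b), tolerance = 1e-12,
                 info = sprintf("rep %d", rep))
  }
  # and for unequal small sizes
  a <- c(.05, .31, .48, .77); b <- c(.22, .59, .83)
  expect_equal(ks_vaf_test(a, b)$p_value, oracle_ks_exact_p(a, b),
               tolerance = 1e-12)
})

test_that("opportunity counting: conservation, hand enumeration, exclusion", {
  ref <- tiny_ref(seed = 33)
  L <- count_opportunities(ref)
  heavy <- ref$genes[ref$genes$strand == "heavy", ]
  n_sites <- heavy$end - heavy$start + 1
  expect_equal(sum(L), 3 * n_sites)

  # the light-strand gene contributes no opportunities at all
  ref_no_light <- mt_reference(ref$sequence,
                               genes = ref$genes[ref$genes$strand == "heavy",
                                                 , drop = FALSE])
  expect_equal(count_opportunities(ref_no_light), L)
  only_light <- mt_reference(ref$sequence,
                             genes = ref$genes[ref$genes$strand == "light",
                                               , drop = FALSE])
  expect_error(count_opportunities(only_light), "no heavy-strand")

  # brute-force oracle on a 9-codon heavy gene
  cds <- "ATGACCGCATTATGATCCAAAGGGTAT"  # 27 bp
  seqn <- paste0("AAAAA", revcomp_chr(cds), "AAAAA")
  ref9 <- mt_reference(seqn, genes = data.frame(
    name = "G", start = 6, end = 32, strand = "heavy"))
  L9 <- count_opportunities(ref9)
  expect_equal(sum(L9), 81)
  # oracle: enumerate every substitution, classify independently
  counts_or <- c(synonymous = 0, missense = 0, nonsense = 0)
  ch9 <- strsplit(ref9$sequence, "")[[1]]
  for (pos in 6:32) {
    for (ab in setdiff(c("A", "C", "G", "T"), ch9[pos])) {
      cons <- oracle_consequence(ref9, pos, ch9[pos], ab)
      counts_or[cons] <- counts_or[cons] + 1
    }
  }
  expect_equal(colSums(L9), counts_or[colnames(L9)])
})

test_that("dN/dS single-context fit matches the closed-form rate ratio", {
  L <- matrix(0, nrow = 192, ncol = 3,
              dimnames = list(context_labels(),
                              c("synonymous", "missense", "nonsense")))
  n <- L
  L[1, ] <- c(1000, 2000, 150)
  n[1, ] <- c(40, 36, 2)
  fit <- dnds_fit(n, L, ci = FALSE)
  expect_equal(fit$w_mis, (36 / 2000) / (40 / 1000), tolerance = 1e-8)
  expect_equal(fit$w_non, (2 / 150) / (40 / 1000), tolerance = 1e-8)

  # boundary: zero observed nonsense with positive opportunity
  n0 <- n; n0[1, "nonsense"] <- 0
  fit0 <- dnds_fit(n0, L, ci = FALSE)
  expect_equal(fit0$w_non, 0)

  # LRT statistics are never negative; CIs bracket the estimate
  fit_ci <- dnds_fit(n, L)
  expect_gte(fit_ci$lrt$missense$statistic, 0)
  expect_gte(fit_ci$lrt$nonsense$statistic, 0)
  expect_lte(fit_ci$ci$missense[["lower"]], fit_ci$w_mis)
  expect_gte(fit_ci$ci$missense[["upper"]], fit_ci$w_mis)

  expect_error(dnds_fit(n * 0, L), "all observed")
})

test_that("MLE is a local optimum of the Poisson likelihood", {
  ref <- tiny_ref(seed = 7)
  L <- count_opportunities(ref)
  set.seed(11)
  n <- simulate_dnds_counts(L, 400, w_mis = 0.6, w_non = 0.3)
  fit <- dnds_fit(n, L, ci = FALSE)
  keep <- rowSums(L) > 0
  ll_at <- function(w_mis, w_non) {
    f <- mtclade:::.dnds_mle(n[keep, ], L[keep, ],
                             fix = c(mis = w_mis, non = w_non))
    f$loglik
  }
  base <- fit$loglik
  for (d in c(-0.07, 0.07)) {
    expect_lte(ll_at(fit$w_mis + d, fit$w_non), base + 1e-8)
    expect_lte(ll_at(fit$w_mis, max(fit$w_non + d, 1e-6)), base + 1e-8)
  }
})

test_that("null p-values are approximately uniform", {
  ref <- tiny_ref(seed = 13)
  L <- count_opportunities(ref)
  set.seed(101)
  p_mis <- replicate(400, {
    n <- simulate_dnds_counts(L, 300)
    dnds_fit(n, L, ci = FALSE)$lrt$missense$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p_mis, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("truncating-vs-other comparisons wire groups correctly", {
  subs <- data.frame(
    norm_vaf = c(runif(30, 0, .5), runif(40, .5, 1), runif(20, .4, 1)),
    consequence = c(rep("nonsense", 30), rep("missense", 40),
                    rep("synonymous", 20)))
  ind <- data.frame(norm_vaf = c(runif(15, 0, .4), runif(10, .6, 1)),
                    frameshift = c(rep(TRUE, 15), rep(FALSE, 10)))
  res <- truncating_vs_other_comparisons(subs, ind)
  expect_s3_class(res$substitutions, "KsComparison")
  expect_equal(res$substitutions$n_a, 30)
  expect_equal(res$substitutions$n_b, 60)
  expect_lt(res$substitutions$p_value, 0.05)
  expect_s3_class(res$indels, "KsComparison")

  # an empty group is reported as skipped, not an error
  res2 <- truncating_vs_other_comparisons(
    subs[subs$consequence != "nonsense", ], NULL)
  expect_true(res2$substitutions$skipped)
})

test_that("selection on VAFs is detectable and calibrated in simulation", {
  # heteroplasmy-penalised nonsense variants sit below the others
  set.seed(55)
  non <- rbeta(40, 2, 4)
  oth <- rbeta(200, 6, 2)
  res <- ks_vaf_test(non, oth)
  expect_lt(res$p_value, 0.05)

  # under the null the rejection rate tracks alpha
  set.seed(56)
  rej <- replicate(200, {
    ks_vaf_test(rbeta(30, 4, 2), rbeta(30, 4, 2))$p_value < 0.05
  })
  expect_lt(mean(rej), 0.12)
})
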