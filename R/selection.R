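# Negative-selection inference: VAF cumulative-distribution comparisons
# (two-sample Kolmogorov-Smirnov) and a context-dependent Poisson dN/dS.
#
# The dN/dS model: observed substitution counts in context j (12
# substitution types x 4 five-prime x 4 three-prime bases on the coding
# strand, 192 contexts) and impact class i (synonymous, missense,
# nonsense) are modelled as
#     n[j, i] ~ Poisson(r[j] * L[j, i] * w[i]),   w[syn] = 1,
# where L[j, i] are mutational opportunities counted from the
# reference. Selection coefficients w below 1 indicate negative
# selection; deviation from neutrality is tested per coefficient with a
# 1-df likelihood-ratio test, and 95% CIs come from the profile
# likelihood.

#' Two-sample Kolmogorov-Smirnov comparison of VAF distributions
#'
#' Two-sided test; the p-value is exact when `n_a * n_b <= 10^4` (and
#' there are no ties), asymptotic otherwise.
#'
#' @param values_a,values_b Numeric vectors (e.g. normalised VAFs).
#' @param label_a,label_b Group labels carried into the result.
#' @return List of class `KsComparison`: `statistic` (D), `p_value`,
#'   `n_a`, `n_b`, labels and values.
#' @export
ks_vaf_test <- function(values_a, values_b, label_a = "A", label_b = "B") {
  if (!length(values_a) || !length(values_b)) {
    .stopf("both groups must be non-empty")
  }
  exact <- length(values_a) * length(values_b) <= 1e4
  res <- suppressWarnings(
    stats::ks.test(values_a, values_b, exact = exact))
  structure(list(statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 label_a = label_a, label_b = label_b,
                 values_a = values_a, values_b = values_b),
            class = "KsComparison")
}

#' @export
print.KsComparison <- function(x, ...) {
  cat(sprintf("KS comparison %s (n=%d) vs %s (n=%d): D = %.4f, p = %.3g\n",
              x$label_a, x$n_a, x$label_b, x$n_b, x$statistic, x$p_value))
  invisible(x)
}

#' Truncating-vs-other VAF comparisons
#'
#' Builds the two negative-selection VAF contrasts: nonsense
#' substitutions against missense plus synonymous substitutions (from
#' the conservative somatic list), and frameshift against non-frameshift
#' somatic indels. A contrast with an empty group is reported as
#' skipped rather than tested.
#'
#' @param substitutions Data frame with `norm_vaf` and `consequence`
#'   (`synonymous` / `missense` / `nonsense` / `non_coding`).
#' @param indels Data frame with `norm_vaf` and `frameshift` (logical),
#'   or `NULL`.
#' @return List with elements `substitutions` and `indels`, each a
#'   `KsComparison` or a skip record `list(skipped = TRUE, message =)`.
#' @export
truncating_vs_other_comparisons <- function(substitutions, indels = NULL) {
  non <- substitutions$norm_vaf[substitutions$consequence == "nonsense"]
  oth <- substitutions$norm_vaf[substitutions$consequence %in%
                                  c("missense", "synonymous")]
  sub_res <- if (!length(non) || !length(oth)) {
    list(skipped = TRUE,
         message = "empty nonsense or missense+synonymous group")
  } else {
    ks_vaf_test(non, oth, "nonsense", "missense+synonymous")
  }

  ind_res <- NULL
  if (!is.null(indels)) {
    fs <- indels$norm_vaf[indels$frameshift]
    nfs <- indels$norm_vaf[!indels$frameshift]
    ind_res <- if (!length(fs) || !length(nfs)) {
      list(skipped = TRUE, message = "empty frameshift or non-frameshift group")
    } else {
      ks_vaf_test(fs, nfs, "frameshift", "non_frameshift")
    }
  }
  list(substitutions = sub_res, indels = ind_res)
}

.BASES <- c("A", "C", "G", "T")

# context label on the coding strand
#' @noRd
.context_label <- function(five, from, to, three) {
  paste0(five, "[", from, ">", to, "]", three)
}

#' All 192 substitution-in-context labels
#' @return Character vector of length 192.
#' @export
context_labels <- function() {
  g <- expand.grid(five = .BASES, from = .BASES, to = .BASES,
                   three = .BASES, stringsAsFactors = FALSE)
  g <- g[g$from != g$to, ]
  g <- g[order(g$from, g$to, g$five, g$three), ]
  .context_label(g$five, g$from, g$to, g$three)
}

#' Count mutational opportunities by context and impact
#'
#' Enumerates every possible single-base substitution at every included
#' coding site of every heavy-strand gene (light-strand genes are
#' excluded to avoid strand-bias confounding), classifies it by its
#' 192-context type on the coding strand and by impact, and tallies.
#'
#' @param ref An [mt_reference()].
#' @param exclude Positions excluded from the analysis; defaults to
#'   [excluded_positions()] of `ref`.
#' @return Matrix `L` of dimension 192 x 3 (contexts x
#'   `c("synonymous", "missense", "nonsense")`).
#' @export
count_opportunities <- function(ref, exclude = excluded_positions(ref)) {
  genes <- ref$genes[ref$genes$strand == "heavy", , drop = FALSE]
  if (!nrow(genes)) .stopf("no heavy-strand coding gene in reference")
  chars <- .seq_chars(ref$sequence)
  labels <- context_labels()
  impacts <- c("synonymous", "missense", "nonsense")
  L <- matrix(0L, nrow = length(labels), ncol = 3L,
              dimnames = list(labels, impacts))

  for (gi in seq_len(nrow(genes))) {
    gene <- genes[gi, ]
    for (pos in seq.int(gene$start, gene$end)) {
      if (pos %in% exclude) next
      ref_b <- chars[pos]
      if (!(ref_b %in% .BASES)) next
      # coding strand is the heavy strand: complement and flip flanks
      from <- .complement(ref_b)
      five <- .complement(chars[.circ(pos + 1L, ref$length)])
      three <- .complement(chars[.circ(pos - 1L, ref$length)])
      for (alt_b in setdiff(.BASES, ref_b)) {
        cons <- annotate_consequence(ref, pos, ref_b, alt_b)
        if (cons == "non_coding") next
        lab <- .context_label(five, from, .complement(alt_b), three)
        L[lab, cons] <- L[lab, cons] + 1L
      }
    }
  }
  L
}

#' Tally observed somatic substitutions by context and impact
#'
#' @param ref An [mt_reference()].
#' @param variants Data frame with `position`, `ref`, `alt`
#'   (substitutions in heavy-strand coding genes; others are dropped).
#' @return Matrix `n` of dimension 192 x 3, conformable with
#'   [count_opportunities()].
#' @export
count_observed <- function(ref, variants) {
  labels <- context_labels()
  impacts <- c("synonymous", "missense", "nonsense")
  n <- matrix(0L, nrow = length(labels), ncol = 3L,
              dimnames = list(labels, impacts))
  chars <- .seq_chars(ref$sequence)
  heavy_genes <- ref$genes[ref$genes$strand == "heavy", , drop = FALSE]
  if (!nrow(variants)) return(n)
  for (i in seq_len(nrow(variants))) {
    pos <- variants$position[i]
    in_heavy <- any(heavy_genes$start <= pos & heavy_genes$end >= pos)
    if (!in_heavy) next
    cons <- annotate_consequence(ref, pos, variants$ref[i], variants$alt[i])
    if (cons == "non_coding") next
    from <- .complement(variants$ref[i])
    to <- .complement(variants$alt[i])
    five <- .complement(chars[.circ(pos + 1L, ref$length)])
    three <- .complement(chars[.circ(pos - 1L, ref$length)])
    lab <- .context_label(five, from, to, three)
    n[lab, cons] <- n[lab, cons] + 1L
  }
  n
}

# log-likelihood of the Poisson factorisation (constant terms dropped)
#' @noRd
.dnds_loglik <- function(n, L, r, w) {
  mu <- outer(r, w) * L
  keep <- L > 0
  mu_k <- mu[keep]; n_k <- n[keep]
  pos <- mu_k > 0
  if (any(!pos & n_k > 0)) return(-Inf)
  sum(n_k[pos] * log(mu_k[pos]) - mu_k[pos]) - sum(lgamma(n_k + 1))
}

# MLE by coordinate ascent: r and w each have closed-form updates
#' @noRd
.dnds_mle <- function(n, L, fix = c(mis = NA, non = NA),
                      tol = 1e-12, max_iter = 5000L) {
  w <- c(synonymous = 1, missense = 1, nonsense = 1)
  if (!is.na(fix[["mis"]])) w[["missense"]] <- fix[["mis"]]
  if (!is.na(fix[["non"]])) w[["nonsense"]] <- fix[["non"]]
  free <- c(is.na(fix[["mis"]]), is.na(fix[["non"]]))

  r <- rep(0, nrow(n))
  for (iter in seq_len(max_iter)) {
    w_old <- w
    denom <- as.vector(L %*% w)
    r <- ifelse(denom > 0, rowSums(n) / denom, 0)
    for (k in which(c(free[1L], free[2L]))) {
      impact <- c("missense", "nonsense")[k]
      opp <- sum(r * L[, impact])
      w[[impact]] <- if (opp > 0) sum(n[, impact]) / opp else 0
    }
    if (max(abs(w - w_old)) < tol && iter > 1L) break
  }
  list(r = r, w = w, loglik = .dnds_loglik(n, L, r, w))
}

# profile log-likelihood over one selection coefficient
#' @noRd
.profile_ci <- function(n, L, which_w, w_hat, ll_hat, level = 0.95) {
  crit <- stats::qchisq(level, df = 1) / 2
  prof <- function(w_val) {
    fix <- c(mis = NA, non = NA)
    fix[[which_w]] <- w_val
    .dnds_mle(n, L, fix = fix)$loglik - (ll_hat - crit)
  }
  lower <- 0
  if (w_hat > 0 && prof(max(w_hat * 1e-6, 1e-12)) < 0) {
    lower <- stats::uniroot(prof, c(max(w_hat * 1e-6, 1e-12), w_hat),
                            tol = 1e-8)$root
  }
  hi <- max(w_hat, 1e-6) * 2
  while (prof(hi) > 0 && hi < 1e6) hi <- hi * 2
  upper <- if (hi >= 1e6) Inf else
    stats::uniroot(prof, c(max(w_hat, 1e-12), hi), tol = 1e-8)$root
  c(lower = lower, upper = upper)
}

#' Fit the context-dependent Poisson dN/dS model
#'
#' Maximum-likelihood estimation of the 192 context rates and the
#' selection coefficients `w_MIS` and `w_NON` (with `w_SYN` fixed at 1),
#' per-coefficient likelihood-ratio tests of neutrality (`w = 1`), and
#' profile-likelihood 95% confidence intervals.
#'
#' @param n Observed count matrix (192 x 3) from [count_observed()].
#' @param L Opportunity matrix (192 x 3) from [count_opportunities()].
#' @param ci Compute profile CIs (slower); default `TRUE`.
#' @return Object of class `DnDsFit`: `w_mis`, `w_non`, `rates`,
#'   log-likelihoods, `lrt` (statistic and p per coefficient), `ci`.
#' @export
dnds_fit <- function(n, L, ci = TRUE) {
  stopifnot(identical(dim(n), dim(L)))
  if (sum(n) == 0) .stopf("all observed counts are zero")
  # contexts with no opportunity anywhere carry no information
  keep <- rowSums(L) > 0
  n_k <- n[keep, , drop = FALSE]
  L_k <- L[keep, , drop = FALSE]

  fit <- .dnds_mle(n_k, L_k)
  ll_alt <- fit$loglik
  fit_mis1 <- .dnds_mle(n_k, L_k, fix = c(mis = 1, non = NA))
  fit_non1 <- .dnds_mle(n_k, L_k, fix = c(mis = NA, non = 1))

  lrt_mis <- max(0, 2 * (ll_alt - fit_mis1$loglik))
  lrt_non <- max(0, 2 * (ll_alt - fit_non1$loglik))

  cis <- NULL
  if (ci) {
    cis <- list(
      missense = .profile_ci(n_k, L_k, "mis", fit$w[["missense"]], ll_alt),
      nonsense = .profile_ci(n_k, L_k, "non", fit$w[["nonsense"]], ll_alt))
  }
  rates <- stats::setNames(rep(NA_real_, nrow(n)), rownames(n))
  rates[keep] <- fit$r

  structure(list(
    w_mis = fit$w[["missense"]], w_non = fit$w[["nonsense"]],
    rates = rates,
    loglik = ll_alt,
    loglik_mis_null = fit_mis1$loglik,
    loglik_non_null = fit_non1$loglik,
    lrt = list(
      missense = list(statistic = lrt_mis,
                      p_value = stats::pchisq(lrt_mis, 1, lower.tail = FALSE)),
      nonsense = list(statistic = lrt_non,
                      p_value = stats::pchisq(lrt_non, 1, lower.tail = FALSE))),
    ci = cis,
    n_observed = sum(n)), class = "DnDsFit")
}

#' @export
print.DnDsFit <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (is.null(ci)) return("")
    sprintf(" [%.3f, %.3f]", ci[["lower"]], ci[["upper"]])
  }
  cat(sprintf("dN/dS fit on %d substitutions\n", x$n_observed))
  cat(sprintf("  w_MIS = %.3f%s, LRT p = %.3g\n", x$w_mis,
              fmt_ci(x$ci$missense), x$lrt$missense$p_value))
  cat(sprintf("  w_NON = %.3f%s, LRT p = %.3g\n", x$w_non,
              fmt_ci(x$ci$nonsense), x$lrt$nonsense$p_value))
  invisible(x)
}
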