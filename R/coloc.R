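# Approximate-Bayes-factor fine-mapping and two-trait colocalization.
#
# Per-SNP evidence is the Wakefield asymptotic log Bayes factor computed from
# an effect estimate and its variance under a Gaussian effect prior:
#   lABF = 1/2 [ log(1 - r) + r z^2 ],  r = W / (W + V),  z = beta / sqrt(V),
# with W the prior effect variance. Under the assumption of at most one
# causal variant per trait in the region, the five colocalization hypotheses
# (H0 none, H1 trait-1 only, H2 trait-2 only, H3 two distinct causal
# variants, H4 one shared causal variant) have posteriors proportional to
# prior-weighted sums of per-SNP Bayes factors, all accumulated in log space.

#' Wakefield approximate log Bayes factor
#'
#' @param beta Effect estimate.
#' @param varbeta Variance of the estimate (`se^2`), > 0. Vectorized over
#'   `beta`/`varbeta`.
#' @param W Prior variance of the true effect, >= 0 (default 0.0225, i.e.
#'   prior sd 0.15, the usual quantitative-trait choice).
#' @return log ABF (natural log), same length as `beta`.
#' @export
#' @examples
#' log_abf(0.3, 0.01)          # strong association, positive lABF
#' log_abf(0, 1, W = 0)        # null prior: BF = 1, lABF = 0
log_abf <- function(beta, varbeta, W = 0.0225) {
  if (any(!is.finite(varbeta)) || any(varbeta <= 0))
    stop("varbeta must be > 0")
  if (any(W < 0)) stop("prior variance W must be >= 0")
  r <- W / (W + varbeta)
  z2 <- beta^2 / varbeta
  0.5 * (log1p(-r) + r * z2)
}

# numerically stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# align two assoc_stats on shared rsids, preserving trait-1 order
.align_traits <- function(t1, t2) {
  shared <- intersect(t1$rsid, t2$rsid)
  dropped <- (nrow(t1) - length(shared)) + (nrow(t2) - length(shared))
  if (length(shared) < 2L) {
    stop(sprintf(
      "need >= 2 shared SNPs for colocalization (trait 1: %d, trait 2: %d, shared: %d)",
      nrow(t1), nrow(t2), length(shared)))
  }
  if (dropped > 0)
    message(sprintf("coloc: dropped %d SNPs present in only one trait",
                    dropped))
  list(t1 = t1[match(shared, t1$rsid), , drop = FALSE],
       t2 = t2[match(shared, t2$rsid), , drop = FALSE],
       snps = shared)
}

#' Two-trait approximate-Bayes-factor colocalization
#'
#' Computes the PP0-PP4 hypothesis posteriors and the per-SNP posterior of
#' being the shared causal variant, from per-trait effect estimates and
#' variances. Hypothesis sums are accumulated with log-sum-exp; the H3 term
#' `exp(S1 + S2) - exp(S12)` (a sum over distinct SNP pairs, mathematically
#' non-negative) is clamped to zero with a warning if floating error drives
#' it negative.
#'
#' @param t1,t2 [assoc_stats()] containers (intersected on shared rsids;
#'   SNPs present in only one trait are dropped with a message).
#' @param p1,p2 Prior probability a SNP is causal for trait 1 / trait 2 only
#'   (defaults 1e-4).
#' @param p12 Prior probability a SNP is causal for both traits (default
#'   1e-5).
#' @param W1,W2 Prior effect variances per trait (default 0.0225 each).
#' @return List of class `coloc_result`: `pp` (named length-5 vector
#'   PP0..PP4), `per_snp_h4` (named posterior vector over shared SNPs),
#'   `snps`, `positions`, `n_snps`, `priors`, `W`.
#' @export
coloc_abf <- function(t1, t2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W1 = 0.0225, W2 = 0.0225) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1)
  al <- .align_traits(t1, t2)
  l1 <- log_abf(al$t1$beta, al$t1$varbeta, W1)
  l2 <- log_abf(al$t2$beta, al$t2$varbeta, W2)
  s1 <- .logsumexp(l1)
  s2 <- .logsumexp(l2)
  s12 <- .logsumexp(l1 + l2)
  # log(exp(s1 + s2) - exp(s12)), clamped: the difference is a sum over
  # off-diagonal SNP pairs and cannot be negative in exact arithmetic
  delta <- s12 - (s1 + s2)
  if (delta >= 0) {
    if (delta > 1e-9) warning("H3 term negative beyond rounding; clamped to 0")
    l_h3_sum <- -Inf
  } else {
    l_h3_sum <- s1 + s2 + log1p(-exp(delta))
  }
  lw <- c(h0 = 0,
          h1 = log(p1) + s1,
          h2 = log(p2) + s2,
          h3 = log(p1) + log(p2) + l_h3_sum,
          h4 = log(p12) + s12)
  m <- max(lw)
  pp <- exp(lw - m) / sum(exp(lw - m))
  names(pp) <- paste0("PP", 0:4)
  snp_lh <- l1 + l2
  h4 <- exp(snp_lh - .logsumexp(snp_lh))
  names(h4) <- al$snps
  structure(list(pp = pp, per_snp_h4 = h4, snps = al$snps,
                 positions = al$t1$pos, n_snps = length(al$snps),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 W = c(W1 = W1, W2 = W2)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d SNPs\n", x$n_snps))
  print(round(x$pp, 4))
  top <- which.max(x$per_snp_h4)
  cat(sprintf("top shared-causal SNP: %s (posterior %.3f)\n",
              names(x$per_snp_h4)[top], x$per_snp_h4[top]))
  invisible(x)
}

#' Per-SNP posterior of being the shared causal variant
#'
#' The softmax of `lABF1 + lABF2` over the SNPs shared by the two traits:
#' the posterior probability, under H4, that each SNP is the single shared
#' causal variant. Sums to 1.
#'
#' @inheritParams coloc_abf
#' @return Named numeric vector over shared SNPs with attribute `positions`.
#' @export
per_snp_h4 <- function(t1, t2, W1 = 0.0225, W2 = 0.0225) {
  al <- .align_traits(t1, t2)
  lh <- log_abf(al$t1$beta, al$t1$varbeta, W1) +
        log_abf(al$t2$beta, al$t2$varbeta, W2)
  post <- exp(lh - .logsumexp(lh))
  names(post) <- al$snps
  attr(post, "positions") <- al$t1$pos
  post
}

#' Single-trait fine-mapping under one causal variant
#'
#' The softmax of the per-SNP Wakefield log ABFs: the posterior that each
#' SNP is the causal variant, assuming exactly one causal variant in the
#' region. Sums to 1.
#'
#' @param t An [assoc_stats()] container with >= 2 SNPs.
#' @param W Prior effect variance (default 0.0225).
#' @return Named numeric vector over the trait's SNPs with attribute
#'   `positions`.
#' @export
finemap_single_trait <- function(t, W = 0.0225) {
  if (nrow(t) < 2L) stop("need >= 2 SNPs to fine-map")
  lh <- log_abf(t$beta, t$varbeta, W)
  post <- exp(lh - .logsumexp(lh))
  names(post) <- t$rsid
  attr(post, "positions") <- t$pos
  post
}
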