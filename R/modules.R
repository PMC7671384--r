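# Co-expression module detection: eGene-anchored gene-set assembly, average-
# linkage hierarchical clustering on the 1 - rho distance, gap-statistic
# selection of the number of modules (globalSEmax rule), and the eQTL-content
# filter.

#' Pairwise Spearman correlation matrix
#'
#' Rank correlation with average ranks for ties; symmetric with unit
#' diagonal. A constant gene row yields undefined correlations: these are
#' kept as `NA` and the offending genes are recorded in attribute
#' `undefined_genes` rather than silently dropped.
#'
#' @param expr A complete [expression_matrix()] (genes x samples).
#' @param genes Optional subset of gene ids (default: all).
#' @return List of class `correlation_matrix`: `genes`, `rho`.
#' @export
spearman_matrix <- function(expr, genes = NULL) {
  x <- unclass(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
      stop(sprintf("gene '%s' not in expression matrix", missing[1L]))
    x <- x[genes, , drop = FALSE]
  }
  if (ncol(x) < 3L) stop("need at least 3 samples")
  if (anyNA(x)) stop("expression matrix must be complete (impute first)")
  constant <- rownames(x)[apply(x, 1L, function(v) length(unique(v)) == 1L)]
  rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2  # enforce exact symmetry
  structure(list(genes = rownames(x), rho = rho,
                 undefined_genes = constant),
            class = "correlation_matrix")
}

#' Assemble the eGene-anchored co-expression gene set
#'
#' The eGenes plus every gene whose absolute Spearman correlation with at
#' least one eGene reaches `rho_threshold` (inclusive; anti-correlated
#' partners qualify through the absolute value).
#'
#' @param egenes Character vector of eGene ids (must be in `expr`).
#' @param expr Complete [expression_matrix()].
#' @param rho_threshold Co-expression threshold, default 0.90.
#' @return Character vector of gene ids (eGenes first, then partners, each in
#'   expression-matrix order).
#' @export
assemble_geneset <- function(egenes, expr, rho_threshold = 0.90) {
  if (!length(egenes)) stop("no eGenes to anchor modules")
  all_genes <- rownames(expr)
  missing <- setdiff(egenes, all_genes)
  if (length(missing))
    stop(sprintf("eGene '%s' not in expression matrix", missing[1L]))
  cm <- spearman_matrix(expr)
  sub <- abs(cm$rho[, match(egenes, cm$genes), drop = FALSE])
  partner <- all_genes[apply(sub, 1L, max) >= rho_threshold]
  egenes_o <- all_genes[all_genes %in% egenes]
  c(egenes_o, setdiff(partner, egenes_o))
}

#' Hierarchical co-expression tree
#'
#' Agglomerative average-linkage clustering on the distance `d = 1 - rho`
#' (range \[0, 2\]; perfectly correlated genes merge at height 0,
#' anti-correlated genes join near height 2).
#'
#' @param corr A `correlation_matrix` from [spearman_matrix()].
#' @return An [stats::hclust] dendrogram over the genes.
#' @export
cluster_tree <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (length(corr$genes) < 2L) stop("need at least 2 genes to cluster")
  if (length(corr$undefined_genes))
    stop(sprintf("undefined correlations for: %s",
                 paste(corr$undefined_genes, collapse = ", ")))
  d <- stats::as.dist(1 - corr$rho)
  stats::hclust(d, method = "average")
}

# within-cluster dispersion W_k in the pairwise-distance form:
# sum over clusters of (sum of all pairwise distances in cluster) / (2 n_r).
# Valid for arbitrary (non-Euclidean) dissimilarities such as 1 - rho.
.within_dispersion <- function(D, labels) {
  w <- 0
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) > 1L)
      w <- w + sum(D[idx, idx]) / (2 * length(idx))
  }
  w
}

# log W_k for k = 1..k_max from an expression sub-matrix (genes x samples)
.log_wk_curve <- function(x, k_max) {
  rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  diag(rho) <- 1
  D <- 1 - (rho + t(rho)) / 2
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  vapply(seq_len(k_max), function(k) {
    labels <- stats::cutree(tree, k = k)
    w <- .within_dispersion(D, labels)
    log(max(w, .Machine$double.xmin))
  }, numeric(1))
}

#' Gap statistic over hierarchical cuts of the co-expression tree
#'
#' For each k, the within-module dispersion `W_k` (pairwise-distance form on
#' the 1 - rho distances under the k-cut of the average-linkage tree) is
#' compared against `B` reference datasets: `Gap(k) = mean_b log W*_kb -
#' log W_k`, `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`. The default reference
#' permutes each gene's values across samples independently, which destroys
#' gene-gene correlation while preserving every gene's marginal distribution;
#' `reference = "uniform"` draws each sample column uniformly within its
#' observed range instead (the original box reference).
#'
#' @param expr_subset Numeric matrix (genes x samples) restricted to the
#'   assembled gene set, complete.
#' @param k_max Largest number of modules to consider (< number of genes).
#' @param B Number of reference datasets, default 50.
#' @param seed Integer seed making the reference draws reproducible.
#' @param reference `"permute"` (default) or `"uniform"`.
#' @return List of class `gap_curve`: `k_values`, `gap`, `se`, `log_wk`,
#'   `log_wk_ref` (B x k matrix), `b_reference`.
#' @export
gap_statistic <- function(expr_subset, k_max, B = 50, seed = 1L,
                          reference = c("permute", "uniform")) {
  reference <- match.arg(reference)
  x <- unclass(expr_subset)
  n <- nrow(x)
  if (k_max >= n) stop("k_max must be smaller than the number of genes")
  stopifnot(B >= 1)
  log_wk <- .log_wk_curve(x, k_max)
  ref <- matrix(NA_real_, nrow = B, ncol = k_max)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(B)) {
    xb <- switch(reference,
      permute = t(apply(x, 1L, sample)),
      uniform = apply(x, 2L, function(col)
        stats::runif(n, min(col), max(col))))
    if (reference == "uniform") xb <- matrix(xb, nrow = n)
    ref[b, ] <- .log_wk_curve(xb, k_max)
  }
  gap <- colMeans(ref) - log_wk
  se <- apply(ref, 2L, stats::sd) * sqrt(1 + 1 / B)
  if (B == 1L) se <- rep(0, k_max)
  structure(list(k_values = seq_len(k_max), gap = gap, se = se,
                 log_wk = log_wk, log_wk_ref = ref, b_reference = B),
            class = "gap_curve")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Choose the number of modules by the globalSEmax rule
#'
#' With `k* = argmax Gap(k)` (smallest k on ties), the chosen K is the
#' smallest k with `Gap(k) >= Gap(k*) - s_{k*}` — the smallest module count
#' whose gap is within one standard error of the global maximum.
#'
#' @param curve A `gap_curve`.
#' @return Integer K.
#' @export
choose_k_globalSEmax <- function(curve) {
  stopifnot(inherits(curve, "gap_curve"), length(curve$gap) >= 1L)
  k_star <- which.max(curve$gap)  # which.max returns the first (smallest) max
  thr <- curve$gap[k_star] - curve$se[k_star]
  curve$k_values[which(curve$gap >= thr)[1L]]
}

#' Cut the tree into K modules and apply the eQTL-content filter
#'
#' Modules containing no gene flagged as an eQTL gene are dropped from
#' `retained` (the pathway-enrichment half of the omission rule is applied
#' downstream by [omit_unenriched()]).
#'
#' @param tree An [stats::hclust] tree from [cluster_tree()].
#' @param K Number of modules (>= 1).
#' @param egene_map Named logical vector over the tree's genes: `TRUE` when
#'   the gene has an eQTL.
#' @param gap_curve Optional `gap_curve` stored alongside.
#' @return List of class `module_partition`: `assignments` (named integer
#'   vector gene -> 1..K), `K`, `retained` (integer labels), `gap_curve`.
#' @export
cut_and_filter <- function(tree, K, egene_map, gap_curve = NULL) {
  stopifnot(K >= 1)
  assignments <- stats::cutree(tree, k = K)
  flags <- egene_map[names(assignments)]
  flags[is.na(flags)] <- FALSE
  retained <- sort(unique(assignments[flags]))
  structure(list(assignments = assignments, K = K,
                 retained = as.integer(retained), gap_curve = gap_curve),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d genes in %d modules, %d retained (%s)\n",
              length(x$assignments), x$K, length(x$retained),
              paste(x$retained, collapse = ",")))
  invisible(x)
}
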