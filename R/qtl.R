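# SNP-gene association testing, expression imputation, eGene selection, and
# static QTL-compendium lookup.

#' k-nearest-neighbour imputation of missing expression values
#'
#' Each missing cell is replaced by the mean, over the k nearest genes, of
#' that sample's values. Gene-gene distance is Euclidean over mutually
#' observed samples, scaled by the number of shared samples, so genes with
#' different missingness patterns remain comparable; only genes observed in
#' the target sample are eligible neighbours. Ties are broken by gene-id
#' order. Observed cells are never altered.
#'
#' A missing cell with fewer than `k` eligible neighbour genes falls back to
#' its gene's observed mean; when any cell does, the result carries
#' attribute `imputation_fallback = TRUE`.
#'
#' @param expr An [expression_matrix()] (genes x samples), `NA` = missing.
#' @param k Number of neighbours, default 10.
#' @return A complete [expression_matrix()].
#' @export
knn_impute <- function(expr, k = 10) {
  stopifnot(k >= 1)
  x <- unclass(expr)
  attr(x, "tissue") <- NULL
  miss <- is.na(x)
  all_missing <- rownames(x)[rowSums(!miss) == 0L]
  if (length(all_missing))
    stop(sprintf("gene '%s' has no observed values", all_missing[1L]))
  if (!any(miss)) return(expr)

  gene_order <- order(rownames(x))  # tie-break: gene-id order
  filled <- x
  fallback <- FALSE
  for (i in which(rowSums(miss) > 0L)) {
    obs_i <- !miss[i, ]
    # scaled squared distance to every other gene over shared observed samples
    d2 <- rep(Inf, nrow(x))
    for (g in seq_len(nrow(x))) {
      if (g == i) next
      shared <- obs_i & !miss[g, ]
      ns <- sum(shared)
      if (ns == 0L) next
      d2[g] <- sum((x[i, shared] - x[g, shared])^2) / ns
    }
    for (j in which(miss[i, ])) {
      elig <- which(is.finite(d2) & !miss[, j])
      if (length(elig) < k) {
        filled[i, j] <- mean(x[i, ], na.rm = TRUE)
        fallback <- TRUE
        next
      }
      elig <- elig[order(d2[elig], match(elig, gene_order))]
      filled[i, j] <- mean(x[utils::head(elig, k), j])
    }
  }
  out <- expression_matrix(filled, tissue = attr(expr, "tissue"))
  if (fallback) attr(out, "imputation_fallback") <- TRUE
  out
}

#' Test a single SNP-gene association
#'
#' Ordinary least-squares simple regression of expression on allele dosage:
#' `beta = cov(g, y) / var(g)`, standard error from the residual variance on
#' n - 2 degrees of freedom, two-sided p from the t distribution. Samples
#' are intersected by id when both vectors are named.
#'
#' @param dosages Named numeric vector of dosages in \{0,1,2\}.
#' @param expr_row Named numeric vector of expression values.
#' @param rsid,gene_id,tissue Identifiers carried into the result.
#' @return One-row data.frame: rsid, gene_id, tissue, beta, se, p_value, n.
#' @export
test_eqtl <- function(dosages, expr_row, rsid = "rs0", gene_id = "gene",
                      tissue = "tissue") {
  if (!is.null(names(dosages)) && !is.null(names(expr_row))) {
    shared <- intersect(names(dosages), names(expr_row))
    g <- dosages[shared]; y <- expr_row[shared]
  } else {
    if (length(dosages) != length(expr_row))
      stop("unnamed vectors must have equal length")
    g <- dosages; y <- expr_row
  }
  n <- length(g)
  if (n < 3L) stop("fewer than 3 shared samples")
  if (stats::var(g) == 0)
    stop(sprintf("SNP %s monomorphic in tissue %s", rsid, tissue))
  fit <- .simple_ols(g, y)
  data.frame(rsid = rsid, gene_id = gene_id, tissue = tissue,
             beta = fit$beta, se = fit$se, p_value = fit$p, n = n,
             stringsAsFactors = FALSE)
}

# closed-form simple regression; p capped into (0,1]
.simple_ols <- function(g, y) {
  n <- length(g)
  gc <- g - mean(g); yc <- y - mean(y)
  sxx <- sum(gc^2)
  beta <- sum(gc * yc) / sxx
  resid <- yc - beta * gc
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  if (se == 0) {
    p <- .Machine$double.xmin
  } else {
    p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(beta = beta, se = se, p = p)
}

# marginal OLS of y on each column of G; returns beta, varbeta, p vectors
.marginal_ols <- function(G, y) {
  n <- nrow(G)
  Gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(Gc^2)
  beta <- as.vector(crossprod(Gc, yc)) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  s2 <- rss / (n - 2)
  varbeta <- s2 / sxx
  tval <- beta / sqrt(varbeta)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(beta = beta, varbeta = varbeta, p = pmax(p, .Machine$double.xmin))
}

#' Select eGenes from eQTL results
#'
#' A gene is an eGene when at least one of its association results reaches
#' `p_value <= alpha` (inclusive; per-tissue nominal p, no multiple-testing
#' correction — the enrichment stage reports adjusted values separately).
#' Each retained gene keeps its minimal-p supporting record per tissue.
#'
#' @param results Data.frame of [test_eqtl()] rows.
#' @param alpha Significance threshold, default 0.05.
#' @return List with `genes` (character vector) and `support` (data.frame of
#'   per-gene, per-tissue minimal-p records for the retained genes).
#' @export
select_egenes <- function(results, alpha = 0.05) {
  if (!nrow(results)) stop("no eQTL results supplied")
  hit <- results$p_value <= alpha
  genes <- unique(results$gene_id[hit])
  sub <- results[results$gene_id %in% genes, , drop = FALSE]
  key <- interaction(sub$gene_id, sub$tissue, drop = TRUE)
  idx <- unlist(lapply(split(seq_len(nrow(sub)), key),
                       function(i) i[which.min(sub$p_value[i])]),
                use.names = FALSE)
  support <- sub[sort(idx), , drop = FALSE]
  rownames(support) <- NULL
  list(genes = genes, support = support)
}

#' Look up lead and proxy SNPs in static QTL compendia
#'
#' Exact rsid matches across all QTL classes, each hit annotated with whether
#' it lies on the lead SNP or a proxy.
#'
#' @param lead_rsid Lead SNP rsID.
#' @param proxy_rsids Character vector of proxy rsIDs.
#' @param qtl_table Validated QTL data.frame (all classes stacked, with a
#'   `qtl_class` column).
#' @return The matching rows with an added `hit_on` column
#'   (`"lead"`/`"proxy"`).
#' @export
lookup_static_qtls <- function(lead_rsid, proxy_rsids, qtl_table) {
  keep <- qtl_table$rsid %in% c(lead_rsid, proxy_rsids)
  out <- qtl_table[keep, , drop = FALSE]
  out$hit_on <- ifelse(out$rsid == lead_rsid, "lead", "proxy")
  rownames(out) <- NULL
  out
}
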