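# Fisher-exact pathway enrichment of retained modules, Benjamini-Hochberg
# adjustment within tissue, the enrichment half of the module omission rule,
# and the cross-tissue pathway aggregation.

#' One-sided Fisher exact test on a 2x2 table
#'
#' With `a` = module-and-pathway, `b` = module-only, `c` = pathway-only and
#' `d` = neither (within the gene universe), the one-sided (greater) p-value
#' is the hypergeometric tail `P(X >= a)` with the table's margins, and the
#' odds ratio is the cross-product `a d / (b c)` (`+Inf` when `b c = 0` and
#' `a d > 0`).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `odds_ratio` and `p_value`.
#' @export
#' @examples
#' fisher_exact_greater(5, 0, 0, 5)  # OR = Inf, p = 1/choose(10, 5)
fisher_exact_greater <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  m <- a + b          # module size
  n_p <- a + c        # pathway size
  N <- a + b + c + d  # universe
  # support of the hypergeometric given the margins
  x <- seq.int(max(0, m + n_p - N), min(m, n_p))
  probs <- stats::dhyper(x, n_p, N - n_p, m)
  p <- sum(probs[x >= a])
  p <- min(max(p, .Machine$double.xmin), 1)
  ad <- a * d; bc <- b * c
  or <- if (bc == 0) {
    if (ad > 0) Inf else NaN
  } else ad / bc
  list(odds_ratio = or, p_value = p)
}

#' Enrichment of one module against a pathway collection
#'
#' Pathways are intersected with the universe before counting; pathways with
#' no universe member produce no result row. P-values here are raw; the
#' tissue-level wrapper applies BH across all (module, pathway) pairs.
#'
#' @param module_genes Character vector, subset of `universe`.
#' @param pathways A [pathway_collection()].
#' @param universe Character vector of background genes (typically all genes
#'   in the tissue's expression matrix).
#' @return Data.frame: pathway_id, pathway_name, a, b, c, d, odds_ratio,
#'   p_value.
#' @export
enrich_module <- function(module_genes, pathways, universe) {
  if (!length(universe)) stop("empty gene universe")
  universe <- unique(universe)
  module_genes <- intersect(module_genes, universe)
  rows <- lapply(names(pathways$members), function(pid) {
    pw <- intersect(pathways$members[[pid]], universe)
    if (!length(pw)) return(NULL)
    a <- length(intersect(module_genes, pw))
    b <- length(module_genes) - a
    c_ <- length(pw) - a
    d <- length(universe) - a - b - c_
    ft <- fisher_exact_greater(a, b, c_, d)
    data.frame(pathway_id = pid,
               pathway_name = unname(pathways$names[pid]),
               a = a, b = b, c = c_, d = d,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway_id = character(0), pathway_name = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enrichment of all retained modules in one tissue
#'
#' Runs [enrich_module()] for every retained module of the partition and
#' applies Benjamini-Hochberg adjustment across all (module, pathway) pairs
#' within the tissue.
#'
#' @param partition A `module_partition`.
#' @param pathways A [pathway_collection()].
#' @param universe Background gene set.
#' @param tissue Tissue label carried into the rows.
#' @return Data.frame with columns tissue, module, pathway_id, pathway_name,
#'   a, b, c, d, odds_ratio, p_value, p_adjusted.
#' @export
enrich_partition <- function(partition, pathways, universe,
                             tissue = "tissue") {
  stopifnot(inherits(partition, "module_partition"))
  rows <- lapply(partition$retained, function(lab) {
    genes <- names(partition$assignments)[partition$assignments == lab]
    res <- enrich_module(genes, pathways, universe)
    if (!nrow(res)) return(NULL)
    cbind(data.frame(tissue = tissue, module = lab,
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tissue = character(0), module = integer(0),
                      pathway_id = character(0), pathway_name = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      stringsAsFactors = FALSE))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Apply the enrichment half of the module omission rule
#'
#' A retained module must additionally show at least one pathway with raw
#' `p_value <= alpha_enrich`; modules failing this are dropped from
#' `retained` (BH-adjusted values are reported alongside but the omission
#' rule is on raw p by default).
#'
#' @param results Output of [enrich_partition()] for this partition.
#' @param partition A `module_partition`.
#' @param alpha_enrich Enrichment threshold, default 0.05.
#' @return The partition with `retained` filtered.
#' @export
omit_unenriched <- function(results, partition, alpha_enrich = 0.05) {
  stopifnot(inherits(partition, "module_partition"))
  ok <- unique(results$module[results$p_value <= alpha_enrich])
  partition$retained <- partition$retained[partition$retained %in% ok]
  partition
}

#' Aggregate enrichment across tissues
#'
#' For each (pathway, tissue) pair the best (smallest-p) module-level result
#' is kept, ties broken by the smaller module label; pathways enriched
#' nowhere (no result with `p_value <= alpha`) are absent. Rows are ordered
#' by pathway id then tissue name.
#'
#' @param results_per_tissue List of [enrich_partition()] outputs (one per
#'   tissue), or a single stacked data.frame.
#' @param alpha Enrichment threshold deciding presence, default 0.05.
#' @return Data.frame: pathway_id, pathway_name, tissue, module, odds_ratio,
#'   p_value, p_adjusted.
#' @export
aggregate_across_tissues <- function(results_per_tissue, alpha = 0.05) {
  df <- if (is.data.frame(results_per_tissue)) results_per_tissue
        else do.call(rbind, results_per_tissue)
  if (is.null(df) || !nrow(df)) stop("no tissue analyzed")
  df <- df[df$p_value <= alpha, , drop = FALSE]
  if (!nrow(df)) return(df)
  df <- df[order(df$pathway_id, df$tissue, df$p_value, df$module), ,
           drop = FALSE]
  key <- paste(df$pathway_id, df$tissue, sep = "\r")
  out <- df[!duplicated(key), c("pathway_id", "pathway_name", "tissue",
                                "module", "odds_ratio", "p_value",
                                "p_adjusted"), drop = FALSE]
  rownames(out) <- NULL
  out
}
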