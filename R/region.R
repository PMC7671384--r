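# LD-region construction and candidate-gene search-space expansion.
#
# The LD region of a lead SNP is the genomic span covered by the lead and all
# proxies with r^2 at or above the threshold (0.80 by default). The candidate
# gene set unions (i) genes whose TSS lies within the eQTL mapping window of
# the lead (1 Mb either side by default, the GTEx convention) and (ii) genes
# recruited through chromosomal interactions whose other anchor overlaps the
# LD region, restricted to the region's chromosome.

#' Squared correlation between two dosage vectors
#'
#' Composite LD: the squared Pearson correlation of unphased allele dosages.
#' Symmetric in its arguments and invariant to allele flipping
#' (`d -> 2 - d`).
#'
#' @param dosage_a,dosage_b Numeric vectors of dosages in \{0,1,2\}, equal
#'   length >= 3, neither constant.
#' @return r^2 in \[0,1\].
#' @export
#' @examples
#' compute_r2(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0))  # 1
compute_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b))
    stop("dosage vectors must have equal length")
  if (length(dosage_a) < 3L) stop("need at least 3 samples")
  if (stats::var(dosage_a) == 0 || stats::var(dosage_b) == 0)
    stop("monomorphic variant: constant dosage vector")
  stats::cor(dosage_a, dosage_b)^2
}

#' Build the LD region of a lead SNP
#'
#' Proxies are filtered by `r2 >= r2_threshold` (inclusive, mirroring the
#' usual printed rule "r2 >= 0.80"); the span is the 0-based half-open
#' interval from the minimum to the maximum position over the lead plus
#' qualifying proxies. A lead with no qualifying proxy yields a 1-bp span.
#'
#' @param lead A [snp_record()].
#' @param proxies Data.frame of proxy records for this lead (may be empty).
#' @param r2_threshold Inclusion threshold in (0,1], default 0.80.
#' @return A list of class `ld_region` with fields `lead`, `proxies`
#'   (qualifying rows), `span`, `r2_threshold`.
#' @export
build_ld_region <- function(lead, proxies = NULL, r2_threshold = 0.80) {
  stopifnot(inherits(lead, "snp_record"))
  if (is.na(lead$pos)) stop("lead SNP has no position")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0,1]")
  if (is.null(proxies))
    proxies <- as.data.frame(stats::setNames(
      list(character(0), character(0), character(0), numeric(0), numeric(0)),
      .required_cols$proxies))
  proxies <- validate_records(as.data.frame(proxies), "proxies")
  proxies <- proxies[proxies$lead_rsid == lead$rsid &
                       proxies$proxy_rsid != lead$rsid, , drop = FALSE]
  if (nrow(proxies) && any(proxies$chrom != lead$chrom))
    stop(sprintf("proxy on different chromosome than lead %s", lead$rsid))
  keep <- proxies[proxies$r2 >= r2_threshold, , drop = FALSE]
  rownames(keep) <- NULL
  pos <- c(lead$pos, keep$pos)
  span <- genomic_interval(lead$chrom, min(pos) - 1, max(pos))
  structure(list(lead = lead, proxies = keep, span = span,
                 r2_threshold = r2_threshold),
            class = "ld_region")
}

#' @export
print.ld_region <- function(x, ...) {
  cat(sprintf("ld_region %s: %d proxies (r2 >= %.2f), span %s:%d-%d (%d bp)\n",
              x$lead$rsid, nrow(x$proxies), x$r2_threshold, x$span$chrom,
              x$span$start, x$span$end, x$span$end - x$span$start))
  invisible(x)
}

#' Half-open interval overlap
#'
#' @param a,b [genomic_interval()]s.
#' @return `TRUE` iff the intervals share a chromosome and
#'   `a$start < b$end && b$start < a$end`.
#' @export
overlaps <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# vectorized half-open overlap of (start,end) columns against one interval
.overlaps_vec <- function(chrom, start, end, iv) {
  chrom == iv$chrom & start < iv$end & iv$start < end
}

#' Genes within the eQTL mapping window of a lead SNP
#'
#' Membership is by TSS distance: a gene qualifies when its TSS lies within
#' `window_bp` of the lead position (inclusive) on the same chromosome —
#' the 1 Mb-either-side-of-TSS mapping-window convention, with gene-body
#' overlap deliberately not used.
#'
#' @param lead A [snp_record()].
#' @param genes Validated gene data.frame (with `tss`).
#' @param window_bp Window half-width in bp, default 1e6.
#' @return The qualifying rows of `genes`.
#' @export
window_genes <- function(lead, genes, window_bp = 1e6) {
  stopifnot(window_bp > 0)
  keep <- genes$chrom == lead$chrom & abs(genes$tss - lead$pos) <= window_bp
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes recruited through chromosomal interactions
#'
#' For each interaction with at least one anchor overlapping the LD-region
#' span, genes whose interval overlaps the *other* anchor are recruited; when
#' both anchors overlap the region, genes under either anchor qualify.
#' Recruitment is restricted to the region's chromosome and the result is
#' de-duplicated.
#'
#' @param region An `ld_region`.
#' @param interactions Validated interactions data.frame.
#' @param genes Validated gene data.frame.
#' @return The recruited rows of `genes`.
#' @export
interaction_genes <- function(region, interactions, genes) {
  stopifnot(inherits(region, "ld_region"))
  span <- region$span
  hit <- logical(nrow(genes))
  if (nrow(interactions)) {
    a_in <- .overlaps_vec(interactions$chrom_a, interactions$start_a,
                          interactions$end_a, span)
    b_in <- .overlaps_vec(interactions$chrom_b, interactions$start_b,
                          interactions$end_b, span)
    for (i in which(a_in | b_in)) {
      take_b <- a_in[i]
      take_a <- b_in[i]
      if (take_b && interactions$chrom_b[i] == span$chrom) {
        iv <- genomic_interval(interactions$chrom_b[i],
                               interactions$start_b[i], interactions$end_b[i])
        hit <- hit | .overlaps_vec(genes$chrom, genes$start, genes$end, iv)
      }
      if (take_a && interactions$chrom_a[i] == span$chrom) {
        iv <- genomic_interval(interactions$chrom_a[i],
                               interactions$start_a[i], interactions$end_a[i])
        hit <- hit | .overlaps_vec(genes$chrom, genes$start, genes$end, iv)
      }
    }
  }
  out <- genes[hit & genes$chrom == span$chrom, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expanded candidate-gene set with provenance
#'
#' Union of [window_genes()] (relative to the region's lead) and
#' [interaction_genes()], each gene tagged `window`, `interaction` or `both`,
#' ordered by gene start then id.
#'
#' @param region An `ld_region`.
#' @param genes Validated gene data.frame.
#' @param interactions Validated interactions data.frame.
#' @param window_bp Mapping-window half-width, default 1e6.
#' @return Data.frame of candidate genes with a `provenance` column.
#' @export
candidate_genes <- function(region, genes, interactions, window_bp = 1e6) {
  wg <- window_genes(region$lead, genes, window_bp)
  ig <- interaction_genes(region, interactions, genes)
  ids <- union(wg$gene_id, ig$gene_id)
  out <- genes[match(ids, genes$gene_id), , drop = FALSE]
  out$provenance <- ifelse(
    out$gene_id %in% wg$gene_id & out$gene_id %in% ig$gene_id, "both",
    ifelse(out$gene_id %in% wg$gene_id, "window", "interaction"))
  out <- out[order(out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segmentation records overlapping an LD region
#'
#' @param region An `ld_region`.
#' @param segs Validated segmentation data.frame.
#' @return Named list, one element per epigenome_id present in the overlap,
#'   each the overlapping rows in their original file order.
#' @export
query_segmentations <- function(region, segs) {
  stopifnot(inherits(region, "ld_region"))
  keep <- segs[.overlaps_vec(segs$chrom, segs$start, segs$end, region$span), ,
               drop = FALSE]
  if (!nrow(keep)) return(stats::setNames(list(), character(0)))
  split(keep, factor(keep$epigenome_id, levels = unique(keep$epigenome_id)))
}
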