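# Domain types shared across the pipeline.
#
# Tabular record collections (proxies, genes, segmentations, interactions,
# QTL compendia, association summary statistics) are plain data.frames with a
# fixed column contract, validated at construction; composite results
# (ld_region, gap_curve, module_partition, coloc_result, summary_bundle) are
# lightweight S3 lists. All intervals are stored 0-based half-open internally
# (BED convention); SNP positions and TSSs are 1-based, as in source files.

#' Construct a genomic interval (0-based half-open)
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start (non-negative integer).
#' @param end Exclusive end; must satisfy `end > start`.
#' @return A list of class `genomic_interval` with fields `chrom`, `start`,
#'   `end`.
#' @export
#' @examples
#' genomic_interval("chr5", 96875938, 96875939)
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0)
    stop("interval coordinates must be non-negative numbers")
  if (end <= start)
    stop(sprintf("invalid interval [%s,%s): end must exceed start", start, end))
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d>\n", x$chrom, x$start, x$end))
  invisible(x)
}

#' Construct a SNP record
#'
#' @param rsid rsID string.
#' @param chrom Chromosome name.
#' @param pos 1-based position (>= 1).
#' @param ref_allele,alt_allele Optional allele strings.
#' @return A list of class `snp_record`.
#' @export
snp_record <- function(rsid, chrom, pos, ref_allele = NA_character_,
                       alt_allele = NA_character_) {
  if (!grepl("^rs[0-9]+$", rsid)) stop(sprintf("not an rsID: '%s'", rsid))
  pos <- as.numeric(pos)
  if (is.na(pos) || pos < 1) stop("SNP position must be >= 1")
  structure(list(rsid = rsid, chrom = chrom, pos = pos,
                 ref_allele = ref_allele, alt_allele = alt_allele),
            class = "snp_record")
}

# ---- tabular record validators ------------------------------------------

# Each validator checks required columns exist and row-level invariants hold,
# reporting the offending column or row as the spec's error contract asks.

.required_cols <- list(
  proxies       = c("lead_rsid", "proxy_rsid", "chrom", "pos", "r2"),
  genes         = c("gene_id", "symbol", "chrom", "start", "end", "strand"),
  segmentation  = c("chrom", "start", "end", "state", "epigenome_id"),
  interactions  = c("chrom_a", "start_a", "end_a",
                    "chrom_b", "start_b", "end_b", "tissue"),
  qtl           = c("qtl_class", "rsid", "target", "p_value",
                    "tissue_or_source"),
  summary_stats = c("rsid", "chrom", "pos", "beta", "varbeta")
)

.qtl_classes <- c("pQTL", "lQTL", "sQTL", "meQTL", "miQTL", "mQTL", "eQTL")

#' Chromatin-state vocabulary (Roadmap 15-state core model)
#'
#' The 15 chromatin-state labels used to validate segmentation records.
#' @return Character vector of 15 state labels.
#' @export
chromatin_states <- function() {
  c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG", "7_Enh",
    "8_ZNF/Rpts", "9_Het", "10_TssBiv", "11_BivFlnk", "12_EnhBiv",
    "13_ReprPC", "14_ReprPCWk", "15_Quies")
}

.check_cols <- function(df, schema) {
  need <- .required_cols[[schema]]
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("schema '%s': missing required column '%s'",
                 schema, missing[[1L]]))
  invisible(df)
}

.row_fail <- function(schema, rows, what) {
  stop(sprintf("schema '%s': %s (row %s)", schema, what,
               paste(utils::head(rows, 5L), collapse = ", ")))
}

validate_records <- function(df, schema) {
  .check_cols(df, schema)
  bad <- function(cond, what) if (any(cond)) .row_fail(schema, which(cond), what)
  switch(schema,
    proxies = {
      bad(!is.finite(df$r2) | df$r2 < 0 | df$r2 > 1, "r2 outside [0,1]")
      bad(df$pos < 1, "position must be >= 1")
    },
    genes = {
      bad(df$end <= df$start, "end must exceed start")
      bad(df$start < 0, "negative coordinate")
      bad(!df$strand %in% c("+", "-"), "strand must be '+' or '-'")
      if (anyDuplicated(df$gene_id))
        .row_fail(schema, which(duplicated(df$gene_id)), "duplicate gene_id")
      if (!"tss" %in% names(df)) {
        # strand decides which interval end carries the TSS (1-based)
        df$tss <- ifelse(df$strand == "+", df$start + 1, df$end)
      } else {
        bad(df$tss < df$start + 1 | df$tss > df$end,
            "tss outside gene interval")
      }
    },
    segmentation = {
      bad(df$end <= df$start, "end must exceed start")
      bad(df$start < 0, "negative coordinate")
      bad(!df$state %in% chromatin_states(), "unknown chromatin state")
      # non-overlap within an epigenome
      for (ep in unique(df$epigenome_id)) {
        sub <- df[df$epigenome_id == ep, , drop = FALSE]
        for (ch in unique(sub$chrom)) {
          s <- sub[sub$chrom == ch, , drop = FALSE]
          o <- order(s$start)
          if (any(s$start[o][-1L] < s$end[o][-nrow(s)]))
            stop(sprintf(
              "schema 'segmentation': overlapping intervals in epigenome %s", ep))
        }
      }
    },
    interactions = {
      bad(df$end_a <= df$start_a | df$end_b <= df$start_b,
          "anchor end must exceed start")
      bad(df$start_a < 0 | df$start_b < 0, "negative coordinate")
    },
    qtl = {
      bad(!df$qtl_class %in% .qtl_classes, "unknown qtl_class")
      bad(!is.finite(df$p_value) | df$p_value <= 0 | df$p_value > 1,
          "p_value outside (0,1]")
    },
    summary_stats = {
      bad(!is.finite(df$varbeta) | df$varbeta <= 0, "varbeta must be > 0")
      if (anyDuplicated(df$rsid))
        .row_fail(schema, which(duplicated(df$rsid)), "duplicate rsid")
    },
    stop(sprintf("unknown schema '%s'", schema))
  )
  df
}

#' Construct an expression matrix container
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). TPM-scale, non-negative;
#'   `NA` marks missing cells.
#' @param tissue Tissue label.
#' @return The matrix with class `expression_matrix` and a `tissue` attribute.
#' @export
expression_matrix <- function(values, tissue = "tissue") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (any(values < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  structure(values, tissue = tissue, class = c("expression_matrix", "matrix"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, tissue '%s', %d missing\n",
              nrow(x), ncol(x), attr(x, "tissue"), sum(is.na(x))))
  invisible(x)
}

#' Construct a pathway collection
#'
#' @param pathways Named list: pathway id -> character vector of member genes.
#' @param names_ Optional named character vector of display names (defaults to
#'   the ids).
#' @return A list of class `pathway_collection` with elements `members` and
#'   `names`.
#' @export
pathway_collection <- function(pathways, names_ = NULL) {
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)))
    stop("pathway ids must be unique and named")
  if (any(lengths(pathways) == 0L)) stop("pathway member sets must be non-empty")
  members <- lapply(pathways, function(g) unique(as.character(g)))
  if (is.null(names_)) names_ <- stats::setNames(names(members), names(members))
  structure(list(members = members, names = names_),
            class = "pathway_collection")
}

#' Assemble a per-trait association statistics container
#'
#' @param trait_id Trait label.
#' @param df Data.frame with columns rsid, chrom, pos, beta, varbeta.
#' @return Data.frame of class `assoc_stats` with a `trait_id` attribute.
#' @export
assoc_stats <- function(trait_id, df) {
  df <- validate_records(as.data.frame(df), "summary_stats")
  structure(df, trait_id = trait_id,
            class = c("assoc_stats", "data.frame"))
}
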