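# Readers and writers for every external file format the pipeline touches:
# SNP lists, typed TSVs, segmentation BED, expression TSV, GMT pathway sets,
# genotype dosage TSV, and the per-SNP JSON summary bundle.

#' Read a lead-SNP list
#'
#' One rsID per line; order preserved, duplicates collapsed to the first
#' occurrence. Any token that is not `rs` followed by digits is rejected with
#' the offending line number.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of rsIDs.
#' @export
read_snp_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("no SNPs in '%s'", path))
  bad <- which(!grepl("^rs[0-9]+$", lines))
  if (length(bad))
    stop(sprintf("malformed SNP id '%s' at line %d of '%s'",
                 lines[bad[1L]], bad[1L], path))
  unique(lines)
}

# column classes per schema so read errors surface as type failures
.schema_classes <- list(
  proxies       = c(lead_rsid = "character", proxy_rsid = "character",
                    chrom = "character", pos = "numeric", r2 = "numeric"),
  genes         = c(gene_id = "character", symbol = "character",
                    chrom = "character", start = "numeric", end = "numeric",
                    strand = "character"),
  segmentation  = c(chrom = "character", start = "numeric", end = "numeric",
                    state = "character", epigenome_id = "character"),
  interactions  = c(chrom_a = "character", start_a = "numeric",
                    end_a = "numeric", chrom_b = "character",
                    start_b = "numeric", end_b = "numeric",
                    tissue = "character"),
  qtl           = c(qtl_class = "character", rsid = "character",
                    target = "character", p_value = "numeric",
                    tissue_or_source = "character"),
  summary_stats = c(rsid = "character", chrom = "character", pos = "numeric",
                    beta = "numeric", varbeta = "numeric")
)

#' Read a typed record table
#'
#' Tab-separated file with a header naming at least the schema's required
#' columns. The segmentation schema additionally accepts headerless
#' five-column BED (`chrom start end state epigenome_id`). Rows are
#' materialized as validated records; invariant violations report the row.
#'
#' @param path File path.
#' @param schema One of `"proxies"`, `"genes"`, `"segmentation"`,
#'   `"interactions"`, `"qtl"`, `"summary_stats"`.
#' @return A validated data.frame (genes gain a `tss` column when absent,
#'   derived from strand).
#' @export
read_table_records <- function(path,
                               schema = c("proxies", "genes", "segmentation",
                                          "interactions", "qtl",
                                          "summary_stats")) {
  schema <- match.arg(schema)
  first <- readLines(path, n = 1L, warn = FALSE)
  header <- TRUE
  if (schema == "segmentation" &&
      !grepl("^chrom\\b", first) && !grepl("^#", first)) {
    header <- FALSE
  }
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if (!header) {
    if (ncol(df) < 5L)
      stop(sprintf("segmentation BED '%s' needs 5 columns", path))
    names(df)[1:5] <- .required_cols$segmentation
  }
  .check_cols(df, schema)
  validate_records(df, schema)
}

#' Read a tissue expression matrix
#'
#' TSV with gene ids in the first column and one column per sample. Missing
#' values must be encoded as the literal token `NA`; they are flagged, never
#' zeroed. Negative or non-numeric cells are rejected.
#'
#' @param path File path.
#' @param tissue Tissue label attached to the result (defaults to the file
#'   name without extension).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, tissue = NULL) {
  if (is.null(tissue))
    tissue <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop(sprintf("expression file '%s' has no sample columns", path))
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene id '%s' in '%s'",
                 genes[duplicated(genes)][1L], path))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(vals) & !(raw == "NA" | raw == ""))
  if (length(bad))
    stop(sprintf("non-numeric expression cell '%s' in '%s'", raw[bad[1L]], path))
  if (any(vals < 0, na.rm = TRUE))
    stop(sprintf("negative expression value in '%s' (TPM must be non-negative)",
                 path))
  dimnames(vals) <- list(genes, colnames(raw))
  expression_matrix(vals, tissue = tissue)
}

#' Read a GMT pathway file
#'
#' Standard GMT dialect: pathway id, description, then member genes, all
#' tab-separated. Members are de-duplicated; duplicate pathway ids and lines
#' with fewer than three fields are errors.
#'
#' @param path File path.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty GMT file '%s'", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d of '%s' has fewer than 3 fields",
                 short[1L], path))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate pathway id '%s' in '%s'",
                 ids[duplicated(ids)][1L], path))
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  descr <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  pathway_collection(members, names_ = descr)
}

#' Read a genotype dosage table
#'
#' TSV with column `rsid` followed by one column per sample; dosages must be
#' 0, 1 or 2.
#'
#' @param path File path.
#' @return Numeric matrix, SNPs in rows (rownames = rsids), samples in
#'   columns.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "rsid")
    stop(sprintf("genotype file '%s': first column must be 'rsid'", path))
  if (anyDuplicated(df$rsid)) stop("duplicate rsid in genotype file")
  g <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(g %in% c(0, 1, 2)))
    stop(sprintf("genotype dosages must be 0/1/2 in '%s'", path))
  storage.mode(g) <- "numeric"
  rownames(g) <- df$rsid
  g
}

# ---- summary bundle serialization ---------------------------------------

#' Write a per-SNP summary bundle as JSON
#'
#' One file per lead SNP, named `<rsid>.json`. The bundle aggregates the LD
#' region, candidate genes with provenance, eQTL test results, static-QTL
#' hits, overlapping segmentation states, and recruiting interactions.
#'
#' @param bundle A `summary_bundle` (see [summary_bundle()]).
#' @param dir Writable output directory.
#' @return The path of the written file, invisibly.
#' @seealso [read_bundle()]
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "summary_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop(sprintf("directory '%s' not writable", dir))
  path <- file.path(dir, paste0(bundle$snp$rsid, ".json"))
  payload <- list(
    snp = unclass(bundle$snp),
    region = list(
      lead = unclass(bundle$region$lead),
      proxies = bundle$region$proxies,
      span = unclass(bundle$region$span)
    ),
    candidate_genes = bundle$candidate_genes,
    eqtls = bundle$eqtls,
    static_qtl_hits = bundle$static_qtl_hits,
    segment_states = bundle$segment_states,
    interactions = bundle$interactions
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, na = "null", null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

.as_df <- function(x, template_cols) {
  # jsonlite returns named lists of columns (or empty list); rebuild the
  # data.frame with stable column order and types
  if (is.null(x) || length(x) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(template_cols)), template_cols))
    return(out)
  }
  cols <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Read a per-SNP summary bundle from JSON
#'
#' Inverse of [write_bundle()]: `read_bundle(write_bundle(b, d))` equals `b`
#' field for field.
#'
#' @param path Path to a bundle JSON file.
#' @return A `summary_bundle`.
#' @export
read_bundle <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) stop(sprintf("corrupt bundle file '%s': %s",
                                     path, conditionMessage(e))))
  need <- c("snp", "region", "candidate_genes", "eqtls", "static_qtl_hits",
            "segment_states", "interactions")
  if (!all(need %in% names(payload)))
    stop(sprintf("corrupt bundle file '%s': missing fields", path))
  snp <- do.call(snp_record, payload$snp[c("rsid", "chrom", "pos")])
  snp$ref_allele <- payload$snp$ref_allele %||% NA_character_
  snp$alt_allele <- payload$snp$alt_allele %||% NA_character_
  span <- payload$region$span
  region <- structure(list(
    lead = snp,
    proxies = .coerce_df(payload$region$proxies, .required_cols$proxies),
    span = genomic_interval(span$chrom, span$start, span$end)
  ), class = "ld_region")
  summary_bundle(
    snp = snp, region = region,
    candidate_genes = .coerce_df(payload$candidate_genes,
                                 c("gene_id", "symbol", "chrom", "start",
                                   "end", "strand", "tss", "provenance")),
    eqtls = .coerce_df(payload$eqtls,
                       c("rsid", "gene_id", "tissue", "beta", "se",
                         "p_value", "n")),
    static_qtl_hits = .coerce_df(payload$static_qtl_hits,
                                 c(.required_cols$qtl, "effect", "hit_on")),
    segment_states = .coerce_df(payload$segment_states,
                                .required_cols$segmentation),
    interactions = .coerce_df(payload$interactions,
                              c(.required_cols$interactions, "score"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.coerce_df <- function(x, cols) {
  if (is.null(x) || (is.list(x) && !is.data.frame(x) && length(x) == 0L))
    return(as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols)))
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  df[, intersect(cols, names(df)), drop = FALSE]
}

#' Construct a summary bundle
#'
#' @param snp A [snp_record()].
#' @param region The lead SNP's `ld_region`.
#' @param candidate_genes Data.frame of candidate genes with a `provenance`
#'   column (`window`/`interaction`/`both`).
#' @param eqtls Data.frame of eQTL test results.
#' @param static_qtl_hits Data.frame of static-QTL lookups with a `hit_on`
#'   column (`lead`/`proxy`).
#' @param segment_states Data.frame of overlapping segmentation records.
#' @param interactions Data.frame of interactions touching the region.
#' @return A list of class `summary_bundle`.
#' @export
summary_bundle <- function(snp, region, candidate_genes, eqtls,
                           static_qtl_hits, segment_states, interactions) {
  stopifnot(inherits(snp, "snp_record"), inherits(region, "ld_region"))
  if (region$lead$rsid != snp$rsid)
    stop("bundle region does not reference the bundle's lead SNP")
  structure(list(snp = snp, region = region,
                 candidate_genes = candidate_genes, eqtls = eqtls,
                 static_qtl_hits = static_qtl_hits,
                 segment_states = segment_states,
                 interactions = interactions),
            class = "summary_bundle")
}

#' @export
print.summary_bundle <- function(x, ...) {
  cat(sprintf(
    "summary_bundle %s (%s:%d): %d proxies, %d candidate genes, %d eQTL tests, %d QTL hits\n",
    x$snp$rsid, x$snp$chrom, x$snp$pos, nrow(x$region$proxies),
    nrow(x$candidate_genes), nrow(x$eqtls), nrow(x$static_qtl_hits)))
  invisible(x)
}
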