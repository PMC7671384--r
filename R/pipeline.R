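# Pipeline orchestration: the two-call interface (summarize the per-SNP
# evidence, then analyze modules/enrichment across SNPs), plus single-locus
# colocalization and the static report export. A thin command-line wrapper
# over these functions ships in inst/scripts/locuslens.

#' Assemble a run configuration
#'
#' @param data_dir Directory with the input files (see
#'   [write_fixture_dir()] for the expected layout: `snps.txt`,
#'   `snp_info.tsv`, `proxies.tsv`, `genes.tsv`, `interactions.tsv`,
#'   `segmentation.bed`, `qtls.tsv`, `genotypes.tsv`,
#'   `expression_<tissue>.tsv`, `pathways.gmt`).
#' @param out_dir Output directory.
#' @param tissues Tissue labels to analyze (default: every
#'   `expression_*.tsv` found in `data_dir`).
#' @param r2_threshold LD-region proxy threshold (default 0.80).
#' @param window_bp eQTL mapping-window half-width (default 1e6).
#' @param rho_threshold Co-expression threshold (default 0.90).
#' @param alpha_egene eGene p-value threshold (default 0.05).
#' @param alpha_enrich Enrichment p-value threshold (default 0.05).
#' @param coloc_priors Named list p1, p2, p12, W1, W2.
#' @param gap Named list B, k_max, reference.
#' @param knn_k Imputation neighbours (default 10).
#' @param seed Integer seed for the gap-statistic reference draws.
#' @return List of class `run_config`.
#' @export
run_config <- function(data_dir, out_dir, tissues = NULL,
                       r2_threshold = 0.80, window_bp = 1e6,
                       rho_threshold = 0.90, alpha_egene = 0.05,
                       alpha_enrich = 0.05,
                       coloc_priors = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                                           W1 = 0.0225, W2 = 0.0225),
                       gap = list(B = 50L, k_max = 10L,
                                  reference = "permute"),
                       knn_k = 10L, seed = 1L) {
  if (!dir.exists(data_dir)) stop(sprintf("data_dir '%s' not found", data_dir))
  stopifnot(r2_threshold > 0, r2_threshold <= 1,
            rho_threshold > 0, rho_threshold <= 1,
            alpha_egene > 0, alpha_egene <= 1,
            alpha_enrich > 0, alpha_enrich <= 1)
  if (is.null(tissues)) {
    ef <- list.files(data_dir, pattern = "^expression_.*\\.tsv$")
    tissues <- sub("^expression_(.*)\\.tsv$", "\\1", ef)
  }
  structure(list(data_dir = data_dir, out_dir = out_dir, tissues = tissues,
                 r2_threshold = r2_threshold, window_bp = window_bp,
                 rho_threshold = rho_threshold, alpha_egene = alpha_egene,
                 alpha_enrich = alpha_enrich, coloc_priors = coloc_priors,
                 gap = gap, knn_k = knn_k, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; missing keys fall back to
#' the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

.log_line <- function(cfg, stage, snp, msg) {
  line <- sprintf("[%s] %s %s", stage, snp, msg)
  message(line)
  logf <- file.path(cfg$out_dir, "run.log")
  cat(line, "\n", file = logf, append = TRUE, sep = "")
}

.load_inputs <- function(cfg) {
  dd <- cfg$data_dir
  path <- function(f) file.path(dd, f)
  snp_info <- utils::read.delim(path("snp_info.tsv"),
                                stringsAsFactors = FALSE)
  list(
    snps = read_snp_list(path("snps.txt")),
    snp_info = snp_info,
    proxies = read_table_records(path("proxies.tsv"), "proxies"),
    genes = read_table_records(path("genes.tsv"), "genes"),
    interactions = read_table_records(path("interactions.tsv"),
                                      "interactions"),
    segs = read_table_records(path("segmentation.bed"), "segmentation"),
    qtls = read_table_records(path("qtls.tsv"), "qtl"),
    genotypes = read_genotypes(path("genotypes.tsv"))
  )
}

.load_expression <- function(cfg, tissue) {
  f <- file.path(cfg$data_dir, sprintf("expression_%s.tsv", tissue))
  if (!file.exists(f)) return(NULL)
  knn_impute(read_expression(f, tissue = tissue), k = cfg$knn_k)
}

#' Collect per-SNP evidence into summary bundles
#'
#' For each lead SNP: build the LD region, expand the candidate-gene set,
#' test the lead against every candidate gene in every tissue, look up the
#' static QTL compendium for lead and proxies, query the segmentations, and
#' write one JSON bundle per SNP. SNPs absent from the inputs are skipped
#' with a logged reason; per-SNP failures never abort the batch.
#'
#' @param cfg A [run_config()].
#' @return List: `bundles` (paths), `skipped` (named reasons), `status`
#'   (0 clean, 1 partial, 2 failed).
#' @export
cmd_summarize <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  inp <- .load_inputs(cfg)
  bundle_dir <- file.path(cfg$out_dir, "bundles")
  if (!dir.exists(bundle_dir)) dir.create(bundle_dir)
  expr_by_tissue <- lapply(stats::setNames(cfg$tissues, cfg$tissues),
                           function(ti) .load_expression(cfg, ti))
  bundles <- character(0)
  skipped <- character(0)
  for (rsid in inp$snps) {
    res <- tryCatch({
      info <- inp$snp_info[inp$snp_info$rsid == rsid, , drop = FALSE]
      if (!nrow(info)) stop("rsid absent from snp_info")
      lead <- snp_record(rsid, info$chrom[1L], info$pos[1L])
      region <- build_ld_region(lead, inp$proxies, cfg$r2_threshold)
      cand <- candidate_genes(region, inp$genes, inp$interactions,
                              cfg$window_bp)
      eqtls <- list()
      if (rsid %in% rownames(inp$genotypes)) {
        dos <- inp$genotypes[rsid, ]
        for (ti in names(expr_by_tissue)) {
          ex <- expr_by_tissue[[ti]]
          if (is.null(ex)) next
          for (g in intersect(cand$gene_id, rownames(ex))) {
            r <- tryCatch(test_eqtl(dos, ex[g, ], rsid = rsid,
                                    gene_id = g, tissue = ti),
                          error = function(e) NULL)
            if (!is.null(r)) eqtls[[length(eqtls) + 1L]] <- r
          }
        }
      } else {
        .log_line(cfg, "summarize", rsid,
                  "no genotypes; eQTL tests skipped")
      }
      eqtls <- if (length(eqtls)) do.call(rbind, eqtls) else
        data.frame(rsid = character(0), gene_id = character(0),
                   tissue = character(0), beta = numeric(0),
                   se = numeric(0), p_value = numeric(0), n = integer(0))
      hits <- lookup_static_qtls(rsid, region$proxies$proxy_rsid, inp$qtls)
      seg_hits <- query_segmentations(region, inp$segs)
      seg_df <- if (length(seg_hits)) do.call(rbind, c(seg_hits,
                                                       make.row.names = FALSE))
                else inp$segs[0, , drop = FALSE]
      span <- region$span
      ia <- inp$interactions
      touching <- ia[.overlaps_vec(ia$chrom_a, ia$start_a, ia$end_a, span) |
                     .overlaps_vec(ia$chrom_b, ia$start_b, ia$end_b, span), ,
                     drop = FALSE]
      b <- summary_bundle(lead, region, cand, eqtls, hits, seg_df, touching)
      write_bundle(b, bundle_dir)
    }, error = function(e) structure(conditionMessage(e), class = "skip"))
    if (inherits(res, "skip")) {
      skipped[rsid] <- unclass(res)
      .log_line(cfg, "summarize", rsid, paste("skipped:", res))
    } else {
      bundles <- c(bundles, res)
      .log_line(cfg, "summarize", rsid, "bundle written")
    }
  }
  status <- if (!length(bundles)) 2L else if (length(skipped)) 1L else 0L
  list(bundles = bundles, skipped = skipped, status = status)
}

#' Integrated module and enrichment analysis across SNP bundles
#'
#' Per tissue: pool the bundles' eQTL results, select eGenes, assemble the
#' eGene-anchored co-expression set, cluster, choose the module count by the
#' gap statistic (globalSEmax), apply the eQTL-content and enrichment
#' omission rules, and write module/enrichment tables. Emits a warning (but
#' proceeds) when fewer than 20 SNPs contribute, since module detection is
#' unstable on few loci.
#'
#' @param cfg A [run_config()].
#' @param bundle_dir Directory of bundle JSONs (default
#'   `<out_dir>/bundles`).
#' @return List per tissue: `partition`, `enrichment`; plus
#'   `pathway_by_tissue` and the paths written.
#' @export
cmd_analyze <- function(cfg, bundle_dir = file.path(cfg$out_dir, "bundles")) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  files <- list.files(bundle_dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no bundles found; run cmd_summarize first")
  bundles <- lapply(files, read_bundle)
  if (length(bundles) < 20L)
    warning(sprintf(
      "only %d SNPs contribute; twenty and up is advisable for the integrated analysis",
      length(bundles)))
  pathways <- read_gmt(file.path(cfg$data_dir, "pathways.gmt"))
  all_eqtls <- do.call(rbind, lapply(bundles, `[[`, "eqtls"))
  if (is.null(all_eqtls) || !nrow(all_eqtls) ||
      !any(all_eqtls$p_value <= cfg$alpha_egene))
    stop("nothing to modularize: zero eGenes across bundles")

  out <- list()
  enr_all <- list()
  for (ti in cfg$tissues) {
    ex <- .load_expression(cfg, ti)
    if (is.null(ex)) {
      .log_line(cfg, "analyze", ti, "tissue skipped: no expression file")
      next
    }
    res_ti <- all_eqtls[all_eqtls$tissue == ti, , drop = FALSE]
    if (!nrow(res_ti) || !any(res_ti$p_value <= cfg$alpha_egene)) {
      .log_line(cfg, "analyze", ti, "tissue skipped: no eGenes")
      next
    }
    eg <- select_egenes(res_ti, cfg$alpha_egene)
    geneset <- assemble_geneset(eg$genes, ex, cfg$rho_threshold)
    if (length(geneset) < 3L) {
      .log_line(cfg, "analyze", ti, "tissue skipped: gene set too small")
      next
    }
    cm <- spearman_matrix(ex, geneset)
    tree <- cluster_tree(cm)
    k_max <- min(cfg$gap$k_max, length(geneset) - 1L)
    curve <- gap_statistic(unclass(ex)[geneset, , drop = FALSE], k_max,
                           B = cfg$gap$B, seed = cfg$seed,
                           reference = cfg$gap$reference)
    K <- choose_k_globalSEmax(curve)
    flags <- stats::setNames(geneset %in% eg$genes, geneset)
    part <- cut_and_filter(tree, K, flags, gap_curve = curve)
    enr <- enrich_partition(part, pathways, universe = rownames(ex),
                            tissue = ti)
    part <- omit_unenriched(enr, part, cfg$alpha_enrich)
    enr <- enr[enr$module %in% part$retained, , drop = FALSE]
    mod_df <- data.frame(tissue = ti, gene_id = names(part$assignments),
                         module = unname(part$assignments),
                         is_egene = unname(flags),
                         retained = unname(part$assignments) %in%
                           part$retained,
                         stringsAsFactors = FALSE)
    utils::write.table(mod_df,
                       file.path(cfg$out_dir,
                                 sprintf("modules_%s.tsv", ti)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr,
                       file.path(cfg$out_dir,
                                 sprintf("enrichment_%s.tsv", ti)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .log_line(cfg, "analyze", ti,
              sprintf("K=%d, %d modules retained", part$K,
                      length(part$retained)))
    out[[ti]] <- list(partition = part, enrichment = enr)
    enr_all[[ti]] <- enr
  }
  if (!length(out)) stop("no tissue could be analyzed")
  pbt <- tryCatch(aggregate_across_tissues(enr_all, cfg$alpha_enrich),
                  error = function(e) NULL)
  if (!is.null(pbt) && nrow(pbt))
    utils::write.table(pbt, file.path(cfg$out_dir, "pathway_by_tissue.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  json <- lapply(out, function(o) list(
    K = o$partition$K, retained = o$partition$retained,
    assignments = as.list(o$partition$assignments),
    gap = o$partition$gap_curve$gap, gap_se = o$partition$gap_curve$se,
    enrichment = o$enrichment))
  writeLines(jsonlite::toJSON(list(tissues = json, pathway_by_tissue = pbt),
                              dataframe = "columns", auto_unbox = TRUE,
                              digits = NA, na = "null", pretty = TRUE),
             file.path(cfg$out_dir, "analysis.json"))
  c(out, list(pathway_by_tissue = pbt))
}

#' Colocalization of two traits at a locus
#'
#' @param cfg A [run_config()].
#' @param trait1,trait2 Paths to summary-statistic TSVs (rsid, chrom, pos,
#'   beta, varbeta).
#' @param label Output label (files `coloc_<label>.json` / `.tsv`).
#' @return The [coloc_abf()] result, invisibly.
#' @export
cmd_coloc <- function(cfg, trait1, trait2, label = "locus") {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  t1 <- assoc_stats("trait1", read_table_records(trait1, "summary_stats"))
  t2 <- assoc_stats("trait2", read_table_records(trait2, "summary_stats"))
  pri <- cfg$coloc_priors
  res <- coloc_abf(t1, t2, p1 = pri$p1, p2 = pri$p2, p12 = pri$p12,
                   W1 = pri$W1, W2 = pri$W2)
  track <- data.frame(rsid = res$snps, pos = res$positions,
                      h4_posterior = unname(res$per_snp_h4),
                      stringsAsFactors = FALSE)
  utils::write.table(track,
                     file.path(cfg$out_dir,
                               sprintf("coloc_%s_track.tsv", label)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(
    list(pp = as.list(res$pp), priors = as.list(res$priors),
         W = as.list(res$W), n_snps = res$n_snps, track = track),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(cfg$out_dir, sprintf("coloc_%s.json", label)))
  .log_line(cfg, "coloc", label,
            sprintf("PP4=%.3f over %d SNPs", res$pp["PP4"], res$n_snps))
  invisible(res)
}

# minimal inline SVG scatter of a per-SNP posterior track
.svg_track <- function(track, width = 600, height = 160) {
  if (!nrow(track)) return("")
  pad <- 30
  xs <- pad + (track$pos - min(track$pos)) /
    max(1, diff(range(track$pos))) * (width - 2 * pad)
  ys <- height - pad - track$h4_posterior * (height - 2 * pad)
  pts <- paste(sprintf('<circle cx="%.1f" cy="%.1f" r="3" fill="#4477aa"/>',
                       xs, ys), collapse = "")
  sprintf(paste0(
    '<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
    '<rect width="%d" height="%d" fill="#fafafa"/>',
    '<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="#333"/>%s</svg>'),
    width, height, width, height, pad, height - pad, width - pad,
    height - pad, pts)
}

.html_table <- function(df) {
  if (is.null(df) || !nrow(df)) return("<p>(empty)</p>")
  hdr <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""),
                "</tr>")
  rows <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0('<table border="1" cellpadding="3">', hdr,
         paste(rows, collapse = ""), "</table>")
}

#' Export a static report
#'
#' Self-contained HTML plus a JSON mirror of every table: per-SNP sections
#' (LD region, candidate genes, QTL hits, segmentation states), module and
#' enrichment tables per tissue, the pathway-by-tissue matrix, and any
#' colocalization tracks as inline figures.
#'
#' @param cfg A [run_config()].
#' @return Paths of `report.html` and `report.json`, invisibly.
#' @export
cmd_report <- function(cfg) {
  od <- cfg$out_dir
  bundle_dir <- file.path(od, "bundles")
  bundle_files <- if (dir.exists(bundle_dir))
    list.files(bundle_dir, pattern = "\\.json$", full.names = TRUE)
  else character(0)
  analysis_file <- file.path(od, "analysis.json")
  coloc_files <- list.files(od, pattern = "^coloc_.*\\.json$",
                            full.names = TRUE)
  if (!length(bundle_files) && !file.exists(analysis_file))
    stop("missing outputs: no bundles and no analysis.json; run cmd_summarize/cmd_analyze first")

  report <- list()
  html <- c("<html><head><meta charset='utf-8'><title>locus report</title>",
            "</head><body><h1>Locus interpretation report</h1>")

  if (length(bundle_files)) {
    snps <- list()
    for (f in bundle_files) {
      b <- read_bundle(f)
      snps[[b$snp$rsid]] <- list(
        snp = unclass(b$snp),
        span = unclass(b$region$span),
        n_proxies = nrow(b$region$proxies),
        candidate_genes = b$candidate_genes,
        qtl_hits = b$static_qtl_hits,
        n_segment_states = nrow(b$segment_states))
      html <- c(html,
        sprintf("<h2>%s</h2><p>%s:%d; %d proxies; span %d-%d</p>",
                b$snp$rsid, b$snp$chrom, b$snp$pos, nrow(b$region$proxies),
                b$region$span$start, b$region$span$end),
        "<h3>Candidate genes</h3>", .html_table(b$candidate_genes),
        "<h3>Static QTL hits</h3>", .html_table(b$static_qtl_hits))
    }
    report$snps <- snps
  }

  if (file.exists(analysis_file)) {
    analysis <- jsonlite::fromJSON(analysis_file, simplifyDataFrame = TRUE)
    report$analysis <- analysis
    html <- c(html, "<h2>Modules and enrichment</h2>")
    for (ti in names(analysis$tissues)) {
      a <- analysis$tissues[[ti]]
      html <- c(html, sprintf("<h3>%s (K = %d)</h3>", ti, a$K),
                .html_table(as.data.frame(a$enrichment)))
    }
    pbt <- analysis$pathway_by_tissue
    if (!is.null(pbt) && length(pbt)) {
      html <- c(html, "<h3>Pathway by tissue</h3>",
                .html_table(as.data.frame(pbt)))
    }
  }

  if (length(coloc_files)) {
    report$coloc <- list()
    html <- c(html, "<h2>Colocalization</h2>")
    for (f in coloc_files) {
      cj <- jsonlite::fromJSON(f, simplifyDataFrame = TRUE)
      lab <- sub("^coloc_(.*)\\.json$", "\\1", basename(f))
      report$coloc[[lab]] <- cj
      pp <- unlist(cj$pp)
      html <- c(html,
        sprintf("<h3>%s</h3><p>%s</p>", lab,
                paste(sprintf("%s=%.3f", names(pp), pp), collapse = ", ")),
        .svg_track(as.data.frame(cj$track)))
    }
  }

  html <- c(html, "</body></html>")
  html_path <- file.path(od, "report.html")
  json_path <- file.path(od, "report.json")
  writeLines(paste(html, collapse = "\n"), html_path)
  writeLines(jsonlite::toJSON(report, dataframe = "columns",
                              auto_unbox = TRUE, digits = NA, na = "null",
                              pretty = TRUE), json_path)
  invisible(c(html = html_path, json = json_path))
}
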