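# Seeded synthetic-fixture generators. Every input the pipeline consumes can
# be simulated with planted ground truth: LD-block genotypes (Gaussian copula
# thresholded to dosages), block-correlated expression with planted eQTLs,
# per-trait association summary statistics with configurable causal variants,
# and the annotation layer (genes, interactions, segmentations, pathways,
# proxies). Each generator returns its ground truth alongside the data and is
# byte-deterministic given the config seed.

#' Simulation configuration
#'
#' Defaults describe the study conditions the test-bench emulates: 200 SNPs
#' in LD blocks of 10 with within-block latent correlation 0.8 and per-SNP
#' MAF drawn uniformly in \[0.1, 0.5\]; four co-expression modules of 20
#' genes with within-module correlation 0.9 and independent modules; one
#' planted eQTL (gene 1 on SNP 1, effect 1 per dosage unit); colocalization
#' traits with one causal variant each explaining 5% of phenotypic variance
#' in cohorts of 1000; 5% missing expression cells.
#'
#' @param seed Integer seed; all generators derive their RNG state from it.
#' @param n_samples Expression/genotype cohort size.
#' @param n_snps Number of SNPs.
#' @param ld_block_spec List: `block_size`, `within_rho`, `maf_range`.
#' @param module_spec List: `K`, `genes_per_block`, `within_rho`,
#'   `between_rho`.
#' @param eqtl_spec List: `gene` (index), `snp` (index), `beta`.
#' @param coloc_spec List: `causal1`, `causal2` (SNP indices),
#'   `var_explained`, `n`.
#' @param missing_rate Fraction of expression cells masked as missing.
#' @param pathway_spec List: `overlap` (planted-pathway genes from module 1),
#'   `extra` (members from other modules), `n_background`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 200L,
                       n_snps = 200L,
                       ld_block_spec = list(block_size = 10L,
                                            within_rho = 0.8,
                                            maf_range = c(0.1, 0.5)),
                       module_spec = list(K = 4L, genes_per_block = 20L,
                                          within_rho = 0.9,
                                          between_rho = 0),
                       eqtl_spec = list(gene = 1L, snp = 1L, beta = 1),
                       coloc_spec = list(causal1 = 5L, causal2 = 5L,
                                         var_explained = 0.05, n = 1000L),
                       missing_rate = 0.05,
                       pathway_spec = list(overlap = 15L, extra = 10L,
                                           n_background = 5L)) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            coloc_spec$var_explained >= 0, coloc_spec$var_explained < 1,
            ld_block_spec$within_rho >= 0, ld_block_spec$within_rho <= 1,
            module_spec$within_rho >= 0, module_spec$within_rho <= 1)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps), ld_block_spec = ld_block_spec,
                 module_spec = module_spec, eqtl_spec = eqtl_spec,
                 coloc_spec = coloc_spec, missing_rate = missing_rate,
                 pathway_spec = pathway_spec),
            class = "sim_config")
}

.with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

.snp_ids <- function(n) paste0("rs", 1000L + seq_len(n))
.snp_pos <- function(n) 10000L + (seq_len(n) - 1L) * 2000L
.gene_ids <- function(n) sprintf("G%03d", seq_len(n))

# draw an n x m latent matrix with block-diagonal equicorrelation
.latent_blocks <- function(n, block_sizes, rho) {
  cols <- list()
  for (bi in seq_along(block_sizes)) {
    m <- block_sizes[bi]
    if (rho >= 1 - 1e-12) {
      # degenerate block: all SNPs share one latent variable
      cols[[bi]] <- matrix(stats::rnorm(n), n, m)
      next
    }
    R <- matrix(rho, m, m); diag(R) <- 1
    L <- tryCatch(chol(R), error = function(e)
      stop("infeasible correlation matrix: not positive semi-definite"))
    Z <- matrix(stats::rnorm(n * m), n, m) %*% L
    cols[[bi]] <- Z
  }
  do.call(cbind, cols)
}

.dosage_from_latent <- function(Z, maf) {
  # HWE genotype frequencies via latent-normal thresholds per SNP
  q1 <- stats::qnorm((1 - maf)^2)   # below: 0 copies
  q2 <- stats::qnorm(1 - maf^2)     # above: 2 copies
  D <- sweep(Z, 2, q1, ">") + sweep(Z, 2, q2, ">")
  storage.mode(D) <- "numeric"
  D
}

#' Simulate LD-block genotype dosages
#'
#' Dosages are drawn from a latent Gaussian copula with block-diagonal
#' equicorrelation and thresholded to \{0,1,2\} at Hardy-Weinberg genotype
#' frequencies for per-SNP allele frequencies drawn from the configured
#' range.
#'
#' @param cfg A [sim_config()].
#' @param n Cohort size (default `cfg$n_samples`).
#' @param seed_offset Added to `cfg$seed` so independent cohorts can be drawn
#'   from the same LD structure.
#' @return List: `dosages` (SNP x sample matrix, rownames rsids), `maf`,
#'   `target_r2` (latent rho squared), `realized_r2`, `blocks` (block index
#'   per SNP).
#' @export
simulate_genotypes <- function(cfg, n = cfg$n_samples, seed_offset = 101L) {
  m <- cfg$n_snps
  bs <- cfg$ld_block_spec$block_size
  n_blocks <- ceiling(m / bs)
  block_sizes <- rep(bs, n_blocks)
  block_sizes[n_blocks] <- m - bs * (n_blocks - 1L)
  blocks <- rep(seq_len(n_blocks), block_sizes)
  rho <- cfg$ld_block_spec$within_rho
  .with_seed(cfg$seed + seed_offset, {
    maf <- stats::runif(m, cfg$ld_block_spec$maf_range[1],
                        cfg$ld_block_spec$maf_range[2])
    Z <- .latent_blocks(n, block_sizes, rho)
    D <- .dosage_from_latent(Z, maf)
    target <- outer(blocks, blocks, "==") * rho^2
    diag(target) <- 1
    realized <- suppressWarnings(stats::cor(D))^2
    dos <- t(D)
    rownames(dos) <- .snp_ids(m)
    colnames(dos) <- sprintf("S%04d", seq_len(n))
    list(dosages = dos, maf = maf, target_r2 = target,
         realized_r2 = realized, blocks = blocks)
  })
}

#' Simulate block-correlated expression with planted eQTLs
#'
#' Genes load on one latent factor each (`K` factors, within-module
#' correlation as configured); configured eQTL genes add `beta * dosage` of
#' their SNP. Values are mapped to a TPM-like non-negative scale by a
#' monotone affine transform (downstream Spearman-based stages are invariant
#' to it) and cells are masked missing at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()] on the same cohort.
#' @param tissue Tissue label.
#' @param seed_offset RNG offset (distinct tissues get distinct offsets).
#' @return List: `expr` (an [expression_matrix()], possibly with missing
#'   cells), `truth` (module label per gene, eQTL gene/SNP ids).
#' @export
simulate_expression <- function(cfg, genotypes, tissue = "tissueA",
                                seed_offset = 202L) {
  K <- cfg$module_spec$K
  gpb <- cfg$module_spec$genes_per_block
  n_genes <- K * gpb
  n <- ncol(genotypes$dosages)
  w <- cfg$module_spec$within_rho
  bw <- cfg$module_spec$between_rho
  .with_seed(cfg$seed + seed_offset, {
    # factors with optional equicorrelation bw between modules
    Fm <- matrix(stats::rnorm(n * K), n, K)
    if (bw > 0) {
      shared <- stats::rnorm(n)
      Fm <- sqrt(bw) * shared + sqrt(1 - bw) * Fm
    }
    labels <- rep(seq_len(K), each = gpb)
    X <- sqrt(w) * t(Fm[, labels]) +
      sqrt(1 - w) * matrix(stats::rnorm(n_genes * n), n_genes, n)
    eq <- cfg$eqtl_spec
    eq_genes <- .gene_ids(n_genes)[eq$gene]
    eq_snps <- rownames(genotypes$dosages)[eq$snp]
    for (i in seq_along(eq$gene)) {
      X[eq$gene[i], ] <- X[eq$gene[i], ] +
        eq$beta[min(i, length(eq$beta))] * genotypes$dosages[eq$snp[i], ]
    }
    vals <- 100 + 10 * X
    if (min(vals) < 0) vals <- vals - min(vals)
    dimnames(vals) <- list(.gene_ids(n_genes), colnames(genotypes$dosages))
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(length(vals)) < cfg$missing_rate,
                     nrow(vals), ncol(vals))
      # keep at least one observed value per gene
      for (i in which(rowSums(!mask) == 0L)) mask[i, 1L] <- FALSE
      vals[mask] <- NA_real_
    }
    list(expr = expression_matrix(vals, tissue = tissue),
         truth = list(module = stats::setNames(labels, rownames(vals)),
                      eqtl_genes = eq_genes, eqtl_snps = eq_snps))
  })
}

#' Simulate per-trait association summary statistics
#'
#' For each trait an independent cohort is drawn from the configured LD
#' structure; the phenotype is `b * dosage(causal) + N(0,1)` with `b` set so
#' the causal variant explains `var_explained` of the phenotypic variance.
#' Marginal per-SNP OLS effect estimates and their variances form the
#' summary statistics.
#'
#' @param cfg A [sim_config()].
#' @return List: `t1`, `t2` ([assoc_stats()]), `truth` (causal rsids).
#' @export
simulate_summary_stats <- function(cfg) {
  make_trait <- function(trait_id, causal_idx, offset) {
    geno <- simulate_genotypes(cfg, n = cfg$coloc_spec$n, seed_offset = offset)
    G <- t(geno$dosages)  # samples x snps
    ve <- cfg$coloc_spec$var_explained
    g <- G[, causal_idx]
    vg <- stats::var(g)
    b <- if (ve > 0 && vg > 0) sqrt(ve / (1 - ve) / vg) else 0
    y <- .with_seed(cfg$seed + offset + 7L,
                    b * g + stats::rnorm(nrow(G)))
    keep <- apply(G, 2L, stats::var) > 0
    fit <- .marginal_ols(G[, keep, drop = FALSE], y)
    df <- data.frame(rsid = .snp_ids(cfg$n_snps)[keep],
                     chrom = "chr1", pos = .snp_pos(cfg$n_snps)[keep],
                     beta = fit$beta, varbeta = fit$varbeta,
                     stringsAsFactors = FALSE)
    assoc_stats(trait_id, df)
  }
  t1 <- make_trait("trait1", cfg$coloc_spec$causal1, 303L)
  t2 <- make_trait("trait2", cfg$coloc_spec$causal2, 304L)
  list(t1 = t1, t2 = t2,
       truth = list(causal1 = .snp_ids(cfg$n_snps)[cfg$coloc_spec$causal1],
                    causal2 = .snp_ids(cfg$n_snps)[cfg$coloc_spec$causal2]))
}

#' Simulate the annotation layer
#'
#' Genes are tiled on one chromosome around the lead SNP; the last expression
#' gene is planted more than 1 Mb away and linked back to the LD region by a
#' single chromosomal interaction, so it is recoverable only through
#' interaction-based recruitment. A 15-state segmentation tiles the region
#' without gaps for three epigenomes; the proxies table is derived from the
#' realized genotype r2 against the lead; the GMT contains one pathway
#' overlapping planted module 1 plus random background pathways; a static QTL
#' table carries one pQTL hit on the lead and one meQTL hit on a proxy.
#'
#' @param cfg A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()].
#' @return List: `lead` ([snp_record()]), `genes`, `proxies`,
#'   `interactions`, `segmentations`, `qtls` (data.frames), `pathways`
#'   ([pathway_collection()]), `truth` (distal gene id, planted pathway id).
#' @export
simulate_annotation <- function(cfg, genotypes) {
  m <- cfg$n_snps
  rsids <- .snp_ids(m)
  pos <- .snp_pos(m)
  lead_idx <- cfg$eqtl_spec$snp[1L]
  lead <- snp_record(rsids[lead_idx], "chr1", pos[lead_idx])
  n_genes <- cfg$module_spec$K * cfg$module_spec$genes_per_block
  gids <- .gene_ids(n_genes)

  .with_seed(cfg$seed + 405L, {
    # proximal genes: TSS within +/- 0.9 Mb of the lead; distal gene at
    # lead + 2 Mb, outside any mapping window
    tss <- round(seq(max(1, lead$pos - 9e5), lead$pos + 9e5,
                     length.out = n_genes - 1L))
    tss <- c(tss, lead$pos + 2e6)
    starts <- pmax(0, tss - 1L)           # '+' strand: tss = start + 1
    genes <- data.frame(gene_id = gids, symbol = toupper(gids),
                        chrom = "chr1", start = starts,
                        end = starts + 10000L, strand = "+",
                        tss = tss, stringsAsFactors = FALSE)
    genes <- validate_records(genes, "genes")
    distal <- gids[n_genes]

    # one interaction linking the LD region to the distal gene
    block <- genotypes$blocks == genotypes$blocks[lead_idx]
    block_pos <- pos[block]
    interactions <- data.frame(
      chrom_a = "chr1", start_a = min(block_pos) - 1L,
      end_a = max(block_pos) + 1L,
      chrom_b = "chr1", start_b = genes$start[n_genes],
      end_b = genes$end[n_genes],
      tissue = "tissueA", score = 0.9, stringsAsFactors = FALSE)
    interactions <- validate_records(interactions, "interactions")

    # proxies from realized r2 against the lead (same chromosome)
    r2 <- genotypes$realized_r2[lead_idx, ]
    others <- setdiff(seq_len(m), lead_idx)
    proxies <- data.frame(lead_rsid = lead$rsid, proxy_rsid = rsids[others],
                          chrom = "chr1", pos = pos[others],
                          r2 = pmin(pmax(r2[others], 0), 1),
                          stringsAsFactors = FALSE)
    proxies <- proxies[is.finite(proxies$r2), , drop = FALSE]
    rownames(proxies) <- NULL
    proxies <- validate_records(proxies, "proxies")

    # 15-state tiling across the locus, 3 epigenomes, no gaps
    states <- chromatin_states()
    tile <- 2000L
    lo <- max(0L, lead$pos - 20000L); hi <- lead$pos + 40000L
    tile_starts <- seq(lo, hi, by = tile)
    segs <- do.call(rbind, lapply(sprintf("E%03d", 1:3), function(ep) {
      data.frame(chrom = "chr1", start = tile_starts,
                 end = tile_starts + tile,
                 state = states[(seq_along(tile_starts) +
                                   match(ep, sprintf("E%03d", 1:3))) %%
                                  15L + 1L],
                 epigenome_id = ep, stringsAsFactors = FALSE)
    }))
    segs <- validate_records(segs, "segmentation")

    # planted pathway: overlap genes from module 1 plus members from others
    ps <- cfg$pathway_spec
    module1 <- gids[seq_len(cfg$module_spec$genes_per_block)]
    planted <- c(module1[seq_len(min(ps$overlap, length(module1)))],
                 sample(setdiff(gids, module1), ps$extra))
    pw <- list(PW_PLANTED = planted)
    for (i in seq_len(ps$n_background)) {
      pw[[sprintf("PW_BG%02d", i)]] <- sample(gids, sample(10:20, 1L))
    }
    pathways <- pathway_collection(pw)

    # static QTL compendium: pQTL on the lead, meQTL on its strongest proxy
    top_proxy <- proxies$proxy_rsid[which.max(proxies$r2)]
    qtls <- data.frame(
      qtl_class = c("pQTL", "meQTL"),
      rsid = c(lead$rsid, top_proxy),
      target = c("PROT_A", "cg0001"),
      effect = c(0.8, -0.3),
      p_value = c(1e-6, 1e-4),
      tissue_or_source = c("plasma", "whole_blood"),
      stringsAsFactors = FALSE)
    qtls <- validate_records(qtls, "qtl")

    list(lead = lead, genes = genes, proxies = proxies,
         interactions = interactions, segmentations = segs, qtls = qtls,
         pathways = pathways,
         truth = list(distal_gene = distal, planted_pathway = "PW_PLANTED",
                      lead_rsid = lead$rsid))
  })
}

#' Write a complete fixture directory
#'
#' Materializes every pipeline input as files: `snps.txt`, `snp_info.tsv`
#' (rsid, chrom, pos for every simulated SNP), `proxies.tsv`,
#' `genes.tsv`, `interactions.tsv`, `segmentation.bed`, `qtls.tsv`,
#' `genotypes.tsv`, `expression_<tissue>.tsv` per tissue, `pathways.gmt`,
#' `trait1.tsv`/`trait2.tsv` summary statistics, and `truth.json` with all
#' planted ground truth.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param tissues Tissue labels; each gets an independent expression draw.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(cfg, dir, tissues = "tissueA") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  geno <- simulate_genotypes(cfg)
  ann <- simulate_annotation(cfg, geno)
  ss <- simulate_summary_stats(cfg)

  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(ann$lead$rsid, file.path(dir, "snps.txt"))
  wt(data.frame(rsid = .snp_ids(cfg$n_snps), chrom = "chr1",
                pos = .snp_pos(cfg$n_snps), stringsAsFactors = FALSE),
     "snp_info.tsv")
  wt(ann$proxies, "proxies.tsv")
  wt(ann$genes, "genes.tsv")
  wt(ann$interactions, "interactions.tsv")
  utils::write.table(ann$segmentations, file.path(dir, "segmentation.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  wt(ann$qtls, "qtls.tsv")
  gdf <- data.frame(rsid = rownames(geno$dosages), geno$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  wt(gdf, "genotypes.tsv")

  truth_expr <- list()
  for (ti in seq_along(tissues)) {
    sim <- simulate_expression(cfg, geno, tissue = tissues[ti],
                               seed_offset = 202L + ti)
    edf <- data.frame(gene_id = rownames(sim$expr),
                      unclass(sim$expr), check.names = FALSE,
                      stringsAsFactors = FALSE)
    wt(edf, sprintf("expression_%s.tsv", tissues[ti]))
    truth_expr[[tissues[ti]]] <- sim$truth
  }

  gmt <- vapply(names(ann$pathways$members), function(pid) {
    paste(c(pid, ann$pathways$names[pid], ann$pathways$members[[pid]]),
          collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "pathways.gmt"))

  wt(as.data.frame(ss$t1), "trait1.tsv")
  wt(as.data.frame(ss$t2), "trait2.tsv")

  truth <- list(annotation = ann$truth, expression = truth_expr,
                coloc = ss$truth, seed = cfg$seed)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}
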