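# LD-region construction and candidate-gene search-space expansion.

mk_genes <- function(...) {
  g <- data.frame(..., stringsAsFactors = FALSE)
  validate_records(g, "genes")
}

test_that("compute_r2 matches direct Pearson arithmetic and its invariants", {
  expect_equal(compute_r2(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0)), 1)
  expect_equal(compute_r2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)

  a <- c(0, 1, 2, 0, 1, 2); b <- c(0, 1, 1, 0, 2, 2)
  expect_equal(compute_r2(a, b), oracle_pearson(a, b)^2, tolerance = 1e-12)

  # symmetry, allele-flip invariance, bounds on random dosages
  set.seed(11)
  for (i in 1:20) {
    x <- sample(0:2, 30, replace = TRUE)
    y <- sample(0:2, 30, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    r2 <- compute_r2(x, y)
    expect_equal(r2, compute_r2(y, x))
    expect_equal(r2, compute_r2(2 - x, y), tolerance = 1e-12)
    expect_gte(r2, 0); expect_lte(r2, 1)
  }

  expect_error(compute_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_error(compute_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("LD regions keep proxies at the inclusive 0.80 threshold", {
  lead <- snp_record("rs1", "chr1", 100)
  px <- data.frame(lead_rsid = "rs1", proxy_rsid = c("rs2", "rs3", "rs4"),
                   chrom = "chr1", pos = c(90, 110, 120),
                   r2 = c(0.85, 0.80, 0.79), stringsAsFactors = FALSE)
  reg <- build_ld_region(lead, px)
  expect_equal(nrow(reg$proxies), 2L)
  expect_setequal(reg$proxies$proxy_rsid, c("rs2", "rs3"))
})

test_that("LD-region span is min/max over lead and qualifying proxies", {
  lead <- snp_record("rs1", "chr1", 100)
  px <- data.frame(lead_rsid = "rs1", proxy_rsid = c("rs2", "rs3"),
                   chrom = "chr1", pos = c(50, 200), r2 = c(0.9, 0.9),
                   stringsAsFactors = FALSE)
  reg <- build_ld_region(lead, px)
  expect_equal(reg$span$start, 49)
  expect_equal(reg$span$end, 200)

  solo <- build_ld_region(lead, NULL)
  expect_equal(solo$span$end - solo$span$start, 1)
  expect_equal(solo$span$start, 99)

  off <- px; off$chrom <- c("chr1", "chr2")
  expect_error(build_ld_region(lead, off), "chromosome")
})

test_that("lowering the r2 threshold never shrinks proxies or span", {
  set.seed(5)
  lead <- snp_record("rs1", "chr1", 5000)
  px <- data.frame(lead_rsid = "rs1",
                   proxy_rsid = paste0("rs", 2:41), chrom = "chr1",
                   pos = sample(1000:9000, 40), r2 = runif(40),
                   stringsAsFactors = FALSE)
  thresholds <- sort(runif(8, 0.1, 1), decreasing = TRUE)
  prev <- build_ld_region(lead, px, thresholds[1])
  for (thr in thresholds[-1]) {
    cur <- build_ld_region(lead, px, thr)
    expect_gte(nrow(cur$proxies), nrow(prev$proxies))
    expect_lte(cur$span$start, prev$span$start)
    expect_gte(cur$span$end, prev$span$end)
    expect_true(all(prev$proxies$proxy_rsid %in% cur$proxies$proxy_rsid))
    prev <- cur
  }
})

test_that("interval overlap uses half-open semantics", {
  i1 <- genomic_interval("chr1", 0, 10)
  expect_false(overlaps(i1, genomic_interval("chr1", 10, 20)))
  expect_true(overlaps(i1, genomic_interval("chr1", 9, 20)))
  expect_false(overlaps(i1, genomic_interval("chr2", 0, 10)))
})

test_that("window membership is by inclusive TSS distance on one chromosome", {
  lead <- snp_record("rs1", "chr1", 5e6)
  genes <- mk_genes(gene_id = c("gA", "gB", "gC"),
                    symbol = c("A", "B", "C"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(5e6 + 1e6 - 1, 5e6 + 1e6, 5e6 - 1),
                    end = c(5e6 + 1e6 + 1e4, 5e6 + 1e6 + 1e4, 5e6 + 1e4),
                    strand = "+")
  # '+' strand: tss = start + 1 -> gA at exactly +1 Mb, gB at +1 Mb + 1
  got <- window_genes(lead, genes)
  expect_equal(got$gene_id, "gA")
})

test_that("interaction recruitment follows the anchors and the chromosome", {
  lead <- snp_record("rs1", "chr1", 1000)
  px <- data.frame(lead_rsid = "rs1", proxy_rsid = "rs2", chrom = "chr1",
                   pos = 2000, r2 = 0.9, stringsAsFactors = FALSE)
  reg <- build_ld_region(lead, px)  # span [999, 2000)
  genes <- mk_genes(gene_id = c("gDist", "gOther"),
                    symbol = c("D", "O"),
                    chrom = c("chr1", "chr2"),
                    start = c(5e6, 5e6), end = c(5e6 + 1e4, 5e6 + 1e4),
                    strand = "+")
  ia_same <- data.frame(chrom_a = "chr1", start_a = 900, end_a = 1100,
                        chrom_b = "chr1", start_b = 5e6, end_b = 5e6 + 100,
                        tissue = "t", stringsAsFactors = FALSE)
  expect_equal(interaction_genes(reg, ia_same, genes)$gene_id, "gDist")

  ia_trans <- ia_same; ia_trans$chrom_b <- "chr2"
  expect_equal(nrow(interaction_genes(reg, ia_trans, genes)), 0L)

  ia_away <- ia_same; ia_away$start_a <- 3000; ia_away$end_a <- 3100
  expect_equal(nrow(interaction_genes(reg, ia_away, genes)), 0L)
})

test_that("both anchors in the region recruit genes under either anchor", {
  lead <- snp_record("rs1", "chr1", 1000)
  px <- data.frame(lead_rsid = "rs1", proxy_rsid = "rs2", chrom = "chr1",
                   pos = 9000, r2 = 0.99, stringsAsFactors = FALSE)
  reg <- build_ld_region(lead, px)  # span [999, 9000)
  genes <- mk_genes(gene_id = c("gA", "gB"), symbol = c("A", "B"),
                    chrom = "chr1", start = c(1500, 7000),
                    end = c(2500, 8000), strand = "+")
  ia <- data.frame(chrom_a = "chr1", start_a = 1400, end_a = 2600,
                   chrom_b = "chr1", start_b = 6900, end_b = 8100,
                   tissue = "t", stringsAsFactors = FALSE)
  expect_setequal(interaction_genes(reg, ia, genes)$gene_id, c("gA", "gB"))
})

test_that("candidate genes union window and interaction with provenance", {
  lead <- snp_record("rs1", "chr1", 5e6)
  reg <- build_ld_region(lead, NULL)
  genes <- mk_genes(gene_id = c("gWin", "gFar", "gBoth"),
                    symbol = c("W", "F", "B"),
                    chrom = "chr1",
                    start = c(5e6 + 1e4, 1e7, 5e6 - 2e4),
                    end = c(5e6 + 2e4, 1e7 + 1e4, 5e6 - 1e4),
                    strand = "+")
  ia <- data.frame(chrom_a = "chr1", start_a = 5e6 - 100, end_a = 5e6 + 100,
                   chrom_b = c("chr1", "chr1"),
                   start_b = c(1e7, 5e6 - 2e4 + 50),
                   end_b = c(1e7 + 100, 5e6 - 2e4 + 60),
                   tissue = "t", stringsAsFactors = FALSE)
  cand <- candidate_genes(reg, genes, ia)
  expect_equal(nrow(cand), 3L)
  expect_equal(cand$provenance[cand$gene_id == "gWin"], "window")
  expect_equal(cand$provenance[cand$gene_id == "gFar"], "interaction")
  expect_equal(cand$provenance[cand$gene_id == "gBoth"], "both")
  expect_false(anyDuplicated(cand$gene_id) > 0)
  # deterministic order: by start then id
  expect_equal(cand$gene_id, cand$gene_id[order(cand$start, cand$gene_id)])
})

test_that("segmentation queries agree with a brute-force overlap scan", {
  lead <- snp_record("rs1", "chr1", 1000)
  px <- data.frame(lead_rsid = "rs1", proxy_rsid = "rs2", chrom = "chr1",
                   pos = 3000, r2 = 0.9, stringsAsFactors = FALSE)
  reg <- build_ld_region(lead, px)  # span [999, 3000)
  states <- chromatin_states()
  set.seed(21)
  segs <- do.call(rbind, lapply(c("E001", "E002", "E003"), function(ep) {
    starts <- seq(0, 5000, by = 500)
    data.frame(chrom = "chr1", start = starts, end = starts + 500,
               state = sample(states, length(starts), replace = TRUE),
               epigenome_id = ep, stringsAsFactors = FALSE)
  }))
  got <- query_segmentations(reg, segs)
  # brute-force scan oracle
  want <- segs[vapply(seq_len(nrow(segs)), function(i) {
    segs$chrom[i] == reg$span$chrom &&
      segs$start[i] < reg$span$end && reg$span$start < segs$end[i]
  }, logical(1)), , drop = FALSE]
  expect_equal(do.call(rbind, c(got, make.row.names = FALSE)),
               want, ignore_attr = TRUE)
  expect_equal(length(got), 3L)

  # boundary: a segment ending exactly at span start is excluded,
  # one starting at span start is included
  edge <- data.frame(chrom = "chr1", start = c(499, 999), end = c(999, 1000),
                     state = "1_TssA",
                     epigenome_id = c("E009", "E010"),
                     stringsAsFactors = FALSE)
  got_edge <- query_segmentations(reg, edge)
  expect_equal(names(got_edge), "E010")
})
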