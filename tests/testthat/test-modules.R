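# Co-expression gene-set assembly, clustering, gap statistic, module filter.

block_expr <- function(K, gpb, n, within = 0.9, seed = 1, shift = 100) {
  set.seed(seed)
  f <- matrix(rnorm(K * n), K, n)
  x <- sqrt(within) * f[rep(seq_len(K), each = gpb), ] +
    sqrt(1 - within) * matrix(rnorm(K * gpb * n), K * gpb, n)
  vals <- shift + 10 * x
  if (min(vals) < 0) vals <- vals - min(vals)
  dimnames(vals) <- list(sprintf("g%03d", seq_len(K * gpb)),
                         sprintf("s%03d", seq_len(n)))
  list(expr = expression_matrix(vals),
       labels = rep(seq_len(K), each = gpb))
}

test_that("Spearman correlation is rank-based and matches the naive oracle", {
  set.seed(3)
  y1 <- rnorm(30)
  x <- rbind(a = y1, b = exp(y1), c = -y1,
             d = rnorm(30))
  colnames(x) <- paste0("s", 1:30)
  cm <- spearman_matrix(expression_matrix(abs(x) + 1e-9))
  # recompute on the same stored values
  v <- unclass(abs(x) + 1e-9)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cm$rho[i, j], oracle_spearman(v[i, ], v[j, ]),
                 tolerance = 1e-12)
  }
  # monotone transform invariance on the positive scale
  cm2 <- spearman_matrix(expression_matrix(exp(v / max(v))))
  expect_equal(cm$rho, cm2$rho, tolerance = 1e-12)
  expect_equal(diag(cm$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$rho, t(cm$rho), tolerance = 1e-12)
})

test_that("tied values use average ranks, matching the oracle", {
  x <- rbind(a = c(1, 1, 2, 3), b = c(5, 6, 6, 7), c = c(2, 2, 2, 1))
  colnames(x) <- paste0("s", 1:4)
  cm <- spearman_matrix(expression_matrix(x))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm$rho[i, j], oracle_spearman(x[i, ], x[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("constant genes are flagged undefined, not dropped", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  colnames(x) <- paste0("s", 1:4)
  cm <- spearman_matrix(expression_matrix(x))
  expect_equal(cm$undefined_genes, "b")
  expect_equal(cm$genes, c("a", "b"))
  expect_error(cluster_tree(cm), "b")
})

test_that("gene-set assembly is eGene-anchored with inclusive |rho|", {
  # build genes with exact rank relationships to the anchor
  n <- 11
  anchor <- as.numeric(1:n)
  perfect_neg <- rev(anchor)
  # rho = 0.9 exactly: swap ranks to hit the target sum of squared diffs
  # d^2 total = (1 - rho) * n(n^2-1)/6 = 0.1 * 220 = 22
  partner <- anchor; partner[c(1, 2)] <- partner[c(2, 1)]   # d2 = 2
  partner[c(4, 7)] <- partner[c(7, 4)]                       # d2 += 18
  partner[c(10, 11)] <- partner[c(11, 10)]                   # d2 += 2
  stopifnot(sum((rank(anchor) - rank(partner))^2) == 22)
  weak <- sample(anchor)  # shuffled: low correlation (seeded below)
  set.seed(9); weak <- sample(anchor)
  x <- rbind(eg = anchor, pos = partner, neg = perfect_neg, far = weak)
  colnames(x) <- paste0("s", 1:n)
  ex <- expression_matrix(x)
  got <- assemble_geneset("eg", ex, rho_threshold = 0.90)
  expect_true(all(c("eg", "pos", "neg") %in% got))
  expect_equal(cor(anchor, partner, method = "spearman"), 0.9,
               tolerance = 1e-12)
  expect_false("far" %in% got)
  expect_error(assemble_geneset(character(0), ex), "no eGenes")
})

test_that("anti-correlated partners are recruited via absolute value", {
  n <- 20
  set.seed(2)
  a <- rnorm(n)
  x <- rbind(eg = a, anti = -a + 0.001 * rnorm(n), null = rnorm(n))
  colnames(x) <- paste0("s", 1:n)
  got <- assemble_geneset("eg", expression_matrix(x - min(x) + 1),
                          rho_threshold = 0.90)
  expect_true("anti" %in% got)
})

test_that("cluster tree merges by 1 - rho with average linkage", {
  n <- 12
  set.seed(4)
  a <- rnorm(n)
  x <- rbind(g1 = a, g2 = a + 100, g3 = -a)  # g2 monotone in g1, g3 reversed
  colnames(x) <- paste0("s", 1:n)
  cm <- spearman_matrix(expression_matrix(x - min(x)))
  tree <- cluster_tree(cm)
  expect_equal(min(tree$height), 0, tolerance = 1e-12)   # rho = 1 pair
  expect_equal(max(tree$height), 2, tolerance = 1e-12)   # rho = -1 join
})

test_that("merge heights equal the naive O(n^3) agglomerator", {
  set.seed(6)
  for (rep in 1:5) {
    n_genes <- sample(5:12, 1)
    x <- matrix(abs(rnorm(n_genes * 15)) + 0.1, n_genes, 15,
                dimnames = list(sprintf("g%02d", 1:n_genes),
                                sprintf("s%02d", 1:15)))
    cm <- spearman_matrix(expression_matrix(x))
    tree <- cluster_tree(cm)
    D <- 1 - cm$rho
    expect_equal(sort(tree$height),
                 sort(oracle_average_linkage_heights(D)),
                 tolerance = 1e-10)
  }
})

test_that("gap statistic favours k = 1 for a single tight block", {
  for (seed in 1:3) {
    sim <- block_expr(K = 1, gpb = 15, n = 80, within = 0.95, seed = seed)
    curve <- gap_statistic(unclass(sim$expr), k_max = 4, B = 20, seed = seed)
    expect_equal(choose_k_globalSEmax(curve), 1L)
  }
})

test_that("two well-separated blocks select k = 2 in most replicates", {
  # 200 samples keep the rank-correlation estimates tight enough that the
  # gap curve flattens after the true K instead of creeping upward
  hits <- 0L
  for (seed in 1:20) {
    sim <- block_expr(K = 2, gpb = 20, n = 200, within = 0.9, seed = seed)
    curve <- gap_statistic(unclass(sim$expr), k_max = 5, B = 30, seed = seed)
    if (choose_k_globalSEmax(curve) == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90%
})

test_that("B = 1 keeps the curve defined with zero se", {
  sim <- block_expr(K = 2, gpb = 6, n = 40, seed = 8)
  curve <- gap_statistic(unclass(sim$expr), k_max = 3, B = 1, seed = 8)
  expect_true(all(is.finite(curve$gap)))
  expect_equal(curve$se, rep(0, 3))
})

test_that("gap curves are reproducible under a fixed seed", {
  sim <- block_expr(K = 2, gpb = 8, n = 50, seed = 10)
  c1 <- gap_statistic(unclass(sim$expr), k_max = 4, B = 10, seed = 99)
  c2 <- gap_statistic(unclass(sim$expr), k_max = 4, B = 10, seed = 99)
  expect_identical(c1$gap, c2$gap)
  expect_identical(c1$se, c2$se)
})

test_that("globalSEmax rule arithmetic", {
  mk_curve <- function(gap, se) {
    structure(list(k_values = seq_along(gap), gap = gap, se = se,
                   b_reference = 10), class = "gap_curve")
  }
  # 1.4 >= 1.5 - 0.2 -> smallest qualifying k is 2
  expect_equal(choose_k_globalSEmax(mk_curve(c(1.0, 1.4, 1.5),
                                             c(0.3, 0.2, 0.2))), 2L)
  # zero se forces the global max
  expect_equal(choose_k_globalSEmax(mk_curve(c(1, 2, 3), c(0, 0, 0))), 3L)
  # flat curve: smallest qualifying k = 1
  expect_equal(choose_k_globalSEmax(mk_curve(c(1, 1, 1), c(0.1, 0.1, 0.1))),
               1L)
})

test_that("cut_and_filter partitions genes and applies the eQTL filter", {
  sim <- block_expr(K = 3, gpb = 8, n = 60, seed = 12)
  cm <- spearman_matrix(sim$expr)
  tree <- cluster_tree(cm)
  genes <- rownames(sim$expr)
  flags <- setNames(genes %in% genes[sim$labels == 1], genes)
  part <- cut_and_filter(tree, K = 3, flags)
  expect_equal(length(part$assignments), length(genes))
  expect_equal(sort(unique(part$assignments)), 1:3)
  # only the module holding the flagged block is retained
  flagged_modules <- unique(part$assignments[flags])
  expect_setequal(part$retained, flagged_modules)

  # all flags on -> all modules retained; none on -> none retained
  all_on <- cut_and_filter(tree, 3, setNames(rep(TRUE, length(genes)), genes))
  expect_equal(all_on$retained, 1:3)
  none <- cut_and_filter(tree, 3, setNames(rep(FALSE, length(genes)), genes))
  expect_equal(length(none$retained), 0L)

  # retained is monotone in the eQTL map
  extra <- flags; extra[genes[sim$labels == 2][1]] <- TRUE
  part2 <- cut_and_filter(tree, 3, extra)
  expect_true(all(part$retained %in% part2$retained))
})

test_that("K = 1 with any eGene keeps the single module", {
  sim <- block_expr(K = 2, gpb = 5, n = 40, seed = 13)
  tree <- cluster_tree(spearman_matrix(sim$expr))
  genes <- rownames(sim$expr)
  flags <- setNames(c(TRUE, rep(FALSE, length(genes) - 1)), genes)
  part <- cut_and_filter(tree, 1, flags)
  expect_equal(part$K, 1)
  expect_equal(part$retained, 1L)
})

test_that("the ARI helper agrees with mclust on random labelings", {
  skip_if_not_installed("mclust")
  set.seed(22)
  for (i in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(oracle_ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(oracle_ari(rep(1:2, each = 10), rep(1:2, each = 10)), 1)
})
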