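---
title: "From lead SNPs to modules, pathways and causal variants: the methods behind locuslens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lead SNPs to modules, pathways and causal variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locuslens)
```

## Overview

Most genome-wide-significant GWAS variants are non-coding, and the gene they
regulate is rarely the nearest one. `locuslens` implements an offline
interpretation pipeline for such loci. For each lead SNP it (i) builds the
linkage-disequilibrium (LD) region from proxy variants, (ii) expands the
candidate-gene search space beyond the usual mapping window using chromosomal
interactions, (iii) tests SNP–gene associations and selects eGenes,
(iv) detects tissue-wise co-expression modules anchored on those eGenes,
selecting the number of modules with the gap statistic, (v) tests the
retained modules for pathway enrichment with Fisher's exact test, and
(vi) fine-maps individual loci with approximate-Bayes-factor (ABF)
colocalization, producing per-SNP causal posteriors.

Everything runs from local files; a seeded generator
(`sim_config()`/`write_fixture_dir()`) produces every input with planted
ground truth, so the whole pipeline is testable without any download.

## LD regions and the expanded search space

The LD region of a lead SNP is the interval spanned by the lead and all
proxies with $r^2 \ge 0.80$. The threshold is **inclusive**: a proxy at
exactly 0.80 is retained. When genotype dosages are available, `compute_r2()`
computes composite LD — the squared Pearson correlation of unphased dosages —
rather than haplotype-EM $r^2$; this is phase-free and matches dosage data.
Lowering the threshold can only grow the proxy set and the span
(a property the tests exercise). The span is not padded beyond the
min/max proxy positions.

Candidate genes come from two routes:

* **window genes** — genes whose transcription start site (TSS) lies within
  1 Mb of the lead (inclusive, the standard eQTL mapping-window convention;
  gene-body overlap is deliberately not used);
* **interaction genes** — for each chromosomal interaction with an anchor
  overlapping the LD region, the genes under the *other* anchor, restricted
  to the lead's chromosome. When both anchors overlap the region, genes under
  either anchor qualify (the permissive, order-independent choice). Tissue
  labels on interactions are carried through for reporting but do not gate
  recruitment.

All intervals are handled 0-based half-open internally (the BED convention);
SNP positions and TSSs are 1-based in files and converted on read. Abutting
intervals do not overlap.

## eQTL testing and eGene selection

Missing expression values are imputed by k nearest neighbours (`k = 10`):
a missing cell takes the mean, over the k nearest genes, of that sample's
values, with gene–gene distance the Euclidean distance over mutually observed
samples scaled by the number of shared samples, and ties broken by gene-id
order. A cell with fewer than k eligible neighbours falls back to its gene's
observed mean and flags the result. We chose a per-cell fallback (rather than
abandoning the whole matrix) because at realistic missingness almost no gene
is complete in every sample, yet neighbour information is still abundant;
the tests verify the imputation beats column-mean imputation in RMSE on
block-correlated data.

The association model is deliberately plain: ordinary least-squares simple
regression of expression on allele dosage, $\hat\beta = \mathrm{cov}(g,y) /
\mathrm{var}(g)$, standard error from the residual variance on $n-2$ degrees
of freedom, two-sided t-test. No covariates are included; a covariate hook is
left for extension. eGenes are genes with at least one tissue reaching
$p \le 0.05$ (inclusive), per tissue, with no multiple-testing correction at
this screening step — adjusted values are reported downstream by the
enrichment stage. Static QTL compendia (pQTL, lQTL, sQTL, meQTL, miQTL,
mQTL) are queried by exact rsID match for the lead and all proxies, each hit
tagged `lead` or `proxy`.

## Co-expression modules and the gap statistic

Per tissue, the module gene set is the eGenes plus every gene whose absolute
Spearman correlation with **an eGene** reaches 0.90 (inclusive; the absolute
value admits anti-correlated partners). Growth is non-transitive: partners
must correlate with an eGene itself, not merely with another set member.
Genes are clustered by average-linkage agglomeration on the distance
$d = 1 - \rho$ (range $[0,2]$). Average linkage is our choice — standard for
correlation-distance co-expression — as the linkage is otherwise
unspecified; Spearman makes every downstream stage invariant to monotone
transforms of expression, which the tests exploit.

The number of modules K is selected with the gap statistic computed on
hierarchical cuts of that tree. Within-module dispersion uses the
pairwise-distance form
$W_k = \sum_r D_r / (2 n_r)$, valid for non-Euclidean dissimilarities.
The reference distribution permutes each gene's values across samples
independently: this destroys gene–gene correlation while preserving each
gene's marginal, which suits TPM-scale data far better than the original
uniform-box reference (still available via `reference = "uniform"`). With
$B = 50$ reference draws,
$\mathrm{Gap}(k) = \mathrm{mean}_b \log W^*_{kb} - \log W_k$ and
$s_k = \mathrm{sd}_b(\log W^*_{kb})\sqrt{1 + 1/B}$. K is the **globalSEmax**
choice: the smallest k whose gap is within one standard error of the global
maximum. The search range defaults to $1..\min(10, n_\mathrm{genes}-1)$.

Two behaviours of this estimator are worth knowing. First, because the gap
works on $\log W_k$, splitting a very tight cluster can keep the gap creeping
upward past the true K when clusters are small; with 20 genes per module and
100 samples the planted-structure tests recover K correctly in well over 80%
of seeds, and more samples sharpen this further. Second, a gene carrying a
strong planted eQTL effect gains variance from the dosage term and becomes
the most peripheral member of its module; at large K the cut can isolate such
genes. This is a genuine property of eGene-anchored clustering, not an
artifact — in practice multiple eQTL genes per module (the typical situation
for a 20+-SNP locus set) keeps eGene-bearing clusters from being singletons.

Modules pass two filters: they must contain at least one eQTL gene, and
(after enrichment) at least one pathway with raw $p \le 0.05$. Modules
failing either are omitted.

## Pathway enrichment

Each retained module is tested against every pathway with a one-sided
(greater) Fisher exact test on the 2×2 table of module × pathway membership
within the **universe of genes present in the tissue's expression matrix** —
not the whole genome, which would inflate enrichment. The p-value is the
hypergeometric tail $P(X \ge a)$; the odds ratio is the cross-product ratio
$ad/bc$, $+\infty$ when $bc = 0$ with $ad > 0$. One-sidedness is our
interpretation of "enriched" (depletion does not make a module enriched); a
two-sided variant remains a configuration choice. Benjamini–Hochberg
adjustment is applied across all (module, pathway) pairs within a tissue and
reported alongside raw p-values; the omission rule uses raw p at 0.05, since
published enrichment tables of this kind report raw values. The cross-tissue
view keeps, for each (pathway, tissue), the best module-level result, ties
broken by the smaller module label.

## ABF colocalization and fine-mapping

Per-SNP evidence is the Wakefield approximate log Bayes factor computed from
an effect estimate and its variance,
$$\mathrm{lABF} = \tfrac12\left[\log(1-r) + r z^2\right],\qquad
r = \frac{W}{W+V},\quad z = \frac{\hat\beta}{\sqrt V},$$
with prior effect variance $W = 0.0225$ (sd 0.15) per quantitative trait —
the conventional choice, configurable per trait. Under at-most-one causal
variant per trait, the five hypothesis posteriors (H0 no association, H1/H2
single-trait, H3 two distinct causal variants, H4 one shared causal variant)
are prior-weighted sums of per-SNP Bayes factors with priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. All sums run in log space
(log-sum-exp), stable for $|z|$ well beyond 40 across $10^4$ SNPs. The H3
term $e^{S_1+S_2} - e^{S_{12}}$ is mathematically a sum over distinct SNP
pairs and therefore non-negative; if floating error drives it negative it is
clamped to zero with a warning. SNPs present in only one trait are dropped
with a logged count.

The per-SNP causal posterior (the quantity plotted as a track) is the softmax
of $\mathrm{lABF}_1 + \mathrm{lABF}_2$ over shared SNPs; single-trait
fine-mapping is the softmax of one trait's lABFs. Both are probability
vectors by construction.

One unit subtlety: rescaling a trait (multiplying $\hat\beta$ and
$\sqrt{V}$ by a constant) leaves z unchanged but changes $r$ if $W$ is held
fixed, because $W$ is expressed in squared trait units. Posteriors are
exactly invariant under a units change only when $W$ is rescaled along with
the trait, which is how the invariance is tested here.

## The synthetic test bench

The generator plants every structure the pipeline is meant to recover, and
its defaults are the bench's study conditions:

* **genotypes** — 200 SNPs in LD blocks of 10, within-block latent
  correlation 0.8, per-SNP MAF uniform on [0.1, 0.5]; dosages arise from a
  Gaussian copula thresholded at Hardy–Weinberg genotype frequencies. This
  gives direct control of the $r^2$ structure at trivial runtime, which the
  LD-region and colocalization tests need; no attempt is made to match real
  allele-frequency spectra or recombination maps.
* **expression** — four modules of 20 genes, within-module correlation 0.9
  (one latent factor per module), 5% missing cells; planted eQTL genes add
  $\beta\cdot$dosage. Values are mapped to a TPM-like scale by a monotone
  affine transform only — Spearman-based stages cannot tell the difference,
  which is exactly why a fuller TPM error model is unnecessary here.
* **summary statistics** — per trait, an independent cohort of 1000 drawn
  from the same LD structure; the causal variant explains 5% of phenotypic
  variance; marginal per-SNP OLS gives $\hat\beta$ and $V$.
* **annotation** — genes tiled around the lead with one gene planted 2 Mb
  away and linked back by a single interaction (recoverable only through
  interaction recruitment); a gapless 15-state segmentation tiling over
  three epigenomes; proxies from realized $r^2$; one planted pathway
  overlapping module 1 plus random background pathways.

What passing tests do **not** show: robustness to population structure,
covariate confounding, non-Gaussian expression noise, overlapping GWAS
cohorts in colocalization, or realistic LD decay — real data carry all of
these and the bench deliberately does not.

## Problem sizes and numerical choices

The recovery checks use 100 colocalization replicates per scenario
(200 SNPs, n = 1000 per trait), 50 module-recovery seeds (80 genes, 100
samples, B = 50), a 5000-replicate null calibration of the association test,
and a full sweep of every 2×2 table with total ≤ 30 against exact
hypergeometric enumeration. Determinism contracts: identical seeds give
byte-identical fixtures, bundles and gap curves; generators save and restore
the caller's RNG state. p-values are floored at the smallest positive
double rather than returned as 0; undefined correlations (constant genes)
are flagged and reported, never silently dropped.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile()
write_fixture_dir(sim_config(seed = 1), dir)

cfg <- run_config(dir, file.path(dir, "out"), seed = 1)
cmd_summarize(cfg)             # one JSON bundle per lead SNP
cmd_analyze(cfg)               # modules + enrichment per tissue
cmd_coloc(cfg, file.path(dir, "trait1.tsv"), file.path(dir, "trait2.tsv"))
cmd_report(cfg)                # static HTML + JSON report
```

The same steps are available from a shell via the thin CLI in
`inst/scripts/locuslens` (`simulate`, `summarize`, `analyze`, `coloc`,
`report`), with exit codes 0/1/2 for clean/partial/failed runs. The
interactive dashboard such pipelines often ship was intentionally replaced
by this static export: the JSON mirrors every table a front-end would need,
and presentation stays out of the method's way.

## Known limitations

* The eQTL model is covariate-free simple regression; it is a documented
  substitute for a full pipeline with expression PCs and genotype PCs.
* No permutation-based eGene FDR; the $p \le 0.05$ screen is nominal.
* Colocalization assumes at most one causal variant per trait per region;
  no multi-causal (SuSiE-style) extension, no conditional analysis.
* Module assignment is hard; no soft/overlapping membership or soft
  thresholding.
* No genome-build conversion, no remote data access, no RData/HDF5 readers.
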