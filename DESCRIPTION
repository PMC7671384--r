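Package: locuslens
Title: Offline Functional Interpretation of GWAS Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Given lead GWAS SNPs and local data files (LD proxies or genotype
    dosages, gene annotation, chromosomal interaction anchors, chromatin state
    segmentations, tissue expression matrices, static QTL compendia, pathway
    gene sets, and per-trait association summary statistics), locuslens builds
    linkage-disequilibrium regions, expands the candidate-gene search space
    through chromosomal interactions, tests SNP-gene associations and selects
    eGenes, detects tissue-wise co-expression modules with gap-statistic model
    selection (globalSEmax rule), tests pathway enrichment with Fisher's exact
    test, and fine-maps loci via approximate-Bayes-factor colocalization with
    per-SNP causal posteriors. A seeded synthetic-fixture generator produces
    every input with planted ground truth, so the whole pipeline runs and is
    testable fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
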