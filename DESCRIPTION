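Package: poolsweep
Title: Pool-Seq Selective Sweep Scans, Pooled FST, and Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("poolsweep", "maintainers", email = "poolsweep@example.org",
           role = c("aut", "cre"))
Description: Population-genomic analysis of pooled sequencing (Pool-seq) data
    aimed at detecting hard selective sweeps associated with insecticide
    resistance. Reads Popoolation2-style sync allele counts, subsamples sites
    to uniform coverage, computes nucleotide diversity (pi), Watterson's
    theta, and Tajima's D in nonoverlapping windows and per gene, delineates
    low-diversity sweep regions and intersects them across populations,
    estimates pairwise FST with a classical heterozygosity-based estimator
    and a pool-size-corrected ANOVA (identity-probability) estimator, scans
    for outlier SNPs by PCA z-scores with Mahalanobis distances and FDR
    correction, screens coding variants for amino-acid consequences, and fits
    probit dose-response models for LC50 estimation with Fieller confidence
    intervals. Includes a seeded synthetic-data generator that emulates the
    pooled design (neutral site-frequency-spectrum background, an embedded
    hard sweep with a population-specific extension, a fixed nonsynonymous
    "kdr-like" SNP, and differentiated flanking SNPs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
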