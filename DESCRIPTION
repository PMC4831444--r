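Package: radscan
Title: Population-Genomic Divergence Scans for RAD-Seq Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting local adaptation and speciation with
    RAD-seq SNP genotypes sampled under a crossed species-by-location design.
    Implements the Weir-Cockerham ANOVA F_st estimator (per-locus variance
    components and ratio-of-sums multilocus summaries), RAD-specific SNP and
    individual filters, F_st percentile stratification with PCA/k-means and
    neighbor-joining summaries, a forward Wright-Fisher island-model simulator
    used both as a neutral null and as the calibration engine for an
    empirical-p F_st outlier scan with Benjamini-Hochberg FDR control,
    repeated-outlier detection across taxa, linkage-disequilibrium network
    clustering with lambda-based outlier clusters (SOCs), and a synthetic
    RAD-genotype generator with planted divergent loci for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    ape,
    cluster,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
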