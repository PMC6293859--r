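Package: divergescan
Title: Selection-Signature Scans and Stepwise Mixed-Model QTL Mapping in
    Structured Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing divergence between a selected breeding line
    and a control line genotyped at genome-wide SNPs. Implements per-site
    Weir-Cockerham Fst and nucleotide diversity with non-overlapping window
    aggregation and top-quantile selection-signature calling; the VanRaden
    realized genomic relationship matrix and genotype PCA; a mixed linear
    model with fixed line and major-QTL effects and random cage and polygenic
    effects, fitted by restricted maximum likelihood with a stepwise genome
    scan (GEBV, heritability and per-QTL variance contributions); and the
    intersection of elevated-Fst windows with mapped QTL. A full-sib family
    cohort simulator with planted divergent loci and QTL supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
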