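Package: cohesinproc
Title: Genomic-Distance-Biased Analysis of Cohesin Processivity at
    Clustered Gene Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of genomic-distance-biased regulatory
    effects at clustered gene loci such as the clustered protocadherins.
    Provides a synthetic locus generator driven by an explicit
    loop-extrusion processivity model (exponential decay of
    enhancer-promoter contact with linear genomic distance), multi-modal
    quantification (RNA-seq style counts, ChIP peak enrichment, 4C contact
    profiles), a genome-binned Poisson enrichment scan for localized
    clusters of downregulated genes, distance-versus-fold-change trend
    fitting with inversion to a processivity estimate, and contact-matrix
    topology tools (cis-depth normalization, Knight-Ruiz balancing,
    directionality index, HMM-based domain calling, differential contact
    maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    graphics,
    Matrix,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
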