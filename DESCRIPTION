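Package: cloneGD
Title: Clone Trees, Subclonal Whole-Genome Doubling and Heterogeneity
    Metrics from Multi-Region Tumour Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying tumour evolution from multi-region bulk
    DNA sequencing. Provides a realistic clone-level tumour simulator
    (random clone phylogenies; SNV, copy-number and whole-genome-doubling
    events; Dirichlet clone mixing; Poisson/Binomial read counts),
    phylogenetic cancer cell fraction (PhyloCCF) estimation and
    clonal/subclonal/absent classification, presence-pattern pre-clustered
    mutation clustering with clone-tree reconstruction under the pigeonhole
    and crossing rules, a detector for subclonal and parallel
    whole-genome-doubling events from doubled mutation copy numbers,
    intratumour heterogeneity metrics (mutational ITH, SCNA ITH, wGII,
    fraction LOH, recent subclonal expansion score), and a simulation
    benchmark comparing the doubling detector against region-count
    baselines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
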