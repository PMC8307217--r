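Package: algaeLipids
Title: Fatty Acid Profiling, Lipid Nutritional Indices and Antioxidant
    Assay Reduction for Microalgae
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of GC-MS fatty acid methyl
    ester (FAME) profiles of microalgae. Parses delta/omega fatty acid
    shorthand into structured descriptors, aggregates relative-abundance
    profiles into saturation-class and omega-class sums, computes the
    Ulbricht-Southgate atherogenicity and thrombogenicity indices and the
    hypocholesterolemic/hypercholesterolemic ratio, reduces DPPH/ABTS
    microplate kinetics to inhibition percentages, ICx estimates and
    Trolox equivalents, and provides the supporting multivariate
    (glog/PCA/Ward clustering) and univariate (Kruskal-Wallis with Dunn's
    post-hoc) statistics. A synthetic-data generator emulates replicate
    fatty acid tables and plate kinetics with known ground truth so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Lipidomics, Metabolomics, MassSpectrometry, Preprocessing,
    StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
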