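Package: rlbh
Title: Group-Specific Probe Panels and In Silico Reverse Line Blot Hybridization Typing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Design and in silico validation of group-specific degenerate
    oligonucleotide probe panels against labelled marker-sequence collections
    (such as 16S-23S ITS sequences of closely related bacterial strains),
    simulation of (nested) PCR and reverse line blot hybridization producing
    ordinal detection matrices, and downstream niche-preference statistics:
    detection frequencies, sympatry-allopatry/Venn co-occurrence analysis,
    and constrained ordination (CCA/RDA) with Monte Carlo permutation
    forward selection of environmental variables. A synthetic-data generator
    produces strain collections with planted diagnostic sites and habitat
    communities assembled by Gaussian niche (ecotype sorting) models, so the
    whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
biocViews: Sequencing, Microbiome, OligoDesign, Software
RoxygenNote: 7.3.3
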