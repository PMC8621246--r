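Package: zooselect
Title: Ensemble Swarm-Intelligence Feature Selection for Omics Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects small, predictive feature subsets from "large p small n"
    omics matrices (transcriptome or methylome intensities with a binary
    phenotype) by ensembling nine binary animal-inspired swarm-intelligence
    wrapper optimizers (grey wolf, whale, bat, cuckoo, firefly, moth-flame,
    particle swarm, manta-ray and dragonfly). Features are prefiltered by a
    two-sample t-test, each optimizer proposes a subset minimizing a weighted
    combination of inner-split classification error and subset size, the nine
    proposals are combined by majority vote, and the voted subset is refined
    by dynamic recursive feature elimination driven by linear support-vector
    machine weights. Includes stratified splitting and cross-validation
    utilities, Sn/Sp/Acc metrics, a five-classifier maximum-accuracy score,
    an incremental-feature-selection curve, and a seeded synthetic-data
    generator with planted informative features for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    class,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
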