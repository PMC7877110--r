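Package: dicercleave
Title: Structure-Aware Prediction of Human Dicer Cleavage Sites on
    Pre-miRNA Arms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the position of the Dicer scissile bond on the 5p
    and 3p arms of human pre-miRNA hairpins from sequence and predicted
    secondary structure. Extracts 14-nt cleavage and non-cleavage windows
    together with their loop/bulge-aware complementary strands, encodes
    each window position as a categorical base-pair (relational) feature,
    derives an additional class feature by affinity-propagation clustering
    of pairwise edit-distance similarities, and classifies windows with a
    leaf-wise gradient-boosted tree ensemble. Includes readers for FASTA,
    Vienna dot-bracket and CT secondary-structure files, the repeated
    random-split evaluation protocol with sensitivity, specificity,
    accuracy and Matthews correlation coefficient, and a synthetic hairpin
    generator with planted cleavage signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    xgboost,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
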