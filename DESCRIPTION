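Package: anchorfci
Title: Causal Discovery with Reliable Anchors under Latent Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based causal discovery for mixed genotype/phenotype
    data in the presence of latent confounding. Implements a conservative
    RFCI-style engine (order-independent stable skeleton, majority-rule
    triple classification, complete orientation rules R1-R10) extended with
    the anchorFCI strategy: screening of anchor candidates known not to be
    caused by the variables of interest, selection of reliable anchors that
    form only unambiguous triples, an adapted skeleton search respecting the
    partial order, and enforcement of the implied non-ancestral arrowheads.
    Includes a symmetric likelihood-ratio conditional-independence test for
    mixed continuous/binary/multinomial data with p-value merging and
    rank-based inverse-normal transforms, ancestral-graph utilities
    (m-separation, latent projection, structural Hamming distance), a
    random-MAG simulation benchmark with an SHD-difference score, bootstrap
    edge-stability assessment, and causal-effect identification and
    estimation from the learned partial ancestral graph via edge visibility
    and the generalized backdoor criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
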