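Package: phytoniche
Title: Habitat Suitability Modelling and Phytochemical Quality Zoning for
    Medicinal Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline linking ecological niche modelling to
    phytochemical quality for medicinal plants such as Lonicera japonica
    Flos. Implements a presence-background maximum-entropy species
    distribution model (linear, quadratic, product and hinge features with
    L1 regularization and logistic output), model evaluation (AUC, variable
    contributions, permutation importance, jackknife gains, response
    curves), suitability zoning by fixed edges or Fisher-Jenks natural
    breaks with latitude-corrected class areas, centroid range-shift
    analysis with haversine distances, HPLC fingerprint processing (peak
    detection, retention-time alignment, common-peak matching, congruence
    similarity, method-validation RSDs), and environment-metabolite
    regression with quality zoning overlays. Includes synthetic-data
    generators (Gaussian random fields, occurrences from a known
    suitability law, chromatograms with planted peaks) so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'centroid.R'
    'evaluation.R'
    'features.R'
    'fingerprint.R'
    'geodata.R'
    'maxent.R'
    'phytoniche-package.R'
    'pipeline.R'
    'quality.R'
    'synthetic.R'
    'utils.R'
    'varselect.R'
    'zoning.R'
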