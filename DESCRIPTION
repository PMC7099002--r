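Package: secalib
Title: Simulation-Based Assessment of Secondary and Distant Primary
    Calibrations in Divergence-Time Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the error that secondary (molecularly derived)
    calibrations and phylogenetically distant primary calibrations
    introduce into divergence-time estimates.  Provides a seeded
    synthetic-data generator (Yule timetrees split into two nested
    subtrees sharing one overlapping node, gene profiles, autocorrelated
    branch rates), exact HKY sequence simulation and gene
    concatenation, a transparent relative-rate dating engine with
    min/max calibration constraints and resampling-based confidence
    intervals, a factorial study driver covering seven
    calibration-uncertainty scenarios by four calibration settings
    (including the secondary-calibration hand-off between nested
    trees), and the four standard accuracy measures (time departure,
    CI accuracy, CI precision, CI skewness) with Tables-style
    aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'show-methods.R'
    'synthdata.R'
    'hky.R'
    'seqsim.R'
    'io.R'
    'dating.R'
    'study.R'
    'metrics.R'
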