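Package: stripeflow
Title: Quantification of Eve Stripe 2 Enhancer Dynamics in Live Drosophila Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pair-rule stripe formation in live-imaged
    Drosophila blastoderm embryos carrying fluorescent even-skipped reporters.
    Provides a synthetic embryo-movie generator with known ground truth,
    watershed-based nuclei segmentation of the midsagittal cortical layer
    (including a fusion rule for nuclei split by cellularization membranes),
    extraction of anteroposterior expression profiles, smoothing-spline stripe
    feature detection, stripe-2 maturation and positional-robustness
    phenotypes with rank-sum cohort statistics, Mendelian cross expectation
    and rescue-viability arithmetic with balancer lethality, and interval
    level editing of enhancer annotations (deletions and inversion).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
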