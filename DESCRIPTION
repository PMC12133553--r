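Package: mrMediate
Title: Two-Step Mediation Mendelian Randomization with GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample and two-step (mediation) Mendelian
    randomization from GWAS summary statistics. Implements instrument
    selection (p-value thresholds, distance/LD clumping, allele
    harmonization with palindrome removal, instrument-strength F filter,
    confounder blacklist, outcome-association Bonferroni screen), a
    battery of causal-effect estimators (Wald ratio, fixed- and
    random-effects inverse-variance weighting, MR-Egger with NOME I-squared,
    weighted median, mode-based estimation, robust adjusted profile score),
    sensitivity diagnostics (MR-PRESSO global/outlier/distortion tests,
    Steiger directionality, Cochran's Q, leave-one-out, funnel data,
    statistical power), product-of-coefficients mediation with delta-method
    standard errors and mediation-proportion reporting, hypergeometric
    gene-set overrepresentation with false-discovery-rate control, and a
    synthetic summary-statistic generator with known causal and mediation
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
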