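Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for selecting stable reference (housekeeping) genes from
    RT-qPCR quantification-cycle (Cq) panels, built around a canine
    whole-blood study design. Reads wide or long Cq tables with technical
    duplicates, converts Cq to efficiency-corrected relative quantities,
    ranks candidate genes by geNorm pairwise-variation M-values with the
    stepwise-exclusion procedure and the V(n/n+1) optimal-gene-count rule,
    and by a model-based (NormFinder-style) stability value separating
    intra- and intergroup variation. Includes covariate diagnostics
    (disease-group ANOVA, leukocyte-count dichotomy with Holm correction,
    Cq versus log leukocyte-count slopes with a per-dog random intercept,
    repeated-sampling likelihood-ratio tests) and a seeded synthetic cohort
    generator with exported ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
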