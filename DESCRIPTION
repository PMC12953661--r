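Package: mscognet
Title: Structural Connectome Substrates of Processing-Speed Impairment
    in Multiple Sclerosis
Version: 0.1.0
Authors@R: person("MAGNIMS", "Reanalysis Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study structural-connectome correlates of Symbol Digit
    Modalities Test (SDMT) impairment in adult- versus late-onset multiple
    sclerosis. Builds streamline-count and FA-weighted connectomes from
    tractograms and parcellations, computes lesion-based disconnection
    indices, commissural ratio and whole-brain/hemispheric graph metrics,
    converts patient measures to multicenter heteroscedastic normative
    z-scores, runs robust group comparisons with Benjamini-Hochberg FDR,
    univariable robust logistic associations with balanced downsampled
    bootstrap, and center-adjusted elastic-net feature selection with
    bootstrap stability frequencies. Includes a synthetic multicenter cohort
    generator with known injected effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
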