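Package: lipidsum
Title: Sum-Composition Lipid Annotation and Mixed-Effects Lipidomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Accurate-mass annotation of LC-MS lipidomics feature tables at
    the sum-composition level, built on elemental-formula arithmetic and
    enumeration of candidate species from generic lipid-class formulas with
    adduct m/z generation. Annotated features are semi-quantified against a
    spiked internal-standard mix into arbitrary units, then analysed with
    class Z-score trajectories, chain-length and double-bond log2 fold-change
    curves with LOESS smoothing, principal component analysis, and per-lipid
    linear mixed-effects differential testing with Benjamini-Hochberg FDR
    control. Includes seeded generators of synthetic feature tables and
    abundance tables emulating a longitudinal organoid study design (control
    versus ALD donor lines, very-long-chain fatty-acid enrichment) so the
    whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
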