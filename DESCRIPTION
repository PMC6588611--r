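Package: gscreen
Title: Germline Screening of Advanced-Cancer Cohorts with Paired Tumor and
    Expression Evidence
Version: 0.1.0
Authors@R:
    person("CGM", "Pipeline Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to screen germline variant calls from advanced-cancer
    cohorts against a hereditary-cancer gene panel. Implements a four-stage
    variant filter cascade (call quality, population allele frequency,
    consequence, variant allele fraction), a deterministic simplified
    ACMG/AMP-style five-class pathogenicity engine with curation overrides
    and recessive-gene handling, paired tumor-normal loss-of-heterozygosity
    calling, somatic second-hit and reading-frame-restoring reversion
    detection, DNA-repair pathway burden summaries, an expression-signature
    classifier for homologous-recombination deficiency and PARP-inhibitor
    sensitivity (hierarchical clustering followed by k-nearest-neighbour
    classification), clinical significance grouping with treatment and
    return-of-results suggestions, and a synthetic cohort generator that
    emulates the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
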