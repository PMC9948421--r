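Package: tmnseq
Title: Variant Triage, Germline Classification, and Prognostic Modelling
    for Therapy-Related Myeloid Neoplasms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible analysis pipeline for targeted-panel sequencing
    of therapy-related myeloid neoplasms (T-MN). Merges per-caller VCF call
    sets into consensus records, applies a quality / strand-bias /
    population-frequency / panel-of-normals filtering cascade that
    partitions variants into presumed-germline, potential-germline, somatic
    and dual origins, classifies germline candidates with an ACMG/AMP
    criterion-combination engine (PVS1 with ClinGen-style NMD downgrade,
    frequency-based PM2 with inheritance-specific cutoffs, in-silico
    concordance PP3, hotspot PM1, reputable-source PP5), assigns
    AMP/ASCO/CAP somatic tiers, summarizes the cohort mutation landscape
    with multi-hit counting, and models overall survival with Kaplan-Meier,
    log-rank and Cox proportional-hazards analyses including a
    collinearity-screening step. A fully labelled synthetic-cohort
    generator reproduces the statistical structure the analysis assumes so
    that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
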