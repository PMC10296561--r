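Package: stromacall
Title: Stroma-Aware Subtyping, Cell-Cell Communication and Causal Target
    Calling for High-Grade Serous Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-stage in-silico pipeline for characterizing the
    mesenchymal (MES) subtype of high-grade serous ovarian cancer and
    nominating causal therapeutic targets from transcription-factor
    activity. Stages cover congruence-filtered molecular subtyping,
    moderated-t differential expression, preranked and single-sample gene
    set enrichment, single-cell compartment assignment by module scores,
    consensus ligand-receptor inference with robust rank aggregation,
    ligand activity against hallmark programs, regulon-based
    transcription-factor activity (analytic NES), and causal
    contextualization of a signed prior-knowledge network by exact
    combinatorial optimization with pairwise reciprocal-consistency
    consensus target calling. A synthetic-data generator with a planted
    kinase to transcription factor to target-gene cascade makes every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
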