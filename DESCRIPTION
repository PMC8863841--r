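Package: lipidaxis
Title: Lipidomic Structure, Pathway Flux and Microbiome Co-Occurrence
    Analytics for Gut-Brain Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for two-group mass-spectrometry lipidomics and shotgun
    microbiome studies of the microbiota-gut-brain axis. Parses LipidSearch
    style lipid shorthand names into subclass, chain-length, unsaturation
    and molecular-geometry annotations; applies peak-level quality-control
    filters and total-peak-area normalization; performs subclass-, chain-
    and species-level differential analysis with PLS-DA variable importance
    (VIP) double cutoffs; scores lipid reaction-network activity with
    per-edge one-sided tests converted to Z-scores and pathway-level
    aggregation; re-implements a two-class LDA effect size (LEfSe style)
    screen for differential taxa; and builds thresholded Spearman
    co-occurrence networks linking taxa, lipid species and behaviors.
    Includes a seeded synthetic-data generator emulating the study design
    so every stage is testable without raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
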