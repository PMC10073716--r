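Package: upmprofiler
Title: Ureido Protein Modification Profiling of Seminal-Plasma EV Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ureido protein modifications (citrulline and
    homocitrulline) in extracellular-vesicle proteomes quantified by iTRAQ 8-plex
    mass spectrometry. Starting from a peptide-spectrum-match (PSM) table, the
    package classifies mass shifts into modification classes while discriminating
    the isobaric deamidation and N-terminal carbamylation confounds, computes
    cumulative modification burden by spectral counting, performs reporter-based
    relative protein quantification with group testing, estimates per-site
    modification stoichiometry with chi-squared group comparison, correlates
    modification burden with clinical semen parameters, and analyses the sequence
    and domain context of modified sites (BLOSUM62 window consensus, domain
    overlap). A synthetic-data generator with known ground truth emulates the
    study design (two groups pooled into labelled reporter channels) so that
    every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
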