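Package: peakcoloc
Title: Co-Localization Screening of ChIP-Seq Peaks with R-Loop and G-Quadruplex Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A genome-wide co-occupancy screen for chromatin proteins whose
    ChIP-seq binding sites coincide with R-loop and DNA G-quadruplex (G4)
    structure loci. Implements record-level interval overlap with
    report-first/unique semantics, per-protein overlap percentages and their
    cross-protein Pearson correlation, strand-aware promoter annotation and
    promoter-localization fractions, peak-center aggregation profiles,
    scaled-gene metagene profiles, RPKM-style coverage normalization,
    region signal densities, and exon exclusion-ratio summaries. Ships a
    seeded synthetic-data generator that plants exact overlap structure with
    a ground-truth ledger, so the whole pipeline is testable end-to-end
    without external downloads. All tabular results are tibbles; fitted
    result objects have tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
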