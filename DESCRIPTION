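Package: vampseqr
Title: Scoring and Simulation for VAMP-seq Variant Abundance and Toxicity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multiplexed assays of variant effect built around
    VAMP-seq (variant abundance by massively parallel sequencing) of a
    site-saturated missense/nonsense library. Implements barcode-variant
    subassembly from long reads with substitution/indel filtering and
    majority-rule barcode assignment, FACS-bin count normalization and the
    protein stability index (PSI) with wild-type/stop anchored abundance
    scores, slope-based growth-depletion toxicity scores from time-course
    counts, overlapping peptide-tile (degron) library design and tile
    stability index (TSI) scoring with control-tile renormalization,
    residue-level structural covariates (weighted contact number, rescaled
    thermodynamic stability predictions, alignment gap filtering), and the
    downstream analytics used to interpret such maps (positional medians,
    variance explained, bootstrapped correlations, clinical-class summaries,
    replicate statistics). A synthetic-data generator with a bimodal latent
    abundance distribution and exponential variant depletion makes the whole
    pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
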