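Package: thermoccupancy
Title: Thermodynamic Modeling of Transcription Factor Occupancy from ChIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A statistical-thermodynamics model of transcription factor (TF)
    DNA occupancy that predicts ChIP signal over genomic windows from position
    weight matrix (PWM) binding sites, Boltzmann-weighted configurations of
    non-overlapping bound sites, and a single concentration parameter per TF.
    Extends the baseline model with pairwise TF-TF interaction terms to detect
    cooperative, antagonistic and competitive influences of secondary motifs
    on a primary TF's binding profile, assessed by cross-validated correlation
    improvements with shuffled-motif empirical p-values and robust outlier
    Z-scores. Includes accessibility-aware semi-partial correlation analysis,
    inter-site spacing bias tests, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
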