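Package: motifbench
Title: Comparative Quality Assessment of Transcription Factor Binding Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks position weight matrix (PWM) models of transcription
    factor binding specificity. Reads motifs in MEME minimal text format,
    builds labeled positive/negative sequence sets from ChIP-seq peaks and a
    genome (centered peak windows, matched downstream negatives, dinucleotide
    shuffled negatives), scores sequences with five scoring functions (GOMER,
    sum/max/average occupancy, Boltzmann binding-energy, log-odds), quantifies
    discriminative power with AUC, MNCP and rank correlations, and ranks
    motifs and motif databases per transcription factor. Includes a synthetic
    fixture generator with known ground truth so the whole pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
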