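Package: seqscrub
Title: Holistic Quality Control and De Novo Contamination Screening for
    Sequencing Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated quality-control chain for next-generation
    sequencing reads. Provides parallel-friendly read trimming and
    filtering (length trimming, low-quality end trimming, quality-fraction
    filtering, exact-duplicate removal, shifted tag/adapter matching with
    mismatches, pair-aware policies) with a conservation-checked summary
    report; de novo contamination screening that combines a qualitative
    rRNA-read taxonomic screen with a quantitative random-subsample
    k-mer classification, including abundance profiles and
    Kullback-Leibler divergence between compositions; removal of reads
    assigned to confirmed contaminant genomes; a deterministic paired-end
    read simulator (uniform substitution errors, fixed insert size,
    species mixtures, artifact injection) that emits per-read ground
    truth; and evaluation metrics (gene-prediction false-positive rate,
    dataset composition tables) plus a configurable end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
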