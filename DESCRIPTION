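Package: seedseq
Title: siRNA Off-Target Prediction and SeedSeq Record Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts sequence-dependent siRNA off-target transcripts by
    combining seed-motif scanning (7mer-m8 and 6-mer sites), windowed
    Smith-Waterman duplex alignment with G:U wobble tolerance, a rule-based
    classifier (near-exact, partial and miRNA-like off-target classes,
    cleavage-site competence) and conservation filtering of seed-matched
    sites. Reads and writes the SeedSeq GenBank dialect that annotates
    transcripts with the siRNAs predicted to off-target them
    (target_siRNAs features), scores predictions against expression-change
    tables from RNAi transfection experiments, and ships a deterministic
    synthetic-data generator with planted sites for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
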