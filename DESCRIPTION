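Package: contamhalf
Title: Contamination-Aware Genome Halving and ANI Reclassification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores contigs of putatively contaminated prokaryotic genomes by
    taxonomic deviation of their gene-level classifications, splits genomes
    into clean and contaminant halves by nucleotide or marker-gene content,
    re-assigns clean halves to species representatives with a MinHash
    prefilter and fragment-based average nucleotide identity, scores
    taxonomy-string congruency from phylum to genus, and aggregates the
    outcomes into taxon-inflation and category summaries. Ships a synthetic
    chimeric-genome generator with known contamination ground truth so the
    whole pipeline is testable without reference downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
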