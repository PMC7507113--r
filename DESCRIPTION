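Package: sagcensus
Title: Co-Sort Detection, Alternative-Code Coding Density, and Respiratory
    Profiling for Single Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cohort-scale quality control and comparative genomics of single
    amplified genomes (SAGs), with an emphasis on the candidate superphyla
    Patescibacteria and DPANN. Provides a synthetic SAG community generator
    with planted two-cell co-sorts and full truth records; detection of
    heterogeneous DNA sources by single-copy marker duplication and by
    discordant 16S rRNA phylum assignments, with chi-square decomposition of
    cohort tables into per-group percent contributions; ORF calling under
    translation tables 11 and 25 with a total-CDS code-selection rule and
    coding density; a naive-Bayes k-mer 16S classifier with bootstrap
    confidence; electron-transport-chain and oxygen-reductase profiling via a
    KO score-threshold rule, Smith-Waterman local alignment and
    Karlin-Altschul e-values; COG-category relative-abundance ordination by
    classical scaling with rank-sum group tests; and cohort reports (plate
    abundances, box statistics, cumulative-completeness effective genomes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
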