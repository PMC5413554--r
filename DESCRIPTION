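Package: plastomics
Title: Comparative Plastome Structure, Syntenic Non-Coding Loci, and Mutational Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparative analysis of annotated plastid genomes:
    detection of the quadripartite structure (inverted repeats, LSC and SSC),
    characterization of IR/SSC junction shifts relative to ycf1, classification
    of ndh gene loss, extraction and synteny grouping of intergenic and intronic
    loci by flanking genes, perfect microsatellite (SSR) scanning and per-genus
    censusing, a pairwise sequence-variability (SV) statistic with DnaSP-style
    indel-event counting, per-genus mutational-hotspot ranking, nonparametric
    association tests (exact Mann-Whitney, Fisher, Spearman), concatenated
    protein-coding supermatrix export with partition files, and a synthetic
    plastome cohort generator with a planted-truth ledger for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
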