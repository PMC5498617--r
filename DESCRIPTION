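Package: wildallele
Title: Detecting Rice Domestication Alleles in Low-Coverage Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens raw low-coverage FASTQ data for causative indel alleles of
    rice domestication genes (Rc, LABA1) by exact-match 30 bp probe words spanning
    the indel junction, verifies candidate reads by free-end-gap pairwise alignment
    against both allele references, and tabulates per-group allele frequencies with
    heterozygote-aware conventions. Also provides a missing-data-weighted
    polymorphism-density statistic in 10 kb windows around a causative mutation,
    diagnostic-SNP haplotype classification (Sh4, PROG1), parsimony pre-processing
    (informative-site filtering, gap-run recoding), and a synthetic cohort
    generator (truth alleles, Poisson-depth reads, SNP matrices with missingness)
    so the whole pipeline is testable without terabyte-scale archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    rlang,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
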