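Package: intronscreen
Title: Comparative Screen for Conserved RNA Structures in Yeast Introns
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering and characterising
    conserved RNA secondary structures inside spliceosomal introns of
    budding yeast. Maps orthologous introns across a panel of fungal
    genomes by translated seed-and-extend search with flank extension and
    nucleotide-level best-hit selection; screens ortholog alignments with
    three independent scorers (thermodynamic z-score against a
    dinucleotide-shuffled null, structure conservation index, and
    compensatory-mutation counts) combined by an intersection rule;
    quantifies intron and CDS expression (RPKM, host-normalised ratios,
    expression-evidence flags) from mapped RNA-seq reads; scores
    exosome association from cross-linking (CRAC) count tables by
    ORF-normalised percentile ranks averaged across experiments; and
    provides phenotype analytics (growth-curve AUC and sigmoid fits,
    serial-transfer competition statistics, delta-delta-Ct fold changes).
    A synthetic-data module generates every input the pipeline consumes,
    with planted ground truth, so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
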