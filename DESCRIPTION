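Package: celldissect
Title: Cellular Dissection of Bulk Skin Transcriptomes and Regulatory
    Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting bulk two-condition (lesional versus
    uninvolved) skin transcriptomes into cell-type-level signals and for
    prioritizing regulatory variants at intergenic susceptibility loci.
    Implements detection-aware paired differential expression with
    cross-study consistency filtering, assignment of genes to candidate
    cell types from a multi-cell-type expression compendium, an area-type
    gene-set enrichment statistic with bootstrap empirical nulls, weighted
    cell-type signature scores per patient, Spearman co-expression
    networks with a knee-based size cutoff, log-odds position-weight-matrix
    scanning with strand merging, semiparametric logistic motif enrichment,
    and classification of risk alleles that engender or abrogate
    transcription-factor motif matches at SNPs in linkage disequilibrium
    with a lead variant. A synthetic-data module generates every input
    with planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    mgcv,
    jsonlite,
    withr,
    generics,
    ape,
    seqinr,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    knitr
Config/testthat/edition: 3
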