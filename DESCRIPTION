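Package: t2tfinish
Title: Genome-Finishing and Repeat-Evolution Toolkit for Telomere-to-Telomere Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the finishing steps of telomere-to-telomere (T2T) plant
    genome assemblies and for the repeat-evolution analyses that follow them:
    detection and read-based patching of terminal telomeric (TTTAGGG)n arrays,
    reconstruction of tandem rDNA (NOR) arrays from unique 19-mer anchors with
    k-mer-depth copy-number estimation, organelle-contig screening and nuclear
    plastid-insertion detection, LTR retrotransposon insertion-time dating via
    T = K/2r and solo:intact ratios, centromere delineation from windowed
    CENH3 ChIP enrichment or CRM retrotransposon density, windowed pairwise
    identity matrices, and cis-regulatory motif enrichment with set
    intersection. Includes a synthetic-genome simulator with exact feature
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
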