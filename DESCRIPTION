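Package: clonekin
Title: Clonal Kinetics of CAR-T Cells from Repertoire, Integration-Site,
    and Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking the clonal behavior of chimeric antigen
    receptor (CAR) T cells after adoptive transfer. Implements TCR-beta
    repertoire diversity and overlap statistics (downsampled Shannon
    entropy, Morisita-Horn overlap, top-clonotype fractions, competition
    rank tracking), conversion of clonotype frequencies to absolute blood
    counts with a three-way kinetic-pattern classifier, a desk-scale
    lentiviral integration-site clone-calling pipeline (LTR/vector read
    filtering, k-mer seeded alignment, consensus grouping and clone
    merging, exon/intron annotation, fold-change site lists), and a
    single-cell clonotype-fate analysis (QC filtering, Fisher exact tests
    with FDR control for increased/decreased relative frequency
    clonotypes, persistence and cluster-attribution summaries). A
    synthetic-data module generates repertoire timelines, integration-site
    reads, and cell tables with planted ground truth so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
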