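Package: litcooc
Title: Literature Co-Occurrence Networks for Genes and Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene and protein mentions in a document corpus by exact,
    synonym-expanded dictionary matching, quantifies co-occurrence at the
    sentence, paragraph and document level, scores gene pairs with mutual
    information, concentration odds ratios and a two-cell Pearson chi-square
    independence test, and builds weighted co-occurrence networks with XML,
    GraphML and TSV exports. Ships a seeded synthetic-corpus generator with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
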