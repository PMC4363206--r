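Package: accminer
Title: Accession-Number Annotation and Data-Citation Mining for Full-Text Articles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based recognition of biomolecular database accession numbers
    (ENA, UniProt, PDBe, InterPro, Pfam, ArrayExpress, OMIM, Ensembl, RefSeq,
    RefSNP) in full-text articles and their supplementary data files. Pattern
    matches are gated by nearby contextual cue words, overlaps are resolved
    deterministically, and annotations can be validated against user-supplied
    accession tables. Includes JATS XML parsing with supplementary-file triage
    and text extraction, precision/recall/F-score evaluation against gold
    annotation tables, corpus-level citation statistics (body versus
    supplementary distributions, shared citations, top-fraction concentration,
    yearly averages), a ground-truthed synthetic corpus generator, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
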