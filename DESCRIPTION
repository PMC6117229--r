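Package: msready
Title: MS-Ready Chemical Structure Standardization and Candidate Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prepares "MS-Ready" chemical structures for non-targeted and
    suspect-screening high-resolution mass spectrometry (HRMS): substance
    records (salts, mixtures, charged species, organometallics) are
    consistency-checked, split into components, desalted against an
    exclusion list, tautomer/mesomer-normalized, neutralized, stripped of
    stereochemistry and deduplicated by standard InChIKey. Substances,
    original structures and MS-Ready components are kept in a linked
    registry supporting exact and MS-Ready molecular-formula and
    monoisotopic-mass searches (single and batch), export of
    MetFrag-compatible candidate files, and additive candidate scoring
    with 0-1 scaled metadata terms and InChIKey first-block grouping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
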