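Package: chimeraforge
Title: Design and In Silico Verification of Chimeric Transcription-Factor Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing combinatorial libraries of chimeric bacterial
    transcription factors built as DBD-(LNK)-LBD-(OD) fusions. Covers the full
    dry-lab workflow: validation of domain collections with codon-aware removal
    of forbidden restriction sites; exhaustive enumeration of fusion genes with
    a canonical, parseable nomenclature; design of Supra/Infra staple
    oligonucleotides for enhanced ligase chain reaction (eLCR) assembly, with
    in silico verification by cycle-wise annealing/ligation simulation and
    Type IIS + USER adapter-processing round trips; grafting of repressor
    operator boxes into a sigma-70 promoter scaffold under hexamer and spacer
    constraints; and mismatch-tolerant classification of junction-spanning
    amplicon reads into per-chimera abundance and enrichment tables. A seeded
    synthetic-fixture generator emulates every input the workflow consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
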