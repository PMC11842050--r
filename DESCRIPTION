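Package: varrag
Title: Retrieval-Augmented Variant Annotation Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A local, model-agnostic retrieval-augmented generation (RAG) engine
    for genetic variant annotation. Normalizes heterogeneous annotation sources
    (ClinVar, gnomAD exomes, SnpEff-annotated VCF, GWAS Catalog, PharmGKB) into a
    five-column searchable document model, builds a BM25-ranked inverted keyword
    index with line-per-document chunking, parses free-text variant queries
    (chromosome:position, dbSNP rsID, gene or condition), assembles grounded
    prompts answered through a pluggable generation adapter (deterministic
    extractive answerer by default), prepares chat-format fine-tuning datasets in
    JSON Lines, and evaluates annotation accuracy with per-field exact matching
    and Jaro-similarity condition matching. Ships a seeded synthetic-data
    generator emulating all five source dialects so every component is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
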