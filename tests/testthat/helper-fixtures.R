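# Shared fixtures: cached synthetic cohorts, and an independent brute-force
# BM25 oracle used to validate index-based retrieval.

.fixture_cache <- new.env(parent = emptyenv())

# Generate (once per test run) a cohort, parse all five dialects and
# normalize. Returns list(dir, paths, records, docs).
cohort_fixture <- function(n = 30, seed = 101, missing_rate = 0.1) {
  key <- paste("cohort", n, seed, missing_rate, sep = "_")
  if (!is.null(.fixture_cache[[key]])) {
    return(.fixture_cache[[key]])
  }
  dir <- file.path(tempdir(), paste0("varrag-", key))
  paths <- simulate_annotation_sources(
    dir,
    n_per_source = n, seed = seed, missing_rate = missing_rate
  )
  records <- lapply(names(paths), function(s) read_annotation_source(paths[[s]], s))
  names(records) <- names(paths)
  docs <- dplyr::bind_rows(lapply(records, normalize_records))
  out <- list(dir = dir, paths = paths, records = records, docs = docs)
  .fixture_cache[[key]] <- out
  out
}

index_fixture <- function(n = 30, seed = 101, missing_rate = 0.1) {
  key <- paste("index", n, seed, missing_rate, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- build_index(cohort_fixture(n, seed, missing_rate)$docs)
  }
  .fixture_cache[[key]]
}

# Independent linear-scan BM25 oracle: re-derives term frequencies, document
# frequencies and length statistics directly from the document table, scores
# every document with the stated formula, and ranks with the score-then-id
# tie-break. Shares only the analyzer with the implementation under test.
oracle_topk <- function(docs, tokens, k, k1 = 1.2, b = 0.75) {
  fields <- c("chrom_pos", "rsid", "gene", "condition", "content")
  n_docs <- nrow(docs)
  scores <- numeric(n_docs)
  for (f in fields) {
    doc_tokens <- lapply(docs[[f]], analyze_text, field = f)
    lens <- lengths(doc_tokens)
    avg_len <- mean(lens)
    if (avg_len == 0) next
    for (t in tokens) {
      tf <- vapply(doc_tokens, function(tk) sum(tk == t), numeric(1))
      df <- sum(tf > 0)
      if (df == 0) next
      idf <- log(1 + (n_docs - df + 0.5) / (df + 0.5))
      denom <- tf + k1 * (1 - b + b * lens / avg_len)
      scores <- scores + ifelse(tf > 0, idf * tf * (k1 + 1) / denom, 0)
    }
  }
  hit <- which(scores > 0)
  ord <- hit[order(-scores[hit], docs$doc_id[hit])]
  head(tibble::tibble(doc_id = docs$doc_id[ord], score = scores[ord]), k)
}

# Reference statement of the condition normalization applied on ingest:
# multi-valued conditions joined with "; ", underscores become spaces.
normalize_condition_ref <- function(x) {
  out <- gsub("_", " ", gsub("|", "; ", x, fixed = TRUE), fixed = TRUE)
  if (is.na(out) || out == "") "NA" else out
}

# A tiny hand-written ClinVar-dialect VCF with fully known values, used for
# parser assertions verified by manual inspection of the lines.
write_mini_clinvar <- function(path, extra_lines = character(0)) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=RS,Number=.,Type=String,Description="dbSNP ID">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t"),
    paste("chr2", "96799611", "3521", "A", "G", ".", ".",
      "ALLELEID=18526;CLNDN=Epilepsy|Seizure_disorder;CLNREVSTAT=reviewed_by_expert_panel;CLNSIG=Pathogenic;CLNSPDI=NC_000002.12:96799610:A:G;GENEINFO=ADRA2B:151;MC=SO:0001583|missense_variant;RS=28371706",
      sep = "\t"
    ),
    paste("chr7", "5986934", "9001", "C", "T", ".", ".",
      "ALLELEID=24001;CLNSIG=Benign",
      sep = "\t"
    ),
    extra_lines
  ), path)
  path
}
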