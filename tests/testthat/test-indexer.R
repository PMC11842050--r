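test_that("the analyzer splits text fields and passes keyword fields through", {
  expect_equal(analyze_text("Cystic-fibrosis", "condition"), c("cystic", "fibrosis"))
  expect_equal(analyze_text("chr2:96799611", "chrom_pos"), "chr2:96799611")
  expect_equal(analyze_text("RS28371706", "rsid"), "rs28371706")
  expect_equal(analyze_text("", "gene"), character(0))
  expect_equal(analyze_text("NA", "condition"), character(0))
  # stopwords removed from condition/content, never from gene
  expect_equal(analyze_text("disease of the lung", "condition"), c("disease", "lung"))
  expect_equal(analyze_text("OR", "gene"), "or")
  # underscores and punctuation are separators too
  expect_equal(
    analyze_text("Long-QT_syndrome 1", "condition"),
    c("long", "qt", "syndrome", "1")
  )
})

test_that("the analyzer is idempotent on its own space-joined output", {
  fix <- cohort_fixture(n = 20, seed = 31)
  for (f in c("gene", "condition", "content")) {
    for (x in head(unique(fix$docs[[f]]), 40)) {
      once <- analyze_text(x, f)
      again <- analyze_text(paste(once, collapse = " "), f)
      expect_identical(again, once)
    }
  }
})

test_that("posting lists have correct document frequencies and sorted postings", {
  docs <- tibble::tibble(
    doc_id = c("a", "b"),
    chrom_pos = c("chr1:10", "chr1:20"),
    rsid = c("rs1", "rs2"),
    gene = c("TP53", "TP53"),
    condition = c("Asthma", "NA"),
    content = c("x=1", "x=2"),
    source_name = "ClinVar", source_url = "NA"
  )
  idx <- build_index(docs)
  # a token unique to one document has df = 1
  asthma <- idx$postings[idx$postings$term == "asthma", ]
  expect_equal(nrow(asthma), 1)
  # a token shared by two documents: posting list of length 2 sorted by doc_id
  shared <- idx$postings[idx$postings$term == "tp53" & idx$postings$field == "gene", ]
  expect_equal(shared$doc_id, c("a", "b"))
  expect_equal(shared$tf, c(1L, 1L))
  # tf equals the number of recorded positions everywhere
  expect_true(all(idx$postings$tf == lengths(idx$postings$positions)))
  # duplicate ids are a build error naming the id
  expect_error(
    build_index(dplyr::bind_rows(docs, docs[1, ])),
    "a",
    class = "varrag_index_error"
  )
})

test_that("BM25 matches its closed form on a single-document corpus", {
  docs <- tibble::tibble(
    doc_id = "d1", chrom_pos = "chr1:10", rsid = "NA", gene = "BRCA1",
    condition = "NA", content = "NA", source_name = "ClinVar", source_url = "NA"
  )
  idx <- build_index(docs)
  # N = 1, df = 1: idf = ln(1 + (1 - 1 + 0.5)/(1 + 0.5)) = ln(4/3); with
  # tf = 1 and len = avglen the tf factor is (k1+1)/(1+k1) = 1
  expect_equal(score_document(idx, "brca1", "d1"), log(4 / 3))
  # absent terms contribute zero
  expect_equal(score_document(idx, "absent", "d1"), 0)
  expect_equal(score_document(idx, c("brca1", "absent"), "d1"), log(4 / 3))
})

test_that("scores are non-decreasing in term frequency, all else fixed", {
  docs <- tibble::tibble(
    doc_id = c("low", "mid", "high"),
    chrom_pos = paste0("chr1:", 1:3), rsid = "NA", gene = "NA",
    condition = c("alpha beta gamma", "alpha alpha beta", "alpha alpha alpha"),
    content = "NA", source_name = "ClinVar", source_url = "NA"
  )
  idx <- build_index(docs)
  s <- vapply(c("low", "mid", "high"), function(d) score_document(idx, "alpha", d), numeric(1))
  expect_true(s[["low"]] < s[["mid"]], )
  expect_true(s[["mid"]] < s[["high"]])
})

test_that("every document is retrieved at rank 1 by its own chromosome:position key", {
  # 1,000 documents across the four sources with distinct coordinates
  fix <- cohort_fixture(n = 250, seed = 77)
  docs <- fix$docs[fix$docs$source_name != "SnpEff", ]
  expect_equal(nrow(docs), 1000)
  idx <- build_index(docs)
  for (i in seq_len(nrow(docs))) {
    res <- search_index(idx, docs$chrom_pos[i], k = 3)
    expect_identical(res$doc_id[1], docs$doc_id[i])
    expect_true(res$exact[1])
  }
  # SnpEff re-annotates ClinVar coordinates: both land in the exact block
  full_idx <- index_fixture(n = 250, seed = 77)
  cv <- fix$docs[fix$docs$source_name == "ClinVar", ][1, ]
  res <- search_index(full_idx, cv$chrom_pos, k = 5)
  expect_setequal(res$source_name[res$exact], c("ClinVar", "SnpEff"))
  expect_equal(res$chrom_pos[1], cv$chrom_pos)
})

test_that("the chunk writer respects the size bound and concatenates losslessly", {
  # documents whose serialized CSV lines are exactly 1,000 characters
  base <- tibble::tibble(
    doc_id = sprintf("doc-%02d", 1:10),
    chrom_pos = sprintf("chr1:%d", 1:10),
    rsid = "NA", gene = "NA", condition = "NA",
    content = "", source_name = "ClinVar", source_url = "NA"
  )
  line_len <- nchar(strsplit(readr::format_csv(base[1, ]), "\n")[[1]][2])
  base$content <- strrep("x", 999 - line_len) # + newline = 1,000 per line
  out <- withr::local_tempdir()
  paths <- write_chunked_csv(base, out, max_chars = 3500)
  # greedy fill: 3 + 3 + 3 + 1
  expect_length(paths, 4)
  sizes <- vapply(paths, function(p) length(readr::read_lines(p)) - 1L, integer(1))
  expect_equal(unname(sizes), c(3L, 3L, 3L, 1L))
  expect_true(all(file.size(paths) < 3500))

  # concatenation with headers removed after the first reproduces the input
  lines <- unlist(lapply(paths, function(p) readr::read_lines(p)[-1]))
  header <- readr::read_lines(paths[1])[1]
  round_trip <- readr::read_csv(
    I(paste(c(header, lines), collapse = "\n")),
    col_types = readr::cols(.default = "c"), na = character()
  )
  expect_equal(as.data.frame(round_trip), as.data.frame(base))

  # a single line at or over the bound is an error naming the document
  expect_error(
    write_chunked_csv(base, out, max_chars = 900),
    "doc-01",
    class = "varrag_chunk_error"
  )
  # everything fits: exactly one file
  expect_length(write_chunked_csv(base, withr::local_tempdir(), max_chars = 4e6), 1)
})

test_that("a persisted index round-trips bit-exactly and rebuilds from its chunks", {
  idx <- index_fixture(n = 30, seed = 101)
  dir <- withr::local_tempdir()
  write_index(idx, dir, max_chars = 6000)
  expect_true(length(list.files(dir, pattern = "^documents-")) > 1)
  back <- read_index(dir)
  expect_equal(back$docs, idx$docs)
  expect_equal(back$postings, idx$postings)
  expect_equal(back$doc_lengths, idx$doc_lengths)
  expect_equal(back$avg_field_length, idx$avg_field_length)
  expect_equal(back$doc_count, idx$doc_count)
  # rebuilding the index from the persisted chunked CSV gives the same index
  rebuilt <- build_index(read_document_chunks(
    list.files(dir, pattern = "^documents-", full.names = TRUE)
  ))
  expect_equal(rebuilt$postings, idx$postings)
})

test_that("index statistics are conserved", {
  idx <- index_fixture(n = 30, seed = 101)
  n_docs <- idx$doc_count
  df_by_term <- idx$postings |>
    dplyr::count(term, field, name = "df")
  expect_true(all(df_by_term$df <= n_docs))
  # per-field token totals agree between postings and length statistics
  by_post <- idx$postings |>
    dplyr::group_by(field) |>
    dplyr::summarise(total = sum(tf))
  by_len <- idx$doc_lengths |>
    dplyr::group_by(field) |>
    dplyr::summarise(total = sum(len))
  expect_equal(
    dplyr::arrange(by_post, field),
    dplyr::arrange(by_len, field) |> dplyr::filter(total > 0)
  )
})
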