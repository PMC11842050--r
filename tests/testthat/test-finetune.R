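# A dedicated ClinVar pool large enough for the default 3000/1000 split.
finetune_pool <- function() {
  if (is.null(.fixture_cache[["ft_pool"]])) {
    dir <- file.path(tempdir(), "varrag-ft-pool")
    paths <- simulate_annotation_sources(
      dir,
      n_per_source = 6000, seed = 2024, missing_rate = 0
    )
    .fixture_cache[["ft_pool"]] <- read_annotation_source(paths$ClinVar, "ClinVar")
  }
  .fixture_cache[["ft_pool"]]
}

test_that("the default split yields 3000 disjoint training and 1000 validation variants", {
  recs <- finetune_pool()
  ex <- build_finetune_examples(recs, mode = "full13", seed = 9)
  expect_equal(nrow(ex$train), 3000)
  expect_equal(nrow(ex$valid), 1000)
  # train/valid disjoint at the variant level, under several seeds
  for (s in c(9, 10, 77)) {
    e <- build_finetune_examples(recs, mode = "full13", seed = s)
    expect_length(intersect(e$train$variant_key, e$valid$variant_key), 0)
  }
  # same seed reproduces the same split
  again <- build_finetune_examples(recs, mode = "full13", seed = 9)
  expect_identical(again$train$user, ex$train$user)
})

test_that("full-annotation examples embed the variant key and 13 name: value lines", {
  recs <- finetune_pool()
  ex <- build_finetune_examples(recs, mode = "full13", n_train = 20, n_valid = 5, seed = 3)
  for (i in seq_len(nrow(ex$train))) {
    expect_match(ex$train$user[i], "chr[0-9XYM]+:[0-9]+")
    expect_true(grepl(ex$train$variant_key[i], ex$train$user[i], fixed = TRUE))
    lines <- strsplit(ex$train$assistant[i], "\n", fixed = TRUE)[[1]]
    expect_length(lines, 13)
    expect_identical(
      vapply(strsplit(lines, ": ", fixed = TRUE), `[[`, character(1), 1),
      source_fields("ClinVar")
    )
  }
})

test_that("single-field modes answer with only that field's value", {
  recs <- finetune_pool()
  ex <- build_finetune_examples(recs, mode = "gene", n_train = 10, n_valid = 0, seed = 3)
  keys <- ex$train$variant_key
  genes <- vapply(
    seq_along(keys),
    function(i) {
      r <- recs[paste0(recs$chrom, ":", recs$pos) == keys[i], ]
      r$fields[[1]][["gene"]]
    },
    character(1)
  )
  expect_identical(ex$train$assistant, genes)

  # rsID mode through the codebook: a single pronounceable word, decodable
  cb <- make_rsid_codebook(recs$rsid, seed = 5)
  exr <- build_finetune_examples(
    recs,
    mode = "rsid", n_train = 10, n_valid = 0, seed = 3, codebook = cb
  )
  expect_true(all(grepl("^[a-z]+$", exr$train$assistant)))
  rs_truth <- vapply(
    exr$train$variant_key,
    function(k) recs$rsid[paste0(recs$chrom, ":", recs$pos) == k],
    character(1), USE.NAMES = FALSE
  )
  expect_identical(decode_rsid(exr$train$assistant, cb), rs_truth)
})

test_that("a 300-gene, 10-variants-per-gene pool yields 3000 gene-mode examples", {
  # a cohort deep enough that all 300 pool genes accumulate 10 variants
  paths <- simulate_annotation_sources(
    file.path(tempdir(), "varrag-ft-genes"),
    n_per_source = 7500, seed = 424, missing_rate = 0
  )
  recs <- read_annotation_source(paths$ClinVar, "ClinVar")
  by_gene <- split(
    seq_len(nrow(recs)),
    vapply(recs$fields, `[[`, character(1), "gene")
  )
  by_gene <- by_gene[names(by_gene) != "NA"]
  by_gene <- by_gene[lengths(by_gene) >= 10]
  expect_gte(length(by_gene), 300)
  idx <- unlist(lapply(by_gene[seq_len(300)], head, 10))
  pool <- structure(
    recs[idx, ],
    rejects = NULL, class = class(recs)
  )
  expect_equal(nrow(pool), 3000)
  ex <- build_finetune_examples(pool, mode = "gene", n_train = 3000, n_valid = 0, seed = 1)
  expect_equal(nrow(ex$train), 3000)
})

test_that("the repeats knob duplicates training examples only", {
  recs <- finetune_pool()
  ex <- build_finetune_examples(
    recs,
    mode = "gene", n_train = 30, n_valid = 10, seed = 3, repeats = 10
  )
  expect_equal(nrow(ex$train), 300)
  expect_equal(nrow(ex$valid), 10)
  expect_equal(as.integer(table(ex$train$variant_key)), rep(10L, 30))
})

test_that("gene_condition mode skips records missing both fields with a warning", {
  recs <- finetune_pool()[1:20, ]
  blank <- recs$fields[[1]]
  blank[["gene"]] <- "NA"
  blank[["condition"]] <- "NA"
  recs$fields[[1]] <- blank
  expect_warning(
    ex <- build_finetune_examples(recs, mode = "gene_condition", n_train = 19, n_valid = 0, seed = 1),
    "skipped"
  )
  expect_equal(ex$n_skipped, 1)
  expect_equal(nrow(ex$train), 19)
})

test_that("an oversubscribed split is an error", {
  recs <- finetune_pool()[1:50, ]
  expect_error(
    build_finetune_examples(recs, n_train = 40, n_valid = 20, seed = 1),
    "50",
    class = "varrag_finetune_error"
  )
})

test_that("written JSONL validates, round-trips, and records hyperparameters", {
  recs <- finetune_pool()
  ex <- build_finetune_examples(recs, mode = "full13", n_train = 40, n_valid = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_finetune_jsonl(ex$train, path)

  report <- validate_jsonl(path)
  expect_true(report$valid)
  expect_equal(report$n_lines, 40)
  expect_equal(nrow(report$violations), 0)
  expect_equal(report$n_duplicate_users, 0)

  # serialization round trip
  lines <- readr::read_lines(path)
  first <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  expect_equal(first$messages[[1]]$content, ex$train$system[[1]])
  expect_equal(first$messages[[2]]$content, ex$train$user[[1]])
  expect_equal(first$messages[[3]]$content, ex$train$assistant[[1]])

  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$hyperparameters$batch_size, 6)
  expect_equal(meta$hyperparameters$n_epochs, 3)
  expect_equal(meta$hyperparameters$learning_rate_multiplier, 1)
})

test_that("the validator pinpoints malformed lines and accepts empty files", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- '{"messages":[{"role":"system","content":"s"},{"role":"user","content":"u"},{"role":"assistant","content":"a"}]}'
  writeLines(c(good, substr(good, 1, 40), good), path)
  report <- validate_jsonl(path)
  expect_false(report$valid)
  expect_equal(report$violations$line, 2L)

  wrong_roles <- sub("assistant", "tool", good, fixed = TRUE)
  writeLines(c(good, wrong_roles), path)
  expect_equal(validate_jsonl(path)$violations$line, 2L)

  writeLines(character(0), path)
  empty <- validate_jsonl(path)
  expect_true(empty$valid)
  expect_equal(empty$n_lines, 0)
})

test_that("the rsID codebook is deterministic, collision-free and invertible", {
  rs <- paste0("rs", sample.int(9e7, 10000))
  cb <- make_rsid_codebook(rs, seed = 4)
  expect_equal(nrow(cb), length(unique(rs)))
  # 10,000 distinct rsIDs map to 10,000 distinct words
  expect_equal(anyDuplicated(cb$word), 0)
  expect_identical(decode_rsid(encode_rsid(rs, cb), cb), rs)
  expect_identical(encode_rsid("rs28371706", make_rsid_codebook(c(rs, "rs28371706"), seed = 4)),
    encode_rsid("rs28371706", make_rsid_codebook(c(rs, "rs28371706"), seed = 4)))
  # same rsid, same codebook, two calls: same word
  expect_identical(encode_rsid(rs[1], cb), encode_rsid(rs[1], cb))

  # exhaustion reports the required capacity
  expect_error(
    make_rsid_codebook(paste0("rs", 1:100), seed = 1, n_syllables = 1),
    "codebook exhausted",
    class = "varrag_codebook_error"
  )
  expect_error(make_rsid_codebook("rsX"), class = "varrag_codebook_error")
  expect_error(encode_rsid("rs0", cb), class = "varrag_codebook_error")
})
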