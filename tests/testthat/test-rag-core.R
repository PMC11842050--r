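test_that("generation parameter defaults match the evaluation settings", {
  p <- generation_params()
  expect_equal(p$max_tokens, 1600)
  expect_equal(p$temperature, 0)
  expect_equal(p$top_p, 0.5)
  expect_error(generation_params(top_p = 0))
})

# a free-text query guaranteed to match at least three fixture documents
multi_hit_query <- function(idx) {
  genes <- unique(idx$docs$gene[idx$docs$gene != "NA"])
  paste("Provide all the annotations for", paste(genes[1:3], collapse = " "))
}

test_that("prompts contain the user text verbatim and context blocks in rank order", {
  idx <- index_fixture(n = 30, seed = 101)
  q <- multi_hit_query(idx)
  res <- search_index(idx, q, k = 3)
  expect_gte(nrow(res), 3)
  bundle <- assemble_prompt(q, res, char_budget = 50000)
  expect_length(bundle$context_blocks, nrow(res))
  expect_true(grepl(q, bundle$assembled, fixed = TRUE))
  pos <- vapply(
    bundle$context_blocks,
    function(b) regexpr(b, bundle$assembled, fixed = TRUE)[1], numeric(1)
  )
  expect_true(all(diff(pos) > 0))
  expect_lte(nchar(bundle$assembled), bundle$char_budget)
})

test_that("zero retrieved results produce the no-records marker", {
  idx <- index_fixture(n = 30, seed = 101)
  res <- search_index(idx, "rs999999999")
  bundle <- assemble_prompt("rs999999999", res)
  expect_match(bundle$assembled, "No records retrieved", fixed = TRUE)
  expect_match(bundle$assembled, "rs999999999", fixed = TRUE)
})

test_that("over-budget prompts drop lowest-ranked blocks first", {
  idx <- index_fixture(n = 30, seed = 101)
  q <- multi_hit_query(idx)
  res <- head(search_index(idx, q, k = 3), 3)
  full <- assemble_prompt(q, res, char_budget = 100000)
  floor_len <- nchar(full$assembled) -
    sum(nchar(full$context_blocks)) - 2 * length(full$context_blocks)
  # budget that admits exactly the first two blocks
  budget <- floor_len + nchar(full$context_blocks[1]) + nchar(full$context_blocks[2]) + 4
  trimmed <- assemble_prompt(q, res, char_budget = budget)
  expect_identical(trimmed$context_blocks, full$context_blocks[1:2])
  expect_false(grepl(full$context_blocks[3], trimmed$assembled, fixed = TRUE))
  # a budget below system + user is an error
  expect_error(
    assemble_prompt(q, res, char_budget = 50),
    class = "varrag_budget_error"
  )
})

test_that("extractive answers copy fields verbatim from exact-hit documents", {
  idx <- index_fixture(n = 30, seed = 101)
  cv <- idx$docs[idx$docs$source_name == "ClinVar" & idx$docs$gene != "NA", ][1, ]

  gene_q <- sprintf(
    "Provide corresponding gene name for variant %s in GRCh38. Only reply with the gene name.",
    cv$chrom_pos
  )
  out <- answer_query(gene_q, idx)
  expect_identical(out$answer, cv$gene)

  # all-annotations on a ClinVar document: the 13 fields plus provenance
  full_q <- sprintf("Provide all the annotations for variant %s in GRCh38.", cv$chrom_pos)
  intent <- parse_query(full_q)
  res <- search_index(idx, intent, k = 5)
  ans <- extractive_answer(intent, res)
  cv_rows <- ans[ans$source_name == "ClinVar" & !is.na(ans$source_name), ]
  expect_identical(
    cv_rows$field,
    c(source_fields("ClinVar"), "source_name", "source_url")
  )
  expect_identical(
    setNames(cv_rows$value[seq_len(13)], cv_rows$field[seq_len(13)]),
    document_fields(cv)
  )
})

test_that("unmatched keys and empty retrievals answer with the not-found sentinel", {
  idx <- index_fixture(n = 30, seed = 101)
  out <- answer_query("Provide corresponding gene name for variant rs999999999.", idx)
  expect_identical(out$answer, "not found")
  empty <- extractive_answer(parse_query("zzzz"), search_index(idx, "zzzz"))
  expect_identical(empty$value, "not found")
  expect_identical(empty$field, "all-annotations")
})

test_that("the adapter contract behaves: echo identity, determinism, failure propagation", {
  idx <- index_fixture(n = 30, seed = 101)
  q <- sprintf("Provide all the annotations for variant %s in GRCh38.", idx$docs$chrom_pos[1])
  res <- search_index(idx, q, k = 5)
  bundle <- assemble_prompt(q, res)

  # echo adapter returns the assembled prompt itself
  expect_identical(generate(bundle, adapter_echo()), bundle$assembled)
  # the default adapter is deterministic
  expect_identical(generate(bundle), generate(bundle))
  # adapter errors propagate with the prompt hash
  boom <- function(prompt, params) stop("backend unavailable")
  err <- tryCatch(generate(bundle, boom), error = identity)
  expect_s3_class(err, "varrag_adapter_error")
  expect_match(conditionMessage(err), "prompt hash [0-9a-f]+")
  expect_match(conditionMessage(err), "backend unavailable")
})

test_that("the extractive adapter equals direct extraction from the search results", {
  idx <- index_fixture(n = 30, seed = 101)
  docs <- idx$docs
  queries <- c(
    sprintf("Provide all the annotations for variant %s in GRCh38.", docs$chrom_pos[c(2, 33, 71)]),
    sprintf(
      "Provide corresponding gene name for variant %s in GRCh38. Only reply with the gene name.",
      docs$rsid[docs$rsid != "NA"][1]
    ),
    "What is known about TP53?"
  )
  for (q in queries) {
    intent <- parse_query(q)
    res <- search_index(idx, intent, k = 5)
    bundle <- assemble_prompt(intent, res, char_budget = 50000)
    expect_identical(
      generate(bundle, adapter_extractive()),
      render_answer(extractive_answer(intent, res)),
      label = q
    )
  }
})

test_that("extractive answers are grounded: every value occurs in a retrieved document", {
  idx <- index_fixture(n = 40, seed = 19)
  docs <- idx$docs
  for (key in c(docs$chrom_pos[c(1, 50, 120)], docs$rsid[docs$rsid != "NA"][c(1, 9)])) {
    intent <- parse_query(sprintf("Provide all the annotations for variant %s.", key))
    res <- search_index(idx, intent, k = 5)
    ans <- extractive_answer(intent, res)
    retrieved_values <- unlist(c(
      lapply(seq_len(nrow(res)), function(i) document_fields(res[i, ])),
      res$source_name, res$source_url
    ))
    expect_true(all(ans$value %in% retrieved_values), label = key)
  }
})

test_that("a command adapter pipes the prompt through an external process", {
  skip_on_os("windows")
  idx <- index_fixture(n = 30, seed = 101)
  q <- "Provide all the annotations for variant rs999999999."
  bundle <- assemble_prompt(q, search_index(idx, q))
  out <- generate(bundle, adapter_command("cat"))
  expect_identical(out, bundle$assembled)
})
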