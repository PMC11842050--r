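# The inverted keyword index over the five searchable columns, Okapi BM25
# scoring, the size-bounded chunked CSV document store, and the versioned
# on-disk index layout.

#' Build an inverted keyword index over normalized documents
#'
#' Tokenizes every searchable column of every document with [analyze_text()]
#' and builds field-scoped posting lists (term frequency plus token offsets,
#' postings sorted by `doc_id`) together with the corpus statistics BM25
#' scoring needs: document count, per-document field lengths, and mean field
#' lengths.
#'
#' @param documents document tibble from [normalize_records()]; `doc_id` must
#'   be unique.
#' @param k1,b BM25 shape parameters (term-frequency saturation and length
#'   normalization).
#' @param boosts named numeric vector of per-field score multipliers over the
#'   five searchable columns; defaults to 1 everywhere.
#' @return an object of class `varrag_index`.
#' @examples
#' docs <- triage_fixture()$documents
#' idx <- build_index(docs)
#' @export
build_index <- function(documents, k1 = 1.2, b = 0.75, boosts = NULL) {
  stopifnot(all(varrag_searchable_columns %in% names(documents)))
  dup <- documents$doc_id[duplicated(documents$doc_id)]
  if (length(dup)) {
    stop_varrag(
      paste0("duplicate doc_id(s): ", paste(unique(dup), collapse = ", ")),
      "varrag_index_error"
    )
  }
  default_boosts <- setNames(
    rep(1, length(varrag_searchable_columns)), varrag_searchable_columns
  )
  if (!is.null(boosts)) default_boosts[names(boosts)] <- boosts

  tok_tbl <- map(varrag_searchable_columns, function(f) {
    toks <- analyze_column(documents[[f]], f)
    n_tok <- lengths(toks)
    tibble(
      doc_id = rep(documents$doc_id, n_tok),
      field = f,
      term = as.character(unlist(toks)),
      position = unlist(lapply(n_tok, seq_len), use.names = FALSE) %||% integer(0)
    )
  }) |> list_rbind()

  postings <- tok_tbl |>
    group_by(.data$term, .data$field, .data$doc_id) |>
    summarise(
      tf = dplyr::n(),
      positions = list(.data$position),
      .groups = "drop"
    ) |>
    arrange(.data$term, .data$field, .data$doc_id)

  stats <- index_stats(postings, documents$doc_id)
  structure(
    list(
      docs = documents,
      postings = postings,
      doc_count = nrow(documents),
      doc_lengths = stats$doc_lengths,
      avg_field_length = stats$avg_field_length,
      k1 = k1, b = b, boosts = default_boosts,
      analyzer_version = varrag_analyzer_version
    ),
    class = "varrag_index"
  )
}

# Field-length statistics are fully recomputable from the postings: the token
# count of a (doc, field) is the sum of its term frequencies.
index_stats <- function(postings, doc_ids) {
  grid <- tidyr::expand_grid(
    doc_id = doc_ids, field = varrag_searchable_columns
  )
  lens <- postings |>
    group_by(.data$doc_id, .data$field) |>
    summarise(len = sum(.data$tf), .groups = "drop")
  doc_lengths <- grid |>
    left_join(lens, by = c("doc_id", "field")) |>
    mutate(len = as.integer(ifelse(is.na(.data$len), 0L, .data$len))) |>
    arrange(.data$doc_id, .data$field)
  avg_field_length <- doc_lengths |>
    group_by(.data$field) |>
    summarise(avg_len = mean(.data$len), .groups = "drop") |>
    arrange(.data$field)
  list(doc_lengths = doc_lengths, avg_field_length = avg_field_length)
}

#' @export
print.varrag_index <- function(x, ...) {
  cat(sprintf(
    "<varrag_index> %d documents, %d postings, analyzer v%s (BM25 k1=%g, b=%g)\n",
    x$doc_count, nrow(x$postings), x$analyzer_version, x$k1, x$b
  ))
  src <- table(x$docs$source_name)
  cat("  sources:", paste(sprintf("%s=%d", names(src), src), collapse = ", "), "\n")
  invisible(x)
}

# BM25 scores of all documents matching at least one query token.
# idf(t) = ln(1 + (N - df + 0.5) / (df + 0.5)) with per-(term, field) df;
# per-field contribution idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len/avglen)).
score_tokens <- function(index, tokens) {
  if (length(tokens) == 0 || nrow(index$postings) == 0) {
    return(tibble(doc_id = character(0), score = numeric(0)))
  }
  q <- tibble(term = tokens)
  hits <- q |>
    inner_join(index$postings, by = "term", relationship = "many-to-many")
  if (nrow(hits) == 0) {
    return(tibble(doc_id = character(0), score = numeric(0)))
  }
  df_tbl <- index$postings |>
    semi_join(q, by = "term") |>
    count(.data$term, .data$field, name = "df")
  n_docs <- index$doc_count
  k1 <- index$k1
  b <- index$b
  boosts <- tibble(
    field = names(index$boosts), boost = unname(index$boosts)
  )
  hits |>
    left_join(df_tbl, by = c("term", "field")) |>
    left_join(index$doc_lengths, by = c("doc_id", "field")) |>
    left_join(index$avg_field_length, by = "field") |>
    left_join(boosts, by = "field") |>
    mutate(
      idf = log(1 + (n_docs - .data$df + 0.5) / (.data$df + 0.5)),
      denom = .data$tf + k1 * (1 - b + b * .data$len / .data$avg_len),
      contrib = .data$boost * .data$idf * .data$tf * (k1 + 1) / .data$denom
    ) |>
    group_by(.data$doc_id) |>
    summarise(score = sum(.data$contrib), .groups = "drop")
}

#' BM25 relevance score of one document for a token list
#'
#' The Okapi BM25 score summed over query tokens and the five searchable
#' fields. Tokens absent from the document contribute zero; holding all else
#' fixed the score is non-decreasing in term frequency.
#'
#' @param index a `varrag_index`.
#' @param query_tokens character vector of analyzed query tokens.
#' @param doc_id document identifier.
#' @return a non-negative number.
#' @export
score_document <- function(index, query_tokens, doc_id) {
  s <- score_tokens(index, query_tokens)
  hit <- s$score[s$doc_id == doc_id]
  if (length(hit)) hit else 0
}

#' Write documents as size-bounded CSV chunks
#'
#' Serializes the document table as RFC-4180 CSV and splits it greedily into
#' files each strictly smaller than `max_chars` characters (the default bound
#' is 4,000,000). Every chunk carries the header row; no document line is
#' split across files, and concatenating the chunks (dropping headers after
#' the first) reproduces the document set exactly.
#'
#' @param documents document tibble.
#' @param out_dir output directory (created if needed).
#' @param max_chars exclusive per-file character bound; must exceed the
#'   longest single line.
#' @param prefix chunk filename prefix.
#' @return character vector of chunk file paths.
#' @export
write_chunked_csv <- function(documents, out_dir, max_chars = 4e6,
                              prefix = "documents") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- readr::format_csv(documents, na = "")
  lines <- strsplit(csv, "\n", fixed = TRUE)[[1]]
  header <- lines[1]
  body <- lines[-1]
  body <- body[nzchar(body)]
  hdr_chars <- nchar(header) + 1L # trailing newline

  chunks <- list()
  cur <- character(0)
  cur_chars <- hdr_chars
  flush <- function() {
    if (length(cur) || length(chunks) == 0) {
      chunks[[length(chunks) + 1]] <<- cur
    }
    cur <<- character(0)
    cur_chars <<- hdr_chars
  }
  for (i in seq_along(body)) {
    line_chars <- nchar(body[i]) + 1L
    if (hdr_chars + line_chars >= max_chars) {
      stop_varrag(
        sprintf(
          "document %s serializes to %d characters and cannot fit under max_chars = %s",
          documents$doc_id[i], line_chars, format(max_chars, scientific = FALSE)
        ),
        "varrag_chunk_error"
      )
    }
    if (cur_chars + line_chars >= max_chars && length(cur)) flush()
    cur <- c(cur, body[i])
    cur_chars <- cur_chars + line_chars
  }
  flush()

  paths <- vapply(seq_along(chunks), function(i) {
    p <- file.path(out_dir, sprintf("%s-%05d.csv", prefix, i))
    readr::write_lines(c(header, chunks[[i]]), p)
    p
  }, character(1))
  paths
}

read_document_chunks <- function(paths) {
  docs <- map(paths, function(p) {
    readr::read_csv(
      p,
      col_types = readr::cols(.default = readr::col_character()),
      na = character(), show_col_types = FALSE, progress = FALSE
    )
  }) |> list_rbind()
  as_tibble(as.data.frame(docs, check.names = FALSE, stringsAsFactors = FALSE))
}

#' Persist an index to a versioned on-disk layout
#'
#' Writes the document store as chunked CSV (see [write_chunked_csv()]), the
#' posting lists as CSV, and a JSON manifest recording the document count,
#' per-source counts, field statistics, analyzer version, BM25 parameters and
#' an MD5 content hash of the document chunks. [read_index()] restores an
#' identical index (statistics are recomputed from the postings).
#'
#' @param index a `varrag_index`.
#' @param dir target directory.
#' @param max_chars chunk size bound passed to [write_chunked_csv()].
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir, max_chars = 4e6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chunk_paths <- write_chunked_csv(index$docs, dir, max_chars = max_chars)
  postings_flat <- index$postings |>
    mutate(positions = map_chr(.data$positions, paste, collapse = " "))
  readr::write_csv(postings_flat, file.path(dir, "postings.csv"), na = "")

  src_counts <- as.list(table(index$docs$source_name))
  manifest <- list(
    format_version = 1L,
    doc_count = index$doc_count,
    source_counts = src_counts,
    analyzer_version = index$analyzer_version,
    k1 = index$k1, b = index$b,
    boosts = as.list(index$boosts),
    avg_field_length = setNames(
      as.list(index$avg_field_length$avg_len), index$avg_field_length$field
    ),
    chunks = basename(chunk_paths),
    chunks_md5 = unname(tools::md5sum(chunk_paths))
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Load a persisted index
#'
#' @param dir directory written by [write_index()].
#' @return a `varrag_index` identical to the one written.
#' @export
read_index <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_varrag(sprintf("no index manifest at %s", manifest_path), "varrag_io_error")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  docs <- read_document_chunks(file.path(dir, manifest$chunks))
  if (nrow(docs) != manifest$doc_count) {
    stop_varrag(
      sprintf(
        "index manifest declares %d documents but chunks contain %d",
        manifest$doc_count, nrow(docs)
      ),
      "varrag_io_error"
    )
  }
  postings <- readr::read_csv(
    file.path(dir, "postings.csv"),
    col_types = readr::cols(
      term = readr::col_character(), field = readr::col_character(),
      doc_id = readr::col_character(), tf = readr::col_integer(),
      positions = readr::col_character()
    ),
    na = character(), show_col_types = FALSE, progress = FALSE
  ) |>
    mutate(positions = map(
      strsplit(.data$positions, " ", fixed = TRUE), as.integer
    )) |>
    arrange(.data$term, .data$field, .data$doc_id)
  postings <- as_tibble(postings)
  stats <- index_stats(postings, docs$doc_id)
  structure(
    list(
      docs = docs,
      postings = postings,
      doc_count = nrow(docs),
      doc_lengths = stats$doc_lengths,
      avg_field_length = stats$avg_field_length,
      k1 = manifest$k1, b = manifest$b,
      boosts = unlist(manifest$boosts),
      analyzer_version = as.character(manifest$analyzer_version)
    ),
    class = "varrag_index"
  )
}

# Content hash of an index directory's manifest, for run logging.
index_manifest_hash <- function(dir) {
  unname(tools::md5sum(file.path(dir, "manifest.json")))
}
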