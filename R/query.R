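# Free-text query parsing into structured search intents, and ranked
# retrieval with exact-keyword precedence.

# Instruction vocabulary stripped from residual query text before gene- and
# condition-term extraction.
query_noise_words <- c(
  "provide", "corresponding", "name", "names", "variant", "variants", "only",
  "reply", "with", "the", "for", "in", "grch38", "annotation", "annotations",
  "gene", "genes", "condition", "conditions", "disease", "diseases",
  "phenotype", "phenotypes", "what", "which", "is", "are", "of", "please",
  "list", "give", "tell", "me", "about", "all", "full", "a", "an", "and",
  "to", "dbsnp", "rsid", "id"
)

#' Parse a free-text query into a structured search intent
#'
#' Pattern-extracts chromosome:position keys (tolerating `"chr2: 96799611"`
#' spacing, a missing or capitalized `"chr"` prefix) and dbSNP rsIDs, infers
#' the requested fields from keyword cues (`"gene"`, `"condition"`/
#' `"disease"`/`"phenotype"`; `"annotation"` or no cue means all annotations),
#' and classifies the residual words: capitalized symbol-like tokens become
#' gene terms, the remaining words a condition phrase. An intent with all
#' lists empty is valid.
#'
#' @param text the query string.
#' @return an object of class `varrag_intent` with elements `raw`,
#'   `chrom_pos_keys`, `rsids`, `gene_terms`, `condition_terms`,
#'   `requested_fields`.
#' @examples
#' parse_query("Provide corresponding gene name for variant chr2:96799611 in GRCh38.")
#' parse_query("rs28371706")
#' @export
parse_query <- function(text) {
  raw <- if (length(text) == 0 || is.na(text)) "" else as.character(text)
  residual <- raw

  cp <- str_match_all(
    raw,
    regex("\\b(?:chr)?([0-9]{1,2}|[XY]|MT?)\\s*:\\s*([0-9]+)\\b", ignore_case = TRUE)
  )[[1]]
  chrom_pos_keys <- character(0)
  if (nrow(cp)) {
    chroms <- normalize_chrom(cp[, 2])
    ok <- !is.na(chroms)
    chrom_pos_keys <- unique(paste0(chroms[ok], ":", as.integer(cp[ok, 3])))
    for (m in cp[, 1]) residual <- sub(m, " ", residual, fixed = TRUE)
  }

  rs <- unlist(str_extract_all(residual, regex("\\brs[0-9]+\\b", ignore_case = TRUE)))
  rsids <- unique(str_to_lower(rs))
  for (m in rs) residual <- sub(m, " ", residual, fixed = TRUE)

  lower <- str_to_lower(raw)
  requested <- character(0)
  if (str_detect(lower, "\\bgene")) requested <- c(requested, "gene")
  if (str_detect(lower, "\\bcondition|\\bdisease|\\bphenotype")) {
    requested <- c(requested, "condition")
  }
  if (str_detect(lower, "\\bannotation") || length(requested) == 0) {
    requested <- c(requested, "all-annotations")
  }

  words <- strsplit(residual, "[^A-Za-z0-9-]+")[[1]]
  words <- words[nzchar(words)]
  words <- words[!str_to_lower(words) %in% query_noise_words]
  is_gene <- str_detect(words, "^[A-Z][A-Z0-9-]{1,9}$")
  gene_terms <- unique(words[is_gene])
  cond_words <- str_to_lower(words[!is_gene])
  condition_terms <- if (length(cond_words)) paste(cond_words, collapse = " ") else character(0)

  structure(
    list(
      raw = raw,
      chrom_pos_keys = chrom_pos_keys,
      rsids = rsids,
      gene_terms = gene_terms,
      condition_terms = condition_terms,
      requested_fields = requested
    ),
    class = "varrag_intent"
  )
}

#' @export
print.varrag_intent <- function(x, ...) {
  cat("<varrag_intent>\n")
  cat("  raw:", x$raw, "\n")
  show <- function(nm) {
    if (length(x[[nm]])) cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  show("chrom_pos_keys"); show("rsids"); show("gene_terms")
  show("condition_terms"); show("requested_fields")
  invisible(x)
}

as_intent <- function(query) {
  if (inherits(query, "varrag_intent")) query else parse_query(query)
}

# All analyzed tokens of an intent, in deterministic order.
intent_tokens <- function(intent) {
  unique(c(
    str_to_lower(intent$chrom_pos_keys),
    intent$rsids,
    unlist(analyze_column(intent$gene_terms, "gene"), use.names = FALSE),
    unlist(analyze_column(intent$condition_terms, "condition"), use.names = FALSE)
  ))
}

# Exact keyword hits for the intent's structured keys: one row per
# (doc, first matching key).
exact_key_hits <- function(index, intent) {
  lookups <- rbind(
    if (length(intent$chrom_pos_keys)) {
      data.frame(field = "chrom_pos", key = intent$chrom_pos_keys)
    },
    if (length(intent$rsids)) {
      data.frame(field = "rsid", key = intent$rsids)
    }
  )
  if (is.null(lookups) || nrow(index$postings) == 0) {
    return(tibble(doc_id = character(0), matched_key = character(0)))
  }
  hits <- map(seq_len(nrow(lookups)), function(i) {
    p <- index$postings
    ids <- p$doc_id[p$field == lookups$field[i] & p$term == str_to_lower(lookups$key[i])]
    if (length(ids)) tibble(doc_id = ids, matched_key = lookups$key[i]) else NULL
  }) |> compact() |> list_rbind()
  if (nrow(hits) == 0) {
    return(tibble(doc_id = character(0), matched_key = character(0)))
  }
  hits |> distinct(.data$doc_id, .keep_all = TRUE)
}

#' Ranked retrieval over an index
#'
#' Structured keys (chromosome:position, rsID) are matched against their
#' keyword fields first: whenever exact keyword hits exist they are ranked
#' above all free-text matches (so a variant present in the corpus is always
#' rank 1 for its own key). All query tokens are then scored with BM25 over
#' every searchable field. Ties are broken by ascending `doc_id`, making the
#' ranking deterministic, and results for `k` are a prefix of results for
#' `k + 1`. Queries naming several variants fan out over all extracted keys;
#' exact hits carry their matching key in `matched_key`.
#'
#' @param index a `varrag_index`.
#' @param query a query string or a parsed `varrag_intent`.
#' @param k maximum number of results (default 5).
#' @return tibble of ranked results (`rank`, `doc_id`, `score`, `exact`,
#'   `matched_key`, plus all document columns); zero rows when nothing
#'   matches. The parsed intent is attached as attribute `"intent"`.
#' @examples
#' idx <- build_index(triage_fixture()$documents)
#' search_index(idx, "rs75527207")
#' @export
search_index <- function(index, query, k = 5) {
  stopifnot(k >= 1)
  intent <- as_intent(query)
  scores <- score_tokens(index, intent_tokens(intent))
  exact <- exact_key_hits(index, intent)

  ranked <- scores |>
    full_join(exact, by = "doc_id") |>
    mutate(
      exact = !is.na(.data$matched_key),
      score = ifelse(is.na(.data$score), 0, .data$score)
    ) |>
    arrange(desc(.data$exact), desc(.data$score), .data$doc_id) |>
    head(k)

  out <- ranked |>
    mutate(rank = row_number()) |>
    left_join(index$docs, by = "doc_id") |>
    select(
      "rank", "doc_id", "score", "exact", "matched_key",
      dplyr::all_of(c(
        "chrom_pos", "rsid", "gene", "condition", "content",
        "source_name", "source_url"
      ))
    )
  attr(out, "intent") <- intent
  out
}
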