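# Evaluation protocol: Jaro string similarity with the strict 0.8 condition
# threshold, exact gene matching, seeded test-set sampling, and the per-field
# benchmark over a built index and a generation adapter.

jaro_one <- function(a, b) {
  a <- str_to_lower(str_trim(a))
  b <- str_to_lower(str_trim(b))
  # identical (case-folded, trimmed) strings score 1, including two empties
  if (identical(a, b)) return(1)
  s1 <- strsplit(a, "", fixed = TRUE)[[1]]
  s2 <- strsplit(b, "", fixed = TRUE)[[1]]
  l1 <- length(s1)
  l2 <- length(s2)
  if (l1 == 0 || l2 == 0) return(0)
  w <- max(floor(max(l1, l2) / 2) - 1, 0)
  used2 <- logical(l2)
  m1 <- integer(0)
  m2 <- integer(0)
  for (i in seq_len(l1)) {
    lo <- max(1L, i - w)
    hi <- min(l2, i + w)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!used2[j] && s1[i] == s2[j]) {
        used2[j] <- TRUE
        m1 <- c(m1, i)
        m2 <- c(m2, j)
        break
      }
    }
  }
  m <- length(m1)
  if (m == 0) return(0)
  # transpositions: matched characters compared in string order
  t <- sum(s1[m1] != s2[sort(m2)]) / 2
  (m / l1 + m / l2 + (m - t) / m) / 3
}

#' Jaro string similarity
#'
#' The Jaro similarity in `[0, 1]`: characters match if equal and within the
#' window `floor(max(len1, len2) / 2) - 1`; with `m` matching characters and
#' `t` half the number of transpositions, the score is
#' `(m/len1 + m/len2 + (m - t)/m) / 3`, and 0 when `m = 0`. Comparison is
#' case-insensitive after trimming surrounding whitespace. Plain Jaro, no
#' Jaro-Winkler prefix bonus. Symmetric, and 1 exactly when the case-folded,
#' trimmed strings are identical.
#'
#' @param s1,s2 character vectors (recycled to common length).
#' @return numeric vector of similarities in `[0, 1]`.
#' @examples
#' jaro_similarity("MARTHA", "MARHTA")
#' @export
jaro_similarity <- function(s1, s2) {
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.character(s1), n)
  s2 <- rep_len(as.character(s2), n)
  vapply(seq_len(n), function(i) jaro_one(s1[i], s2[i]), numeric(1))
}

#' Condition match by Jaro similarity
#'
#' A prediction matches when its Jaro similarity to the expected condition is
#' strictly greater than the threshold (a score of exactly 0.8 is not a
#' match). Multi-valued expected conditions (`"; "`-separated) match if any
#' one component matches, since equivalent condition names are often phrased
#' slightly differently.
#'
#' @param expected,predicted condition strings.
#' @param threshold similarity threshold in `[0, 1]` (default 0.8).
#' @return logical scalar.
#' @export
match_condition <- function(expected, predicted, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  components <- strsplit(as.character(expected), "; ", fixed = TRUE)[[1]]
  if (length(components) == 0) components <- ""
  any(jaro_similarity(components, predicted) > threshold)
}

#' Exact gene-symbol match
#'
#' True when the strings are identical after trimming surrounding whitespace.
#' Case-sensitive: gene symbols are case-meaningful.
#'
#' @param expected,predicted gene symbols.
#' @return logical scalar.
#' @export
match_gene <- function(expected, predicted) {
  identical(str_trim(as.character(expected)), str_trim(as.character(predicted)))
}

#' Sample seeded variant test sets
#'
#' Draws `n_sets` disjoint sets of `n` variants without replacement from a
#' document collection, reproducibly under the seed. An optional gene filter
#' restricts sampling to variants whose gene is in the list (the
#' well-studied-gene protocol). Defaults follow the benchmark design: three
#' sets of 100 variants.
#'
#' @param documents document tibble.
#' @param n variants per set.
#' @param n_sets number of sets.
#' @param seed integer seed.
#' @param gene_filter optional character vector of gene symbols.
#' @return the sampled documents with a leading `set` column.
#' @export
sample_test_set <- function(documents, n = 100, n_sets = 3, seed = 1,
                            gene_filter = NULL) {
  pool <- documents
  if (!is.null(gene_filter)) {
    pool <- pool |> filter(.data$gene %in% gene_filter)
  }
  if (nrow(pool) < n * n_sets) {
    stop_varrag(
      sprintf(
        "need %d variants (%d sets of %d) but only %d available%s",
        n * n_sets, n_sets, n, nrow(pool),
        if (is.null(gene_filter)) "" else " after gene filtering"
      ),
      "varrag_sampling_error"
    )
  }
  idx <- with_local_seed(seed, sample.int(nrow(pool), n * n_sets))
  bind_cols(tibble(set = rep(seq_len(n_sets), each = n)), pool[idx, ])
}

# Parse an extractive-style answer into [record] sections of name: value maps.
parse_answer_sections <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(list())
  chunks <- strsplit(text, "\n\n", fixed = TRUE)[[1]]
  chunks <- chunks[startsWith(chunks, "[record]")]
  lapply(chunks, function(ch) {
    lines <- strsplit(ch, "\n", fixed = TRUE)[[1]][-1]
    sep <- regexpr(": ", lines, fixed = TRUE)
    keep <- sep > 0
    setNames(
      unescape_newlines(substr(lines[keep], sep[keep] + 2L, nchar(lines[keep]))),
      substr(lines[keep], 1L, sep[keep] - 1L)
    )
  })
}

benchmark_query_text <- function(key, fields) {
  if (identical(fields, "gene")) {
    sprintf(
      "Provide corresponding gene name for variant %s in GRCh38. Only reply with the gene name.",
      key
    )
  } else if (identical(fields, "condition")) {
    sprintf(
      "Provide the associated condition for variant %s in GRCh38. Only reply with the condition.",
      key
    )
  } else {
    sprintf("Provide all the annotations for variant %s in GRCh38.", key)
  }
}

score_one_variant <- function(answer_text, truth_row, fields, threshold) {
  truth_fields <- document_fields(truth_row)
  score_fields <- if (is.null(fields)) names(truth_fields) else intersect(fields, names(truth_fields))

  if (length(score_fields) == 1 && score_fields %in% c("gene", "condition")) {
    # single-field query: the last non-empty line is the predicted value
    lines <- strsplit(answer_text %||% "", "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(str_trim(lines))]
    pred <- if (length(lines)) tail(lines, 1) else ""
    pred <- sub("^[a-z_]+: ", "", pred)
    ok <- if (score_fields == "gene") {
      match_gene(truth_fields[["gene"]], pred)
    } else {
      identical(str_trim(truth_fields[["condition"]]), str_trim(pred)) ||
        match_condition(truth_fields[["condition"]], pred, threshold)
    }
    return(tibble(field = score_fields, match = ok))
  }

  sections <- parse_answer_sections(answer_text)
  src <- truth_row$source_name[[1]]
  hit <- NULL
  for (s in sections) {
    if (identical(unname(s["source_name"]), src)) {
      hit <- s
      break
    }
  }
  if (is.null(hit)) {
    return(tibble(field = score_fields, match = FALSE))
  }
  matches <- vapply(score_fields, function(f) {
    pred <- unname(hit[f])
    if (is.na(pred)) return(FALSE)
    exact <- identical(str_trim(truth_fields[[f]]), str_trim(pred))
    if (f == "condition") {
      exact || match_condition(truth_fields[[f]], pred, threshold)
    } else {
      exact
    }
  }, logical(1))
  tibble(field = score_fields, match = unname(matches))
}

#' Benchmark annotation accuracy through the full retrieval pipeline
#'
#' Implements the evaluation protocol: sample `n` variants per source dialect
#' and per set (seeded, without replacement), render each as a query by
#' chromosome:position or rsID, run retrieval + prompt assembly + the
#' generation adapter, parse the answer, and score every annotation field —
#' exact string match, with the condition field additionally accepted through
#' [match_condition()] at the strict `> threshold` rule. When several sources
#' share a variant's coordinates (SnpEff annotates ClinVar variants), the
#' answer section from the truth record's own source is the one scored.
#' Adapter failures count as non-matches and are logged in the report.
#'
#' @param index a `varrag_index`.
#' @param truth document tibble of ground-truth records (defaults to the
#'   index's own documents).
#' @param adapter generation adapter, see [adapters].
#' @param query_form `"chrom_pos"` or `"rsid"`.
#' @param fields fields to score: `NULL` (all fields of each source's
#'   inventory, queried as full annotations), or `"gene"` / `"condition"`
#'   for the single-field question forms.
#' @param n variants sampled per source and per set.
#' @param n_sets number of independent sets.
#' @param seed integer seed.
#' @param threshold Jaro threshold for condition matching.
#' @param k retrieval depth.
#' @param char_budget prompt budget in characters.
#' @param params generation parameters.
#' @return an `varrag_eval` report; see [tidy.varrag_eval()] and
#'   [glance.varrag_eval()].
#' @export
run_benchmark <- function(index, truth = index$docs,
                          adapter = adapter_extractive(),
                          query_form = c("chrom_pos", "rsid"),
                          fields = NULL, n = 100, n_sets = 1, seed = 1,
                          threshold = 0.8, k = 5, char_budget = 24000,
                          params = generation_params()) {
  query_form <- match.arg(query_form)
  pool <- truth
  if (query_form == "rsid") {
    pool <- pool |> filter(!is_na_value(.data$rsid))
  }
  sources <- sort(unique(pool$source_name))
  sampled <- with_local_seed(seed, {
    map(sources, function(src) {
      sub <- pool |> filter(.data$source_name == src)
      if (nrow(sub) < n * n_sets) {
        stop_varrag(
          sprintf(
            "source %s has %d usable variants; %d needed (%d sets of %d)",
            src, nrow(sub), n * n_sets, n_sets, n
          ),
          "varrag_sampling_error"
        )
      }
      idx <- sample.int(nrow(sub), n * n_sets)
      bind_cols(tibble(set = rep(seq_len(n_sets), each = n)), sub[idx, ])
    }) |> list_rbind()
  })

  failures <- list()
  scored <- map(seq_len(nrow(sampled)), function(i) {
    row <- sampled[i, ]
    key <- if (query_form == "chrom_pos") row$chrom_pos[[1]] else row$rsid[[1]]
    qtext <- benchmark_query_text(key, fields)
    answer_text <- tryCatch(
      answer_query(
        qtext, index,
        adapter = adapter, k = k,
        char_budget = char_budget, params = params
      )$answer,
      error = function(e) {
        failures[[length(failures) + 1]] <<- tibble(
          key = key, reason = conditionMessage(e)
        )
        NA_character_
      }
    )
    score_one_variant(answer_text, row, fields, threshold) |>
      mutate(set = row$set[[1]], source = row$source_name[[1]], key = key)
  }) |> list_rbind()

  per_field <- scored |>
    group_by(.data$set, .data$source, .data$field) |>
    summarise(matches = sum(.data$match), n = dplyr::n(), .groups = "drop") |>
    mutate(accuracy = .data$matches / .data$n)

  structure(
    list(
      per_field = per_field,
      n = n, n_sets = n_sets,
      similarity_threshold = threshold,
      seed = seed, query_form = query_form,
      failures = if (length(failures)) list_rbind(failures) else tibble(key = character(0), reason = character(0))
    ),
    class = "varrag_eval"
  )
}

#' @export
print.varrag_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<varrag_eval> %d set(s) x %d variants/source, query by %s: overall accuracy %.4f over %d field comparisons\n",
    x$n_sets, x$n, x$query_form, g$overall_accuracy, g$n_comparisons
  ))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' One row per (source, field) aggregated over sets: match count, number of
#' comparisons and accuracy.
#'
#' @param x a `varrag_eval`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.varrag_eval <- function(x, ...) {
  x$per_field |>
    group_by(.data$source, .data$field) |>
    summarise(
      matches = sum(.data$matches), comparisons = sum(.data$n),
      .groups = "drop"
    ) |>
    mutate(accuracy = .data$matches / .data$comparisons)
}

#' Glance at an evaluation report
#'
#' @param x a `varrag_eval`.
#' @param ... unused.
#' @return one-row tibble with the pooled accuracy and the run settings.
#' @export
glance.varrag_eval <- function(x, ...) {
  tibble(
    n_variants = x$n * x$n_sets * dplyr::n_distinct(x$per_field$source),
    n_comparisons = sum(x$per_field$n),
    overall_accuracy = sum(x$per_field$matches) / sum(x$per_field$n),
    n_fields = dplyr::n_distinct(paste(x$per_field$source, x$per_field$field)),
    similarity_threshold = x$similarity_threshold,
    seed = x$seed,
    query_form = x$query_form,
    n_failures = nrow(x$failures)
  )
}

#' Plot per-field benchmark accuracy
#'
#' Bar chart of per-field accuracy, faceted by source dialect.
#'
#' @param object a `varrag_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.varrag_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$field, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$source), scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "per-field accuracy",
      title = sprintf(
        "Annotation accuracy (query by %s, %d set(s) x %d variants/source)",
        object$query_form, object$n_sets, object$n
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the score profile of a result list
#'
#' Relevance score against rank for one retrieval, with exact keyword hits
#' highlighted.
#'
#' @param results tibble from [search_index()].
#' @return a ggplot object.
#' @export
plot_score_profile <- function(results) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$rank, y = .data$score, fill = .data$exact)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "rank", y = "BM25 score", fill = "exact key hit") +
    ggplot2::theme_minimal()
}
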