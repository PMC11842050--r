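# Grounded prompt assembly and answer generation through a pluggable adapter
# contract. The default adapter is a deterministic extractive answerer: it
# reads the retrieved records back out of the assembled prompt and copies the
# requested field values verbatim, so retrieval accuracy is testable offline
# with no hosted model.

#' Generation parameters
#'
#' Defaults: `max_tokens = 1600`, `temperature = 0`, `top_p = 0.5`. The
#' built-in adapters are deterministic and ignore them; they are part of the
#' adapter contract so model-backed adapters receive them unchanged.
#'
#' @param max_tokens positive integer.
#' @param temperature non-negative real.
#' @param top_p real in (0, 1].
#' @return list of class `varrag_params`.
#' @export
generation_params <- function(max_tokens = 1600, temperature = 0, top_p = 0.5) {
  stopifnot(max_tokens >= 1, temperature >= 0, top_p > 0, top_p <= 1)
  structure(
    list(max_tokens = max_tokens, temperature = temperature, top_p = top_p),
    class = "varrag_params"
  )
}

#' Default system template
#'
#' Frames the generator as a genomics assistant answering strictly from the
#' retrieved variant annotation records. Configurable: any replacement string
#' is used verbatim.
#' @return character scalar.
#' @export
varrag_system_template <- function() {
  paste(
    "You are a genomics assistant specialized in variant annotation.",
    "Answer the user's question using only the retrieved variant annotation",
    "records below. If the records do not contain the answer, say so."
  )
}

no_records_marker <- "No records retrieved."

escape_newlines <- function(x) gsub("\n", "%0A", gsub("\r", "%0D", x, fixed = TRUE), fixed = TRUE)
unescape_newlines <- function(x) gsub("%0A", "\n", gsub("%0D", "\r", x, fixed = TRUE), fixed = TRUE)

# One context block: the document's five columns (content decoded into
# name: value lines) with provenance in the header line.
render_document_block <- function(doc_row, rank) {
  content <- parse_content(doc_row$content[[1]])
  lines <- c(
    sprintf(
      "### Record %d | source: %s | url: %s",
      rank, doc_row$source_name[[1]], doc_row$source_url[[1]]
    ),
    paste0("chrom_pos: ", doc_row$chrom_pos[[1]]),
    paste0("rsid: ", doc_row$rsid[[1]]),
    paste0("gene: ", doc_row$gene[[1]]),
    paste0("condition: ", doc_row$condition[[1]]),
    if (length(content)) paste0(names(content), ": ", escape_newlines(unname(content)))
  )
  paste(lines, collapse = "\n")
}

parse_document_block <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  hdr <- str_match(lines[1], "^### Record ([0-9]+) \\| source: ([^|]+) \\| url: (.*)$")
  if (is.na(hdr[1, 1])) return(NULL)
  source <- str_trim(hdr[1, 3])
  body <- lines[-1]
  sep <- regexpr(": ", body, fixed = TRUE)
  nms <- substr(body, 1L, sep - 1L)
  vals <- unescape_newlines(substr(body, sep + 2L, nchar(body)))
  f <- setNames(vals, nms)
  cf <- setNames(rep(VARRAG_NA, length(content_fields(source))), content_fields(source))
  present <- intersect(names(cf), nms)
  cf[present] <- f[present]
  tibble(
    chrom_pos = f[["chrom_pos"]],
    rsid = f[["rsid"]],
    gene = f[["gene"]],
    condition = f[["condition"]],
    content = paste(
      paste0(names(cf), "=", escape_value(unname(cf))),
      collapse = "; "
    ),
    source_name = source,
    source_url = hdr[1, 4]
  )
}

compose_prompt_text <- function(system, blocks, user) {
  ctx <- if (length(blocks)) paste(blocks, collapse = "\n\n") else no_records_marker
  paste0(system, "\n\n[Retrieved records]\n", ctx, "\n\n[User query]\n", user)
}

#' Assemble a retrieval-grounded prompt
#'
#' Renders the ranked results as context blocks (rank order preserved) between
#' the system template and the verbatim user query. When the assembled text
#' exceeds `char_budget`, lowest-ranked blocks are dropped first; zero
#' retained results produce a fixed "no records retrieved" marker.
#'
#' @param query query string or parsed intent.
#' @param results ranked results from [search_index()].
#' @param system_template system message.
#' @param char_budget maximum assembled length in characters (default 12000).
#' @return list of class `varrag_prompt` with elements `system`,
#'   `context_blocks`, `user`, `assembled`, `char_budget`, `intent`.
#' @export
assemble_prompt <- function(query, results,
                            system_template = varrag_system_template(),
                            char_budget = 12000) {
  intent <- as_intent(query)
  user <- intent$raw
  blocks <- if (nrow(results)) {
    vapply(
      seq_len(nrow(results)),
      function(i) render_document_block(results[i, ], results$rank[i]),
      character(1)
    )
  } else {
    character(0)
  }
  floor_len <- nchar(compose_prompt_text(system_template, character(0), user))
  if (floor_len > char_budget) {
    stop_varrag(
      sprintf(
        "char_budget %d is too small for system template plus user query (%d characters)",
        char_budget, floor_len
      ),
      "varrag_budget_error"
    )
  }
  assembled <- compose_prompt_text(system_template, blocks, user)
  while (nchar(assembled) > char_budget && length(blocks)) {
    blocks <- blocks[-length(blocks)]
    assembled <- compose_prompt_text(system_template, blocks, user)
  }
  structure(
    list(
      system = system_template, context_blocks = blocks, user = user,
      assembled = assembled, char_budget = char_budget, intent = intent
    ),
    class = "varrag_prompt"
  )
}

#' @export
print.varrag_prompt <- function(x, ...) {
  cat(sprintf(
    "<varrag_prompt> %d context block(s), %d/%d characters\n",
    length(x$context_blocks), nchar(x$assembled), x$char_budget
  ))
  invisible(x)
}

doc_matches_key <- function(doc_row, key) {
  key <- str_to_lower(key)
  identical(str_to_lower(doc_row$chrom_pos[[1]]), key) ||
    identical(str_to_lower(doc_row$rsid[[1]]), key)
}

get_doc_id <- function(results, i) {
  if ("doc_id" %in% names(results)) results$doc_id[[i]] else NA_character_
}

not_found_rows <- function(key, requested) {
  tibble(
    key = key, doc_id = NA_character_, source_name = NA_character_,
    field = requested, value = "not found"
  )
}

record_rows <- function(key, doc_row, doc_id) {
  f <- document_fields(doc_row)
  tibble(
    key = key, doc_id = doc_id, source_name = doc_row$source_name[[1]],
    field = c(names(f), "source_name", "source_url"),
    value = c(unname(f), doc_row$source_name[[1]], doc_row$source_url[[1]])
  )
}

#' Extract requested fields verbatim from retrieved documents
#'
#' For each variant key in the intent, values are copied verbatim from its
#' highest-ranked exact-hit document (every exact-hit document when all
#' annotations are requested, so records from all matching sources are
#' reported); a key without an exact hit maps to the sentinel `"not found"`.
#' An intent without structured keys falls back to the rank-1 result. All
#' values are grounded: each appears verbatim in a retrieved document.
#'
#' @param intent a `varrag_intent`.
#' @param results ranked results from [search_index()].
#' @return tibble with columns `key`, `doc_id`, `source_name`, `field`,
#'   `value`.
#' @export
extractive_answer <- function(intent, results) {
  req <- intent$requested_fields
  full <- "all-annotations" %in% req
  single <- setdiff(req, "all-annotations")
  keys <- c(intent$chrom_pos_keys, intent$rsids)

  answer_for <- function(key, hit_idx) {
    if (length(hit_idx) == 0) {
      return(not_found_rows(key, req))
    }
    if (full) {
      map(hit_idx, function(i) {
        record_rows(key, results[i, ], get_doc_id(results, i))
      }) |> list_rbind()
    } else {
      doc <- results[hit_idx[1], ]
      tibble(
        key = key, doc_id = get_doc_id(results, hit_idx[1]),
        source_name = doc$source_name[[1]],
        field = single,
        value = vapply(single, function(f) as.character(doc[[f]][[1]]), character(1))
      )
    }
  }

  if (length(keys)) {
    map(keys, function(key) {
      hit_idx <- which(vapply(
        seq_len(nrow(results)),
        function(i) doc_matches_key(results[i, ], key), logical(1)
      ))
      answer_for(key, hit_idx)
    }) |> list_rbind()
  } else if (nrow(results)) {
    answer_for(NA_character_, 1L)
  } else {
    not_found_rows(NA_character_, req)
  }
}

#' Render an extractive answer as text
#'
#' A single extracted value renders bare (matching "only reply with the
#' ..." instructions); anything larger renders as `[record]` sections of
#' `name: value` lines, one section per matched document.
#'
#' @param answer tibble from [extractive_answer()].
#' @return character scalar.
#' @export
render_answer <- function(answer) {
  if (nrow(answer) == 1) {
    return(answer$value[[1]])
  }
  grp <- paste(answer$key, answer$doc_id, sep = "\r")
  sections <- lapply(unique(grp), function(g) {
    gg <- answer[grp == g, ]
    key_line <- if (!is.na(gg$key[[1]])) paste0("key: ", gg$key[[1]])
    paste(
      c("[record]", key_line, paste0(gg$field, ": ", escape_newlines(gg$value))),
      collapse = "\n"
    )
  })
  paste(unlist(sections), collapse = "\n\n")
}

#' Generation adapters
#'
#' An adapter is any stateless function from `(assembled_prompt, params)` to
#' answer text. `adapter_extractive()` parses the retrieved records and the
#' user query back out of the assembled prompt and answers by verbatim field
#' extraction; `adapter_echo()` returns the prompt itself; `adapter_command()`
#' pipes the prompt to an external executable's standard input and returns its
#' standard output, which is how a hosted or local language model is plugged
#' in.
#'
#' @return a function of `(prompt, params)`.
#' @name adapters
NULL

#' @rdname adapters
#' @export
adapter_extractive <- function() {
  function(prompt, params) {
    parts <- strsplit(prompt, "\n\n[User query]\n", fixed = TRUE)[[1]]
    user <- if (length(parts) >= 2) paste(parts[-1], collapse = "\n\n[User query]\n") else ""
    intent <- parse_query(user)
    ctx_at <- regexpr("[Retrieved records]\n", parts[1], fixed = TRUE)
    ctx <- if (ctx_at > 0) {
      substr(parts[1], ctx_at + attr(ctx_at, "match.length"), nchar(parts[1]))
    } else {
      ""
    }
    results <- tibble(
      rank = integer(0), doc_id = character(0), chrom_pos = character(0),
      rsid = character(0), gene = character(0), condition = character(0),
      content = character(0), source_name = character(0),
      source_url = character(0)
    )
    if (!identical(ctx, no_records_marker)) {
      blocks <- strsplit(ctx, "\n\n", fixed = TRUE)[[1]]
      parsed <- map(blocks, parse_document_block) |> compact()
      if (length(parsed)) {
        results <- list_rbind(parsed) |>
          mutate(rank = row_number(), doc_id = paste0("ctx-", row_number()))
      }
    }
    render_answer(extractive_answer(intent, results))
  }
}

#' @rdname adapters
#' @export
adapter_echo <- function() {
  function(prompt, params) prompt
}

#' @param command executable name (plus fixed arguments) invoked per call.
#' @rdname adapters
#' @export
adapter_command <- function(command) {
  force(command)
  function(prompt, params) {
    out <- suppressWarnings(system2(
      command[1],
      args = if (length(command) > 1) command[-1] else character(0),
      input = prompt, stdout = TRUE, stderr = FALSE
    ))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop(sprintf("command adapter exited with status %d", status))
    }
    paste(out, collapse = "\n")
  }
}

#' Generate an answer from an assembled prompt
#'
#' Calls the adapter on the assembled prompt and returns its output
#' unmodified. Adapter failures are re-raised with the prompt's content hash
#' so a failing generation is reproducible.
#'
#' @param bundle a `varrag_prompt` from [assemble_prompt()].
#' @param adapter a generation adapter, see [adapters].
#' @param params a `varrag_params`.
#' @return answer text (character scalar).
#' @export
generate <- function(bundle, adapter = adapter_extractive(),
                     params = generation_params()) {
  stopifnot(inherits(bundle, "varrag_prompt"), is.function(adapter))
  tryCatch(
    adapter(bundle$assembled, params),
    error = function(e) {
      stop_varrag(
        sprintf(
          "adapter failed (prompt hash %s): %s",
          hash(bundle$assembled), conditionMessage(e)
        ),
        "varrag_adapter_error"
      )
    }
  )
}

#' End-to-end retrieval-augmented answer
#'
#' Parses the query, retrieves the top `k` documents, assembles the grounded
#' prompt and generates the answer through the adapter.
#'
#' @inheritParams search_index
#' @inheritParams assemble_prompt
#' @inheritParams generate
#' @param query free-text query.
#' @return list of class `varrag_answer`: `answer`, `intent`, `results`,
#'   `prompt`.
#' @examples
#' idx <- build_index(triage_fixture()$documents)
#' answer_query("Provide corresponding gene name for variant rs75527207. Only reply with the gene name.", idx)
#' @export
answer_query <- function(query, index, adapter = adapter_extractive(), k = 5,
                         system_template = varrag_system_template(),
                         char_budget = 12000, params = generation_params()) {
  intent <- as_intent(query)
  results <- search_index(index, intent, k = k)
  bundle <- assemble_prompt(intent, results, system_template, char_budget)
  structure(
    list(
      answer = generate(bundle, adapter, params),
      intent = intent, results = results, prompt = bundle
    ),
    class = "varrag_answer"
  )
}

#' @export
print.varrag_answer <- function(x, ...) {
  cat(x$answer, "\n")
  invisible(x)
}
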