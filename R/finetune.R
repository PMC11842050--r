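# Chat-format fine-tuning dataset construction from ClinVar-dialect records:
# full 13-field annotation prompts or single-field designs, JSON Lines
# serialization with recorded (not executed) training hyperparameters, and a
# JSONL validator. Also the invertible rsID-to-single-word codebook used to
# improve rsID tokenization.

finetune_modes <- c("full13", "gene", "condition", "rsid", "gene_condition")

#' Default fine-tuning message templates
#'
#' `system` frames the assistant as a ClinVar annotation expert; `user` is an
#' sprintf template whose single `%s` receives the variant key
#' (chromosome:position or rsID). Both are configurable in
#' [build_finetune_examples()].
#'
#' @param mode one of `"full13"`, `"gene"`, `"condition"`, `"rsid"`,
#'   `"gene_condition"`.
#' @return list with elements `system` and `user`.
#' @export
finetune_templates <- function(mode = "full13") {
  mode <- match.arg(mode, finetune_modes)
  system <- paste(
    "You are a genomics assistant that provides variant annotations",
    "from the ClinVar database."
  )
  user <- switch(mode,
    full13 = "Provide all the annotations for variant %s in GRCh38.",
    gene = "Provide corresponding gene name for variant %s in GRCh38. Only reply with the gene name.",
    condition = "Provide the associated condition for variant %s in GRCh38. Only reply with the condition.",
    rsid = "Provide the dbSNP ID for variant %s in GRCh38. Only reply with the dbSNP ID.",
    gene_condition = "Provide the gene and the associated condition for variant %s in GRCh38."
  )
  list(system = system, user = user)
}

# Fine-tuning hyperparameters recorded as sidecar metadata only; no training
# job is run by this package.
finetune_hyperparameters <- function() {
  list(batch_size = 6L, n_epochs = 3L, learning_rate_multiplier = 1)
}

assistant_message <- function(fields, mode, codebook = NULL) {
  switch(mode,
    full13 = paste(paste0(names(fields), ": ", unname(fields)), collapse = "\n"),
    gene = fields[["gene"]],
    condition = fields[["condition"]],
    rsid = {
      rs <- fields[["dbSNP ID"]]
      if (!is.null(codebook) && !is_na_value(rs)) encode_rsid(rs, codebook) else rs
    },
    gene_condition = paste0(
      "gene: ", fields[["gene"]], "\ncondition: ", fields[["condition"]]
    )
  )
}

#' Build chat-format fine-tuning examples from ClinVar records
#'
#' Samples variants without replacement under the seed, splits them into
#' disjoint training and validation sets (defaults 3000/1000), and renders one
#' three-message chat example per variant: a system message, a user message
#' embedding the variant's chromosome:position (or rsID) in a natural-language
#' instruction, and the assistant message carrying all 13 annotation fields as
#' `name: value` lines (`full13` mode) or the single requested field's value.
#' Training examples can be duplicated `repeats` times (a repetition strategy
#' knob; validation examples are never repeated).
#'
#' @param records ClinVar-dialect records from [read_annotation_source()].
#' @param mode one of `"full13"`, `"gene"`, `"condition"`, `"rsid"`,
#'   `"gene_condition"`.
#' @param n_train,n_valid split sizes; their sum may not exceed the number of
#'   usable variants.
#' @param seed integer seed for the sampling.
#' @param repeats how many times each training example appears.
#' @param query_form `"chrom_pos"` (default) or `"rsid"`: the key embedded in
#'   the user message.
#' @param templates list with `system` and `user` templates, see
#'   [finetune_templates()].
#' @param codebook optional rsID codebook from [make_rsid_codebook()]; in
#'   `rsid` mode, assistant rsIDs are encoded through it.
#' @return list with tibbles `train` and `valid` (columns `system`, `user`,
#'   `assistant`, `mode`, `variant_key`) and `n_skipped`.
#' @export
build_finetune_examples <- function(records, mode = "full13",
                                    n_train = 3000, n_valid = 1000,
                                    seed = 1, repeats = 1,
                                    query_form = c("chrom_pos", "rsid"),
                                    templates = finetune_templates(mode),
                                    codebook = NULL) {
  mode <- match.arg(mode, finetune_modes)
  query_form <- match.arg(query_form)
  stopifnot(repeats >= 1, n_train >= 0, n_valid >= 0)
  recs <- as_tibble(records)
  if (nrow(recs) == 0 || !all(recs$source == "ClinVar")) {
    stop_varrag("records must be ClinVar-dialect", "varrag_finetune_error")
  }

  n_before <- nrow(recs)
  if (mode == "gene_condition") {
    usable <- vapply(recs$fields, function(f) {
      !(is_na_value(f[["gene"]]) && is_na_value(f[["condition"]]))
    }, logical(1))
    recs <- recs[usable, ]
  }
  if (query_form == "rsid") {
    recs <- recs[!vapply(recs$fields, function(f) is_na_value(f[["dbSNP ID"]]), logical(1)), ]
  }
  n_skipped <- n_before - nrow(recs)
  if (n_skipped > 0) {
    warn(sprintf("%d record(s) unusable for mode '%s' were skipped", n_skipped, mode))
  }
  if (n_train + n_valid > nrow(recs)) {
    stop_varrag(
      sprintf(
        "split needs %d variants but only %d are usable",
        n_train + n_valid, nrow(recs)
      ),
      "varrag_finetune_error"
    )
  }

  idx <- with_local_seed(seed, sample.int(nrow(recs), n_train + n_valid))
  render <- function(rows) {
    if (length(rows) == 0) {
      return(tibble(
        system = character(0), user = character(0), assistant = character(0),
        mode = character(0), variant_key = character(0)
      ))
    }
    sub <- recs[rows, ]
    key <- if (query_form == "chrom_pos") {
      paste0(sub$chrom, ":", sub$pos)
    } else {
      sub$rsid
    }
    tibble(
      system = templates$system,
      user = sprintf(templates$user, key),
      assistant = vapply(
        sub$fields, assistant_message, character(1),
        mode = mode, codebook = codebook
      ),
      mode = mode,
      variant_key = paste0(sub$chrom, ":", sub$pos)
    )
  }
  train <- render(idx[seq_len(n_train)])
  valid <- render(idx[n_train + seq_len(n_valid)])
  if (repeats > 1) {
    train <- train[rep(seq_len(nrow(train)), each = repeats), ]
  }
  list(train = train, valid = valid, n_skipped = n_skipped)
}

#' Write fine-tuning examples as JSON Lines
#'
#' One JSON object per line with a `messages` list of exactly three
#' role/content entries (system, user, assistant). A sidecar
#' `<path>.meta.json` records the mode, counts and the fine-tuning
#' hyperparameters (batch size 6, three epochs, learning-rate multiplier 1) as
#' metadata; no training job is executed.
#'
#' @param examples tibble with `system`, `user`, `assistant` columns.
#' @param path output file path.
#' @param meta extra metadata to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_finetune_jsonl <- function(examples, path, meta = list()) {
  lines <- vapply(seq_len(nrow(examples)), function(i) {
    jsonlite::toJSON(
      list(messages = list(
        list(role = "system", content = examples$system[[i]]),
        list(role = "user", content = examples$user[[i]]),
        list(role = "assistant", content = examples$assistant[[i]])
      )),
      auto_unbox = TRUE
    )
  }, character(1))
  readr::write_lines(lines, path)
  sidecar <- c(
    list(
      n_examples = nrow(examples),
      modes = as.list(table(examples$mode)),
      hyperparameters = finetune_hyperparameters()
    ),
    meta
  )
  jsonlite::write_json(
    sidecar, paste0(path, ".meta.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Validate a chat-format JSON Lines file
#'
#' Checks that every line parses as a single JSON object whose `messages`
#' element is a list of exactly three role/content entries in the order
#' system, user, assistant. The first malformed line is reported with its
#' line number; duplicate user messages are counted.
#'
#' @param path JSONL file path.
#' @return list of class `varrag_jsonl_report`: `n_lines`, `n_valid`,
#'   `violations` (tibble of `line`, `reason`), `n_duplicate_users`, `valid`.
#' @export
validate_jsonl <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  violations <- list()
  users <- character(0)
  for (i in seq_along(lines)) {
    parsed <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) NULL
    )
    reason <- NULL
    if (is.null(parsed) || !is.list(parsed)) {
      reason <- "line is not a JSON object"
    } else if (!identical(names(parsed), "messages") ||
      length(parsed$messages) != 3) {
      reason <- "object must have a single 'messages' list of length 3"
    } else {
      roles <- vapply(parsed$messages, function(m) m$role %||% "", character(1))
      contents_ok <- all(vapply(
        parsed$messages,
        function(m) is.character(m$content %||% NULL) && length(m$content) == 1,
        logical(1)
      ))
      if (!identical(roles, c("system", "user", "assistant")) || !contents_ok) {
        reason <- "messages must be role/content entries in order system, user, assistant"
      } else {
        users <- c(users, parsed$messages[[2]]$content)
      }
    }
    if (!is.null(reason)) {
      violations[[length(violations) + 1]] <- tibble(line = i, reason = reason)
    }
  }
  violations <- if (length(violations)) {
    list_rbind(violations)
  } else {
    tibble(line = integer(0), reason = character(0))
  }
  structure(
    list(
      n_lines = length(lines),
      n_valid = length(lines) - nrow(violations),
      violations = violations,
      n_duplicate_users = sum(duplicated(users)),
      valid = nrow(violations) == 0
    ),
    class = "varrag_jsonl_report"
  )
}

#' @export
print.varrag_jsonl_report <- function(x, ...) {
  cat(sprintf(
    "<varrag_jsonl_report> %d line(s), %d valid, %d violation(s), %d duplicate user message(s)\n",
    x$n_lines, x$n_valid, nrow(x$violations), x$n_duplicate_users
  ))
  if (nrow(x$violations)) print(head(x$violations, 5))
  invisible(x)
}

codebook_consonants <- c(
  "b", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p", "r", "s", "t", "v", "w", "z"
)
codebook_vowels <- c("a", "e", "i", "o", "u")

#' Build an invertible rsID codebook of pronounceable words
#'
#' Maps each rsID to a distinct short word made of consonant-vowel syllables
#' (one "single-token-friendly" word per ID), the encoding used to improve
#' rsID tokenization in single-field fine-tuning. The mapping is deterministic
#' under the seed and invertible.
#'
#' @param rsids character vector of rsIDs (`rs` followed by digits).
#' @param seed integer seed.
#' @param n_syllables word length in consonant-vowel syllables (capacity is
#'   85^n_syllables words).
#' @return tibble of class `varrag_codebook` with columns `rsid`, `word`.
#' @export
make_rsid_codebook <- function(rsids, seed = 1, n_syllables = 3) {
  rsids <- unique(rsids)
  if (!all(grepl("^rs[0-9]+$", rsids))) {
    stop_varrag("all rsIDs must match rs[0-9]+", "varrag_codebook_error")
  }
  syllables <- as.vector(outer(codebook_consonants, codebook_vowels, paste0))
  capacity <- length(syllables)^n_syllables
  if (length(rsids) > capacity) {
    stop_varrag(
      sprintf(
        "codebook exhausted: %d rsIDs need at least %d syllables per word (capacity %d)",
        length(rsids), ceiling(log(length(rsids)) / log(length(syllables))), capacity
      ),
      "varrag_codebook_error"
    )
  }
  idx <- with_local_seed(seed, sample.int(capacity, length(rsids))) - 1L
  word <- vapply(idx, function(v) {
    parts <- character(n_syllables)
    for (s in seq_len(n_syllables)) {
      parts[s] <- syllables[(v %% length(syllables)) + 1L]
      v <- v %/% length(syllables)
    }
    paste(parts, collapse = "")
  }, character(1))
  structure(
    tibble(rsid = rsids, word = word),
    class = c("varrag_codebook", class(tibble()))
  )
}

#' Encode / decode rsIDs through a codebook
#'
#' `decode_rsid(encode_rsid(x, cb), cb)` is the identity for every rsID in the
#' codebook; unknown inputs are an error.
#'
#' @param rsid,word character vectors.
#' @param codebook a `varrag_codebook`.
#' @return character vector of code words (or rsIDs).
#' @export
encode_rsid <- function(rsid, codebook) {
  m <- match(rsid, codebook$rsid)
  if (anyNA(m)) {
    stop_varrag(
      paste0("rsID(s) not in codebook: ", paste(rsid[is.na(m)], collapse = ", ")),
      "varrag_codebook_error"
    )
  }
  codebook$word[m]
}

#' @rdname encode_rsid
#' @export
decode_rsid <- function(word, codebook) {
  m <- match(word, codebook$word)
  if (anyNA(m)) {
    stop_varrag(
      paste0("word(s) not in codebook: ", paste(word[is.na(m)], collapse = ", ")),
      "varrag_codebook_error"
    )
  }
  codebook$rsid[m]
}
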