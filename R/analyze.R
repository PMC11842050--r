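# Tokenization of the five searchable columns. chrom_pos and rsid are keyword
# fields (one verbatim lowercased token, colons preserved so chrom:pos
# survives as a unit); gene, condition and content are text fields split on
# whitespace and punctuation including hyphens. A minimal English stopword
# list is applied to condition and content only; gene symbols are never
# stop-filtered. The analyzer is versioned so index manifests can record it.

varrag_analyzer_version <- "1"

keyword_columns <- c("chrom_pos", "rsid")

#' Stopword list applied to condition and content tokens
#' @export
varrag_stopwords <- c(
  "a", "an", "and", "are", "as", "at", "be", "but", "by", "for", "if", "in",
  "into", "is", "it", "no", "not", "of", "on", "or", "such", "that", "the",
  "their", "then", "there", "these", "they", "this", "to", "was", "will",
  "with"
)

#' Tokenize text for one searchable column
#'
#' Keyword columns (`chrom_pos`, `rsid`) pass their value through as a single
#' lowercased token. Text columns (`gene`, `condition`, `content`) are
#' lowercased and split on any run of non-alphanumeric characters — so phrases
#' and hyphenated words split into component parts — then emptied tokens and
#' (for `condition`/`content` only) stopwords are dropped. The `"NA"` sentinel
#' produces no tokens.
#'
#' @param text a character scalar.
#' @param field one of the five searchable column names.
#' @return character vector of tokens (possibly empty).
#' @examples
#' analyze_text("Cystic-fibrosis", "condition")
#' analyze_text("chr2:96799611", "chrom_pos")
#' @export
analyze_text <- function(text, field) {
  field <- match.arg(field, varrag_searchable_columns)
  analyze_one(text, field)
}

analyze_one <- function(text, field) {
  if (length(text) == 0 || is.na(text) || text == "" || text == VARRAG_NA) {
    return(character(0))
  }
  if (field %in% keyword_columns) {
    return(str_to_lower(str_trim(text)))
  }
  toks <- strsplit(str_to_lower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (field %in% c("condition", "content")) {
    toks <- toks[!toks %in% varrag_stopwords]
  }
  toks
}

# Vectorized analyzer: list of token vectors, one per input string.
analyze_column <- function(texts, field) {
  lapply(texts, analyze_one, field = field)
}
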