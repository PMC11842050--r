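# Shared low-level helpers: missing-value sentinel, content-column escaping,
# chromosome label normalization.

#' Missing-value sentinel used throughout the document model
#'
#' Annotation fields that are absent from a source record are represented by
#' the literal string `"NA"` in field maps, documents and the chunked CSV
#' store, so that missingness survives plain-text round trips.
#' @keywords internal
VARRAG_NA <- "NA"

is_na_value <- function(x) {
  is.na(x) | x == VARRAG_NA | x == ""
}

na_value <- function(x) {
  out <- as.character(x)
  names(out) <- names(x)
  out[is_na_value(out)] <- VARRAG_NA
  out
}

# Percent-escaping for values embedded in the `name=value; ` content
# serialization. Escapes the two delimiters, newlines and "%" itself so the
# serialization is invertible for any value.
escape_value <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("\r", "%0D", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

unescape_value <- function(x) {
  x <- gsub("%0A", "\n", x, fixed = TRUE)
  x <- gsub("%0D", "\r", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Normalize a chromosome label to "chr"-prefixed form
#'
#' Accepts `"2"`, `"chr2"`, `"Chr2"`, `"X"`, `"MT"` and returns the canonical
#' `"chr"`-prefixed label (`"chr2"`, `"chrX"`, `"chrM"`). Coordinates are
#' 1-based inclusive as in the VCF standard.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels; `NA` for labels outside
#'   1-22, X, Y, M/MT.
#' @examples
#' normalize_chrom(c("2", "Chr2", "MT"))
#' @export
normalize_chrom <- function(x) {
  core <- str_replace_all(str_trim(x), regex("^chr", ignore_case = TRUE), "")
  core <- str_to_upper(core)
  core[core == "MT"] <- "M"
  ok <- core %in% c(as.character(1:22), "X", "Y", "M")
  out <- ifelse(ok, paste0("chr", core), NA_character_)
  out
}

# RefSeq chromosome accessions (GRCh38) used for canonical SPDI rendering.
refseq_accession <- function(chrom) {
  core <- sub("^chr", "", chrom)
  nums <- suppressWarnings(as.integer(core))
  acc <- character(length(chrom))
  patch <- c(
    "10", "11", "12", "11", "9", "12", "14", "11", "12", "11",
    "10", "12", "11", "9", "10", "10", "11", "10", "10", "11",
    "9", "11"
  )
  for (i in seq_along(chrom)) {
    if (!is.na(nums[i])) {
      acc[i] <- sprintf("NC_%06d.%s", nums[i], patch[nums[i]])
    } else if (core[i] == "X") {
      acc[i] <- "NC_000023.11"
    } else if (core[i] == "Y") {
      acc[i] <- "NC_000024.10"
    } else {
      acc[i] <- "NC_012920.1"
    }
  }
  acc
}

stop_varrag <- function(message, class, ...) {
  abort(message, class = c(class, "varrag_error"), ...)
}
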