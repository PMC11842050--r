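# Field inventories for the five annotation-source dialects, and the
# reconstruction of a record's full field map from a normalized document.

#' Annotation source dialects
#'
#' The five supported annotation sources: the ClinVar VCF, the gnomAD exome
#' VCF, SnpEff-annotated VCF output, the GWAS Catalog association TSV, and the
#' PharmGKB clinical-annotation TSV.
#' @export
varrag_sources <- c("ClinVar", "gnomAD", "SnpEff", "GWASCatalog", "PharmGKB")

# gnomAD continental populations whose allele frequencies are carried into the
# content column; the set is configurable at parse/generation time.
gnomad_default_populations <- c("afr", "amr", "eas", "nfe", "sas")

#' Field inventory of an annotation-source dialect
#'
#' Returns the ordered field names that every record of the given dialect
#' carries (values may be `"NA"`). The ClinVar inventory is the fixed set of
#' 13 informative annotation fields extracted from the ClinVar VCF.
#'
#' @param source one of [varrag_sources].
#' @param populations gnomAD population codes whose allele frequencies are
#'   included (ignored for other sources).
#' @return character vector of field names in declared order.
#' @examples
#' source_fields("ClinVar")
#' @export
source_fields <- function(source, populations = gnomad_default_populations) {
  source <- match.arg(source, varrag_sources)
  switch(source,
    ClinVar = c(
      "chromosome", "position", "reference allele", "alternative allele",
      "dbSNP ID", "Variation ID", "Allele ID", "canonical SPDI",
      "molecular consequence", "germline review", "germline status",
      "gene", "condition"
    ),
    gnomAD = c(
      "chromosome", "position", "reference allele", "alternative allele",
      "dbSNP ID", "filter", "allele count", "allele number",
      "allele frequency", paste0("allele frequency ", populations)
    ),
    SnpEff = c(
      "chromosome", "position", "reference allele", "alternative allele",
      "dbSNP ID", "effect", "putative impact", "gene", "gene ID",
      "feature type", "transcript biotype", "HGVS.c"
    ),
    GWASCatalog = c(
      "chromosome", "position", "dbSNP ID", "strongest risk allele",
      "gene", "condition", "p-value", "OR or beta", "study accession"
    ),
    PharmGKB = c(
      "chromosome", "position", "dbSNP ID", "clinical annotation ID",
      "gene", "condition", "level of evidence", "phenotype category", "drugs"
    )
  )
}

# Field names lifted out of the field map into dedicated searchable columns.
lifted_fields <- function(source) {
  intersect(
    c("chromosome", "position", "dbSNP ID", "gene", "condition"),
    source_fields(source)
  )
}

# Field names serialized into the content column, in declared order.
content_fields <- function(source) {
  setdiff(source_fields(source), lifted_fields(source))
}

#' The five searchable document columns
#' @export
varrag_searchable_columns <- c("chrom_pos", "rsid", "gene", "condition", "content")

#' Per-source search URL templates
#'
#' ClinVar URLs are keyed on the Variation ID, gnomAD on the
#' chrom-pos-ref-alt variant string, PharmGKB on the clinical-annotation ID.
#' GWAS Catalog and SnpEff documents carry no URL (`"NA"`).
#'
#' @return named list of `sprintf` templates.
#' @export
varrag_url_templates <- function() {
  list(
    ClinVar = "https://www.ncbi.nlm.nih.gov/clinvar/variation/%s/",
    gnomAD = "https://gnomad.broadinstitute.org/variant/%s?dataset=gnomad_r4",
    PharmGKB = "https://www.pharmgkb.org/clinicalAnnotation/%s"
  )
}

# Serialize the non-lifted fields of one record into the content column.
serialize_content <- function(fields, source) {
  nms <- content_fields(source)
  vals <- escape_value(na_value(unname(fields[nms])))
  paste(paste0(nms, "=", vals), collapse = "; ")
}

# Invert serialize_content: named character vector of content fields.
parse_content <- function(content) {
  if (is_na_value(content)) {
    return(setNames(character(0), character(0)))
  }
  parts <- strsplit(content, "; ", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  nms <- substr(parts, 1L, eq - 1L)
  vals <- unescape_value(substr(parts, eq + 1L, nchar(parts)))
  setNames(vals, nms)
}

#' Reconstruct the full field map of a normalized document
#'
#' Inverts normalization: rebuilds the source record's ordered field map
#' (chromosome and position from `chrom_pos`, the lifted dbSNP ID / gene /
#' condition columns, and the remaining fields parsed out of the content
#' column). The condition value carries the normalization applied on ingest
#' (multi-valued conditions joined with `"; "`, underscores as spaces).
#'
#' @param doc a one-row document tibble, or a list-like with the document
#'   columns.
#' @return named character vector over the source's field inventory, in
#'   declared order.
#' @export
document_fields <- function(doc) {
  source <- as.character(doc$source_name[[1]])
  nms <- source_fields(source)
  cp <- strsplit(as.character(doc$chrom_pos[[1]]), ":", fixed = TRUE)[[1]]
  content <- parse_content(as.character(doc$content[[1]]))
  out <- setNames(character(length(nms)), nms)
  for (nm in nms) {
    out[[nm]] <- switch(nm,
      "chromosome" = cp[[1]],
      "position" = cp[[2]],
      "dbSNP ID" = as.character(doc$rsid[[1]]),
      "gene" = as.character(doc$gene[[1]]),
      "condition" = as.character(doc$condition[[1]]),
      if (nm %in% names(content)) content[[nm]] else VARRAG_NA
    )
  }
  na_value(out)
}
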