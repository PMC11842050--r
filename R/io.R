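# Parsing of the five annotation-source dialects into records, and
# normalization of records into the five-column searchable document model.
#
# Parsing is line-oriented so that a malformed data line is collected into a
# rejects report (with its line number and reason) instead of aborting a
# large build; only a malformed header aborts.

new_records <- function(tbl, rejects = tibble(line = integer(), reason = character())) {
  structure(
    tbl,
    rejects = rejects,
    class = c("varrag_records", class(tibble())))
}

#' Rejected-line report of a parsed source
#'
#' Data lines that could not be parsed (fewer columns than the header, invalid
#' coordinates) are skipped during parsing and enumerated here.
#'
#' @param records a records tibble from [read_annotation_source()].
#' @return tibble with columns `line` (1-based line number in the file) and
#'   `reason`.
#' @export
rejects <- function(records) {
  attr(records, "rejects") %||% tibble(line = integer(), reason = character())
}

parse_info_field <- function(info) {
  if (info == "." || info == "") {
    return(setNames(character(0), character(0)))
  }
  items <- strsplit(info, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", items, fixed = TRUE)
  nms <- ifelse(eq > 0, substr(items, 1L, eq - 1L), items)
  vals <- ifelse(eq > 0, substr(items, eq + 1L, nchar(items)), "TRUE")
  setNames(vals, nms)
}

info_get <- function(info, key, alt_index = NULL) {
  v <- unname(info[key])
  if (is.na(v)) return(NA_character_)
  if (!is.null(alt_index)) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    if (length(parts) >= alt_index) return(parts[alt_index])
  }
  v
}

vcf_dialect_columns <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")

# Generic tolerant VCF reader. `extract` maps one (line, alt) pair to a named
# field vector over the dialect's inventory.
parse_vcf_generic <- function(path, source, extract) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    stop_varrag(
      sprintf("%s: not a VCF header (line 1 must declare ##fileformat=VCF)", path),
      "varrag_dialect_error"
    )
  }
  is_meta <- startsWith(lines, "##")
  hdr_idx <- which(startsWith(lines, "#CHROM"))[1]
  first_nonmeta <- which(!is_meta)[1]
  if (is.na(hdr_idx) || !identical(first_nonmeta, hdr_idx)) {
    stop_varrag(
      sprintf(
        "%s: malformed VCF header, expected #CHROM line at line %d",
        path, first_nonmeta %||% length(lines)
      ),
      "varrag_dialect_error"
    )
  }
  hdr_cols <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(hdr_cols) < 8 || !identical(hdr_cols[1:8], vcf_dialect_columns)) {
    stop_varrag(
      sprintf("%s: malformed #CHROM header at line %d", path, hdr_idx),
      "varrag_dialect_error"
    )
  }

  data_idx <- setdiff(seq_along(lines), seq_len(hdr_idx))
  data_idx <- data_idx[nzchar(lines[data_idx])]
  rej <- list()
  rows <- list()
  for (i in data_idx) {
    cols <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(cols) < 8) {
      rej[[length(rej) + 1]] <- tibble(line = i, reason = "fewer columns than header (8 required)")
      next
    }
    chrom <- normalize_chrom(cols[1])
    pos <- suppressWarnings(as.integer(cols[2]))
    if (is.na(chrom)) {
      rej[[length(rej) + 1]] <- tibble(line = i, reason = paste0("unrecognized chromosome label: ", cols[1]))
      next
    }
    if (is.na(pos) || pos < 1) {
      rej[[length(rej) + 1]] <- tibble(line = i, reason = paste0("invalid position: ", cols[2]))
      next
    }
    info <- parse_info_field(cols[8])
    alts <- strsplit(cols[5], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      f <- extract(chrom, pos, cols[3], cols[4], alts[j], j, info, cols[7])
      rsid <- f[["dbSNP ID"]]
      rows[[length(rows) + 1]] <- list(
        chrom = chrom, pos = pos, ref = cols[4], alt = alts[j],
        rsid = if (is_na_value(rsid)) NA_character_ else rsid,
        source = source, fields = na_value(f)
      )
    }
  }
  new_records(
    bind_record_rows(rows),
    rejects = if (length(rej)) list_rbind(rej) else tibble(line = integer(), reason = character())
  )
}

bind_record_rows <- function(rows) {
  if (length(rows) == 0) {
    return(empty_records_tbl())
  }
  tibble(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    rsid = vapply(rows, `[[`, character(1), "rsid"),
    source = vapply(rows, `[[`, character(1), "source"),
    fields = lapply(rows, `[[`, "fields")
  )
}

empty_records_tbl <- function() {
  tibble(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), rsid = character(0), source = character(0),
    fields = list()
  )
}

extract_clinvar <- function(chrom, pos, id, ref, alt, j, info, filter) {
  rs <- info_get(info, "RS")
  gene <- info_get(info, "GENEINFO")
  if (!is.na(gene)) {
    # GENEINFO is symbol:id, possibly |-separated for overlapping genes
    gene <- strsplit(strsplit(gene, "|", fixed = TRUE)[[1]][1], ":", fixed = TRUE)[[1]][1]
  }
  setNames(c(
    chrom, as.character(pos), ref, alt,
    if (is.na(rs)) NA_character_ else paste0("rs", sub("^rs", "", rs)),
    if (id %in% c(".", "")) NA_character_ else id,
    info_get(info, "ALLELEID"),
    info_get(info, "CLNSPDI"),
    info_get(info, "MC"),
    info_get(info, "CLNREVSTAT"),
    info_get(info, "CLNSIG"),
    gene,
    info_get(info, "CLNDN")
  ), source_fields("ClinVar"))
}

extract_gnomad <- function(populations) {
  function(chrom, pos, id, ref, alt, j, info, filter) {
    pop_vals <- vapply(
      populations,
      function(p) info_get(info, paste0("AF_", p), alt_index = j),
      character(1)
    )
    setNames(c(
      chrom, as.character(pos), ref, alt,
      if (grepl("^rs[0-9]+$", id)) id else NA_character_,
      if (filter %in% c(".", "")) NA_character_ else filter,
      info_get(info, "AC", alt_index = j),
      info_get(info, "AN"),
      info_get(info, "AF", alt_index = j),
      pop_vals
    ), source_fields("gnomAD", populations = populations))
  }
}

extract_snpeff <- function(chrom, pos, id, ref, alt, j, info, filter) {
  ann <- info_get(info, "ANN")
  sub_fields <- rep(NA_character_, 7)
  if (!is.na(ann)) {
    entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
    parts_list <- strsplit(entries, "|", fixed = TRUE)
    hit <- which(vapply(parts_list, function(p) identical(p[1], alt), logical(1)))[1]
    parts <- parts_list[[if (is.na(hit)) 1 else hit]]
    get_part <- function(k) if (length(parts) >= k && nzchar(parts[k])) parts[k] else NA_character_
    sub_fields <- c(
      get_part(2), get_part(3), get_part(4), get_part(5),
      get_part(6), get_part(8), get_part(10)
    )
  }
  setNames(c(
    chrom, as.character(pos), ref, alt,
    if (grepl("^rs[0-9]+$", id)) id else NA_character_,
    sub_fields
  ), source_fields("SnpEff"))
}

# Generic tolerant TSV reader for the GWAS Catalog / PharmGKB dialects.
parse_tsv_generic <- function(path, source, required, extract) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0) {
    stop_varrag(sprintf("%s: empty file, no header row (line 1)", path), "varrag_dialect_error")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    stop_varrag(
      sprintf(
        "%s: malformed header at line 1, missing column(s): %s",
        path, paste(missing_cols, collapse = ", ")
      ),
      "varrag_dialect_error"
    )
  }
  rej <- list()
  rows <- list()
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[i])) next
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(cells) < length(header)) {
      n_tabs <- lengths(regmatches(lines[i], gregexpr("\t", lines[i], fixed = TRUE)))
      if (n_tabs == length(header) - 1) {
        cells <- c(cells, rep("", length(header) - length(cells)))
      } else {
        rej[[length(rej) + 1]] <- tibble(line = i, reason = "fewer columns than header")
        next
      }
    }
    if (length(cells) > length(header)) {
      rej[[length(rej) + 1]] <- tibble(line = i, reason = "more columns than header")
      next
    }
    row <- extract(setNames(cells, header))
    if (is.null(row)) {
      rej[[length(rej) + 1]] <- tibble(line = i, reason = "invalid chromosome or position")
      next
    }
    rows[[length(rows) + 1]] <- row
  }
  new_records(
    bind_record_rows(rows),
    rejects = if (length(rej)) list_rbind(rej) else tibble(line = integer(), reason = character())
  )
}

blank_na <- function(x) if (is.na(x) || x == "") NA_character_ else x

extract_gwas_row <- function(cells) {
  chrom <- normalize_chrom(cells[["CHR_ID"]])
  pos <- suppressWarnings(as.integer(cells[["CHR_POS"]]))
  if (is.na(chrom) || is.na(pos) || pos < 1) return(NULL)
  rsid <- blank_na(cells[["SNPS"]])
  if (!is.na(rsid) && !grepl("^rs[0-9]+$", rsid)) rsid <- NA_character_
  f <- setNames(c(
    chrom, as.character(pos), rsid,
    blank_na(cells[["STRONGEST SNP-RISK ALLELE"]]),
    blank_na(cells[["MAPPED_GENE"]]),
    blank_na(cells[["DISEASE/TRAIT"]]),
    blank_na(cells[["P-VALUE"]]),
    blank_na(cells[["OR or BETA"]]),
    blank_na(cells[["STUDY ACCESSION"]])
  ), source_fields("GWASCatalog"))
  list(
    chrom = chrom, pos = pos, ref = ".", alt = ".", rsid = rsid,
    source = "GWASCatalog", fields = na_value(f)
  )
}

extract_pharmgkb_row <- function(cells) {
  loc <- strsplit(cells[["Location"]], ":", fixed = TRUE)[[1]]
  if (length(loc) != 2) return(NULL)
  chrom <- normalize_chrom(loc[1])
  pos <- suppressWarnings(as.integer(loc[2]))
  if (is.na(chrom) || is.na(pos) || pos < 1) return(NULL)
  rsid <- blank_na(cells[["Variant/Haplotypes"]])
  if (!is.na(rsid) && !grepl("^rs[0-9]+$", rsid)) rsid <- NA_character_
  f <- setNames(c(
    chrom, as.character(pos), rsid,
    blank_na(cells[["Clinical Annotation ID"]]),
    blank_na(cells[["Gene"]]),
    blank_na(cells[["Phenotype(s)"]]),
    blank_na(cells[["Level of Evidence"]]),
    blank_na(cells[["Phenotype Category"]]),
    blank_na(cells[["Drug(s)"]])
  ), source_fields("PharmGKB"))
  list(
    chrom = chrom, pos = pos, ref = ".", alt = ".", rsid = rsid,
    source = "PharmGKB", fields = na_value(f)
  )
}

#' Parse an annotation source file into records
#'
#' Reads one of the five supported source dialects and emits one record per
#' (data line, alternate allele) pair, each carrying the dialect's full
#' ordered field map with `"NA"` for absent values. Multi-allelic VCF lines
#' are split into one record per alternate allele (with per-allele INFO values
#' such as gnomAD `AC`/`AF` indexed accordingly). Malformed headers abort with
#' a dialect error naming the offending line; malformed data lines are
#' collected into the [rejects()] report and parsing continues.
#'
#' @param path file path (VCF for ClinVar/gnomAD/SnpEff, header-rowed TSV for
#'   GWAS Catalog/PharmGKB; `.gz` accepted).
#' @param dialect one of [varrag_sources].
#' @param populations gnomAD population codes to extract (gnomAD only).
#' @return a records tibble (columns `chrom`, `pos`, `ref`, `alt`, `rsid`,
#'   `source`, `fields`) with a rejects report attached.
#' @examples
#' dir <- tempfile()
#' paths <- simulate_annotation_sources(dir, n_per_source = 3, seed = 1)
#' read_annotation_source(paths$ClinVar, "ClinVar")
#' @export
read_annotation_source <- function(path, dialect,
                                   populations = gnomad_default_populations) {
  dialect <- match.arg(dialect, varrag_sources)
  if (!file.exists(path)) {
    stop_varrag(sprintf("file does not exist: %s", path), "varrag_io_error")
  }
  switch(dialect,
    ClinVar = parse_vcf_generic(path, "ClinVar", extract_clinvar),
    gnomAD = parse_vcf_generic(path, "gnomAD", extract_gnomad(populations)),
    SnpEff = parse_vcf_generic(path, "SnpEff", extract_snpeff),
    GWASCatalog = parse_tsv_generic(
      path, "GWASCatalog",
      required = c(
        "DISEASE/TRAIT", "CHR_ID", "CHR_POS", "SNPS", "MAPPED_GENE",
        "P-VALUE", "STUDY ACCESSION"
      ),
      extract = extract_gwas_row
    ),
    PharmGKB = parse_tsv_generic(
      path, "PharmGKB",
      required = c(
        "Clinical Annotation ID", "Variant/Haplotypes", "Gene",
        "Level of Evidence", "Phenotype(s)", "Location"
      ),
      extract = extract_pharmgkb_row
    )
  )
}

# Condition values are compared as natural language downstream: multi-valued
# annotations (ClinVar joins phenotypes with "|") become "; "-separated and
# underscores become spaces.
normalize_condition <- function(x) {
  out <- gsub("|", "; ", x, fixed = TRUE)
  out <- gsub("_", " ", out, fixed = TRUE)
  na_value(out)
}

#' Normalize parsed records into searchable documents
#'
#' Maps each record to the five-column searchable document model:
#' `chrom_pos` (`<chrom>:<pos>`), `rsid`, `gene`, `condition` (multi-valued
#' conditions joined with `"; "`, underscores replaced by spaces) and
#' `content` (a deterministic `name=value; ` serialization of all remaining
#' fields in declared order, with delimiter-escaped values). Provenance is
#' recorded in `source_name` and `source_url`; URLs are built from per-source
#' templates (ClinVar keyed on the Variation ID, gnomAD on chrom-pos-ref-alt,
#' PharmGKB on the clinical-annotation ID) and are `"NA"` for GWAS Catalog and
#' SnpEff. Missing inputs surface as `"NA"`, never as an error, and a value
#' present in the source is never turned into `"NA"`.
#'
#' @param records a records tibble from [read_annotation_source()].
#' @param url_templates named list of `sprintf` templates, see
#'   [varrag_url_templates()].
#' @return document tibble with columns `doc_id`, `chrom_pos`, `rsid`, `gene`,
#'   `condition`, `content`, `source_name`, `source_url`.
#' @export
normalize_records <- function(records, url_templates = varrag_url_templates()) {
  if (nrow(records) == 0) {
    return(tibble(
      doc_id = character(0), chrom_pos = character(0), rsid = character(0),
      gene = character(0), condition = character(0), content = character(0),
      source_name = character(0), source_url = character(0)
    ))
  }
  recs <- as_tibble(records)
  recs <- recs |>
    group_by(.data$source) |>
    mutate(doc_id = sprintf("%s-%06d", tolower(.data$source), row_number())) |>
    ungroup()

  field_or_na <- function(f, nm) {
    if (nm %in% names(f)) na_value(f[[nm]]) else VARRAG_NA
  }
  one_url <- function(i) {
    f <- recs$fields[[i]]
    src <- recs$source[[i]]
    if (src == "ClinVar" && !is_na_value(f[["Variation ID"]])) {
      sprintf(url_templates$ClinVar, f[["Variation ID"]])
    } else if (src == "gnomAD") {
      sprintf(
        url_templates$gnomAD,
        paste(sub("^chr", "", recs$chrom[[i]]), recs$pos[[i]],
          recs$ref[[i]], recs$alt[[i]],
          sep = "-"
        )
      )
    } else if (src == "PharmGKB" && !is_na_value(f[["clinical annotation ID"]])) {
      sprintf(url_templates$PharmGKB, f[["clinical annotation ID"]])
    } else {
      VARRAG_NA
    }
  }
  tibble(
    doc_id = recs$doc_id,
    chrom_pos = paste0(recs$chrom, ":", recs$pos),
    rsid = vapply(recs$fields, field_or_na, character(1), nm = "dbSNP ID"),
    gene = vapply(recs$fields, field_or_na, character(1), nm = "gene"),
    condition = normalize_condition(
      vapply(recs$fields, field_or_na, character(1), nm = "condition")
    ),
    content = vapply(
      seq_len(nrow(recs)),
      function(i) serialize_content(recs$fields[[i]], recs$source[[i]]),
      character(1)
    ),
    source_name = recs$source,
    source_url = vapply(seq_len(nrow(recs)), one_url, character(1))
  )
}
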