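# Seeded synthetic-data generator emulating the five annotation-source
# dialects (field inventories, missing-value patterns, ID formats) so that
# parsing, indexing, retrieval and evaluation are testable without downloads.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default gene-symbol pool for synthetic cohorts
#'
#' The ten most well-studied human genes (used by the well-studied-gene
#' benchmark protocol) followed by synthetic symbols, so single-field
#' fine-tuning designs over 300 genes are reachable with the default pool.
#'
#' @param n pool size (at least 10).
#' @return character vector of `n` gene symbols.
#' @export
default_gene_pool <- function(n = 300) {
  stopifnot(n >= 10)
  well_studied <- c(
    "TP53", "TNF", "EGFR", "VEGFA", "APOE",
    "IL6", "TGFB1", "MTHFR", "ESR1", "AKT1"
  )
  c(well_studied, sprintf("SYG%03d", seq_len(n - 10)))[seq_len(n)]
}

#' Default condition-phrase pool for synthetic cohorts
#'
#' Includes hyphenated and underscore variants (ClinVar style) to exercise the
#' analyzer's hyphen splitting and the Jaro condition matcher.
#' @return character vector of condition phrases.
#' @export
default_condition_pool <- function() {
  c(
    "Cystic_fibrosis", "Hereditary_breast_ovarian_cancer_syndrome",
    "Long-QT_syndrome_1", "Familial_hypercholesterolemia", "Lynch_syndrome",
    "not_provided", "not_specified", "Cardiovascular_phenotype",
    "Hereditary_cancer-predisposing_syndrome", "Marfan_syndrome",
    "Charcot-Marie-Tooth_disease", "Dilated_cardiomyopathy_1A",
    "Retinitis_pigmentosa", "Maturity-onset_diabetes_of_the_young",
    "Alzheimer_disease_type_2", "Noonan_syndrome_1",
    "Duchenne_muscular_dystrophy",
    "Glucose-6-phosphate_dehydrogenase_deficiency", "Phenylketonuria",
    "Hemochromatosis_type_1", "Beta-thalassemia", "Sickle_cell_anemia",
    "Coronary_artery_disease", "Type_2_diabetes_mellitus",
    "Rheumatoid_arthritis", "Inflammatory_bowel_disease", "Asthma",
    "Chronic_obstructive_pulmonary_disease", "Warfarin_response",
    "Clopidogrel_response"
  )
}

effect_pool <- c(
  "missense_variant", "synonymous_variant", "stop_gained",
  "splice_region_variant", "intron_variant", "frameshift_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant"
)

so_accessions <- c(
  missense_variant = "SO:0001583", synonymous_variant = "SO:0001819",
  stop_gained = "SO:0001587", splice_region_variant = "SO:0001630",
  intron_variant = "SO:0001627", frameshift_variant = "SO:0001589",
  `5_prime_UTR_variant` = "SO:0001623", `3_prime_UTR_variant` = "SO:0001624"
)

review_pool <- c(
  "criteria_provided,_single_submitter",
  "criteria_provided,_multiple_submitters,_no_conflicts",
  "reviewed_by_expert_panel", "no_assertion_criteria_provided"
)

status_pool <- c(
  "Pathogenic", "Likely_pathogenic", "Uncertain_significance",
  "Likely_benign", "Benign", "not_provided"
)

drug_pool <- c(
  "warfarin", "clopidogrel", "simvastatin", "tamoxifen",
  "azathioprine", "fluorouracil", "codeine", "abacavir"
)

# Drop values to NA independently at the configured missing rate.
drop_missing <- function(x, rate) {
  if (length(x) == 0) return(x)
  ifelse(runif(length(x)) < rate, NA_character_, as.character(x))
}

vcf_info_pair <- function(key, value) {
  ifelse(is.na(value), NA_character_, paste0(key, "=", value))
}

vcf_info_join <- function(...) {
  items <- list(...)
  vapply(seq_along(items[[1]]), function(i) {
    parts <- vapply(items, `[[`, character(1), i)
    parts <- parts[!is.na(parts)]
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))
}

write_vcf <- function(path, meta, chrom, pos, id, ref, alt, filter, info) {
  header <- c(
    "##fileformat=VCFv4.2",
    meta,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      sep = "\t"
    )
  )
  body <- if (length(chrom)) {
    paste(chrom, pos, id, ref, alt, ".", filter, info, sep = "\t")
  } else {
    character(0)
  }
  readr::write_lines(c(header, body), path)
  path
}

write_dialect_tsv <- function(path, df) {
  df[] <- lapply(df, function(x) ifelse(is.na(x), "", as.character(x)))
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t"))
  )
  readr::write_lines(lines, path)
  path
}

#' Generate a seeded synthetic annotation cohort in all five source dialects
#'
#' Emits a ClinVar-dialect VCF carrying the 13 informative annotation fields,
#' a gnomAD-exome-dialect VCF with population allele frequencies, a
#' SnpEff-dialect VCF annotating the same variants as the ClinVar file, and
#' GWAS Catalog / PharmGKB TSVs with their header rows. Fields subject to
#' missingness are dropped independently at `missing_rate`. Chromosome:position
#' keys are unique within and across sources (the SnpEff file intentionally
#' shares the ClinVar coordinates it annotates) and rsIDs are unique
#' everywhere. The same configuration always produces byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_source number of variants per source file.
#' @param seed integer seed governing all randomness.
#' @param gene_pool,condition_pool symbol and phrase pools.
#' @param missing_rate probability in `[0, 1]` that an optional field is
#'   dropped (`"NA"` after normalization).
#' @param chrom_set chromosome labels to draw from.
#' @param pos_range integer interval positions are drawn from (without
#'   replacement across the cohort).
#' @return named list of file paths, one per source, invisibly also written to
#'   `sources.json` in `out_dir`.
#' @examples
#' paths <- simulate_annotation_sources(tempfile(), n_per_source = 5, seed = 1)
#' @export
simulate_annotation_sources <- function(out_dir,
                                        n_per_source = 100,
                                        seed = 1,
                                        gene_pool = default_gene_pool(),
                                        condition_pool = default_condition_pool(),
                                        missing_rate = 0.1,
                                        chrom_set = paste0("chr", c(1:22, "X")),
                                        pos_range = c(10000L, 50000000L)) {
  stopifnot(
    length(gene_pool) > 0, length(condition_pool) > 0,
    missing_rate >= 0, missing_rate <= 1, n_per_source >= 0
  )
  n <- as.integer(n_per_source)
  n_pos <- 4L * n
  if (diff(pos_range) + 1 < n_pos) {
    stop_varrag(
      "pos_range too narrow to draw unique positions for the cohort",
      "varrag_uniqueness_error"
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  with_local_seed(seed, {
    pos <- sample.int(diff(pos_range) + 1L, n_pos) + pos_range[1] - 1L
    chrom <- sample(chrom_set, n_pos, replace = TRUE)
    rsid_num <- sample.int(9e7, 4L * n) + 1e6
    bases <- c("A", "C", "G", "T")
    pick_alt <- function(ref) vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1), USE.NAMES = FALSE)
    slot <- function(block) seq_len(n) + (block - 1L) * n
    take <- function(x, block) if (n) x[slot(block)] else character(0)

    ## --- ClinVar (block 1), SnpEff reuses the same variants -----------------
    cv_chrom <- take(chrom, 1); cv_pos <- take(pos, 1)
    cv_ref <- if (n) sample(bases, n, replace = TRUE) else character(0)
    cv_alt <- pick_alt(cv_ref)
    cv_rsid <- paste0("rs", take(rsid_num, 1))
    cv_varid <- if (n) sample.int(3e6, n) else integer(0)
    cv_alleleid <- cv_varid + 15000L
    cv_gene <- if (n) sample(gene_pool, n, replace = TRUE) else character(0)
    two <- if (n) runif(n) < 0.3 else logical(0)
    cv_cond <- if (n) {
      vapply(seq_len(n), function(i) {
        k <- if (two[i]) 2L else 1L
        paste(sample(condition_pool, k), collapse = "|")
      }, character(1))
    } else {
      character(0)
    }
    cv_effect <- if (n) sample(effect_pool, n, replace = TRUE) else character(0)
    cv_mc <- paste0(so_accessions[cv_effect], "|", cv_effect)
    cv_review <- if (n) sample(review_pool, n, replace = TRUE) else character(0)
    cv_status <- if (n) sample(status_pool, n, replace = TRUE) else character(0)
    cv_spdi <- if (n) {
      paste0(refseq_accession(cv_chrom), ":", cv_pos - 1L, ":", cv_ref, ":", cv_alt)
    } else {
      character(0)
    }

    clinvar_path <- write_vcf(
      file.path(out_dir, "clinvar.vcf"),
      meta = c(
        '##INFO=<ID=ALLELEID,Number=1,Type=Integer,Description="Allele ID">',
        '##INFO=<ID=CLNDN,Number=.,Type=String,Description="Preferred disease name(s)">',
        '##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description="Review status">',
        '##INFO=<ID=CLNSIG,Number=.,Type=String,Description="Germline classification">',
        '##INFO=<ID=CLNSPDI,Number=1,Type=String,Description="Canonical SPDI">',
        '##INFO=<ID=GENEINFO,Number=1,Type=String,Description="Gene symbol:gene id">',
        '##INFO=<ID=MC,Number=.,Type=String,Description="Molecular consequence">',
        '##INFO=<ID=RS,Number=.,Type=String,Description="dbSNP ID">'
      ),
      chrom = cv_chrom, pos = cv_pos, id = cv_varid, ref = cv_ref, alt = cv_alt,
      filter = ".",
      info = vcf_info_join(
        vcf_info_pair("ALLELEID", drop_missing(cv_alleleid, missing_rate)),
        vcf_info_pair("CLNDN", drop_missing(cv_cond, missing_rate)),
        vcf_info_pair("CLNREVSTAT", drop_missing(cv_review, missing_rate)),
        vcf_info_pair("CLNSIG", drop_missing(cv_status, missing_rate)),
        vcf_info_pair("CLNSPDI", drop_missing(cv_spdi, missing_rate)),
        vcf_info_pair("GENEINFO", drop_missing(
          paste0(cv_gene, ":", cv_varid + 7000L), missing_rate
        )),
        vcf_info_pair("MC", drop_missing(cv_mc, missing_rate)),
        vcf_info_pair("RS", drop_missing(sub("^rs", "", cv_rsid), missing_rate))
      )
    )

    ## --- SnpEff over the ClinVar variants -----------------------------------
    ann <- if (n) {
      paste(
        cv_alt, cv_effect,
        sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), n, replace = TRUE),
        cv_gene, sprintf("ENSG%011d", cv_varid),
        "transcript", sprintf("ENST%011d", cv_varid + 500L),
        "protein_coding", "1/1",
        paste0("c.", sample.int(5000, n, replace = TRUE), cv_ref, ">", cv_alt),
        sep = "|"
      )
    } else {
      character(0)
    }
    snpeff_path <- write_vcf(
      file.path(out_dir, "snpeff.vcf"),
      meta = '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations: Allele|Annotation|Annotation_Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|Transcript_BioType|Rank|HGVS.c">',
      chrom = cv_chrom, pos = cv_pos, id = ".", ref = cv_ref, alt = cv_alt,
      filter = ".",
      info = vcf_info_join(vcf_info_pair("ANN", drop_missing(ann, missing_rate)))
    )

    ## --- gnomAD exomes (block 2) ---------------------------------------------
    gn_chrom <- take(chrom, 2); gn_pos <- take(pos, 2)
    gn_ref <- if (n) sample(bases, n, replace = TRUE) else character(0)
    gn_alt <- pick_alt(gn_ref)
    gn_rsid <- paste0("rs", take(rsid_num, 2))
    gn_an <- if (n) 2L * (sample.int(75000, n) + 50000L) else integer(0)
    gn_af_raw <- if (n) stats::rbeta(n, 0.2, 20) else numeric(0)
    gn_ac <- pmax(1L, as.integer(round(gn_af_raw * gn_an)))
    gn_af <- signif(gn_ac / gn_an, 5)
    pop_af <- lapply(gnomad_default_populations, function(p) {
      as.character(signif(pmin(1, gn_af * runif(n, 0, 3)), 5))
    })
    names(pop_af) <- gnomad_default_populations
    pop_pairs <- lapply(gnomad_default_populations, function(p) {
      vcf_info_pair(paste0("AF_", p), drop_missing(pop_af[[p]], missing_rate))
    })
    gnomad_path <- write_vcf(
      file.path(out_dir, "gnomad.vcf"),
      meta = c(
        '##INFO=<ID=AC,Number=A,Type=Integer,Description="Alternate allele count">',
        '##INFO=<ID=AN,Number=1,Type=Integer,Description="Total allele number">',
        '##INFO=<ID=AF,Number=A,Type=Float,Description="Alternate allele frequency">',
        paste0(
          '##INFO=<ID=AF_', gnomad_default_populations,
          ',Number=A,Type=Float,Description="Allele frequency in ',
          gnomad_default_populations, ' population">'
        )
      ),
      chrom = gn_chrom, pos = gn_pos,
      id = ifelse(is.na(drop_missing(gn_rsid, missing_rate)), ".", gn_rsid),
      ref = gn_ref, alt = gn_alt, filter = "PASS",
      info = do.call(vcf_info_join, c(
        list(
          vcf_info_pair("AC", as.character(gn_ac)),
          vcf_info_pair("AN", as.character(gn_an)),
          vcf_info_pair("AF", as.character(gn_af))
        ),
        pop_pairs
      ))
    )

    ## --- GWAS Catalog (block 3) ----------------------------------------------
    gw_chrom <- take(chrom, 3); gw_pos <- take(pos, 3)
    gw_rsid <- paste0("rs", take(rsid_num, 3))
    natural <- function(x) gsub("_", " ", x)
    gw <- tibble(
      `DISEASE/TRAIT` = if (n) natural(sample(condition_pool, n, replace = TRUE)) else character(0),
      CHR_ID = sub("^chr", "", gw_chrom),
      CHR_POS = as.character(gw_pos),
      SNPS = gw_rsid,
      `STRONGEST SNP-RISK ALLELE` = drop_missing(
        paste0(gw_rsid, "-", if (n) sample(bases, n, replace = TRUE) else character(0)),
        missing_rate
      ),
      MAPPED_GENE = drop_missing(
        if (n) sample(gene_pool, n, replace = TRUE) else character(0), missing_rate
      ),
      `P-VALUE` = if (n) sprintf("%.0E", 10^-runif(n, 6, 30)) else character(0),
      `OR or BETA` = drop_missing(
        as.character(signif(runif(n, 0.8, 3.5), 3)), missing_rate
      ),
      `STUDY ACCESSION` = if (n) sprintf("GCST%06d", sample.int(900000, n)) else character(0)
    )
    gwas_path <- write_dialect_tsv(file.path(out_dir, "gwas_catalog.tsv"), gw)

    ## --- PharmGKB (block 4) ---------------------------------------------------
    pg_chrom <- take(chrom, 4); pg_pos <- take(pos, 4)
    pg <- tibble(
      `Clinical Annotation ID` = if (n) sprintf("%09d", sample.int(2e6, n) + 6e8) else character(0),
      `Variant/Haplotypes` = paste0("rs", take(rsid_num, 4)),
      Gene = drop_missing(
        if (n) sample(gene_pool, n, replace = TRUE) else character(0), missing_rate
      ),
      `Level of Evidence` = if (n) sample(c("1A", "1B", "2A", "2B", "3", "4"), n, replace = TRUE) else character(0),
      `Phenotype Category` = drop_missing(
        if (n) sample(c("Efficacy", "Toxicity", "Dosage", "Metabolism/PK"), n, replace = TRUE) else character(0),
        missing_rate
      ),
      `Drug(s)` = drop_missing(
        if (n) sample(drug_pool, n, replace = TRUE) else character(0), missing_rate
      ),
      `Phenotype(s)` = drop_missing(
        if (n) natural(sample(condition_pool, n, replace = TRUE)) else character(0),
        missing_rate
      ),
      Location = paste0(pg_chrom, ":", pg_pos)
    )
    pharmgkb_path <- write_dialect_tsv(file.path(out_dir, "pharmgkb.tsv"), pg)

    paths <- list(
      ClinVar = clinvar_path, gnomAD = gnomad_path, SnpEff = snpeff_path,
      GWASCatalog = gwas_path, PharmGKB = pharmgkb_path
    )
    jsonlite::write_json(
      list(
        sources = lapply(paths, basename),
        config = list(
          n_per_source = n, seed = seed, missing_rate = missing_rate,
          gene_pool_size = length(gene_pool),
          condition_pool_size = length(condition_pool)
        )
      ),
      file.path(out_dir, "sources.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    paths
  })
}

#' Causal-variant triage fixture
#'
#' A fixed five-variant integration fixture for the disease-diagnosis
#' scenario: a cystic fibrosis causal variant (rs75527207, CFTR) plus four
#' variants unrelated to cystic fibrosis, together with a respiratory-symptom
#' query string. Only the causal variant's document mentions cystic fibrosis.
#' Coordinates and annotations other than the rsIDs are synthetic.
#'
#' @return list with `symptom` (query text), `rsids` (all five), `causal_rsid`,
#'   `records` (ClinVar-dialect records) and `documents` (normalized).
#' @export
triage_fixture <- function() {
  rsids <- c("rs75527207", "rs116133558", "rs62143206", "rs58365105", "rs28777")
  chrom <- c("chr7", "chr11", "chr19", "chr3", "chr5")
  pos <- c(117559590L, 5226778L, 44908822L, 46373452L, 33958959L)
  ref <- c("G", "C", "T", "G", "A")
  alt <- c("A", "T", "C", "A", "C")
  gene <- c("CFTR", "SYG101", "SYG102", "SYG103", "SYG104")
  cond <- c(
    "Cystic_fibrosis", "not_provided", "Coronary_artery_disease",
    "Asthma", "not_specified"
  )
  status <- c("Pathogenic", "not_provided", "Benign", "Benign", "Likely_benign")
  varid <- c(7105L, 900101L, 900102L, 900103L, 900104L)

  fields <- lapply(seq_along(rsids), function(i) {
    setNames(c(
      chrom[i], as.character(pos[i]), ref[i], alt[i], rsids[i],
      as.character(varid[i]), as.character(varid[i] + 15000L),
      paste0(refseq_accession(chrom[i]), ":", pos[i] - 1L, ":", ref[i], ":", alt[i]),
      "SO:0001583|missense_variant",
      "criteria_provided,_multiple_submitters,_no_conflicts",
      status[i], gene[i], cond[i]
    ), source_fields("ClinVar"))
  })
  records <- new_records(tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, rsid = rsids,
    source = "ClinVar", fields = fields
  ))
  list(
    symptom = paste(
      "Patient has episodes of worsening respiratory symptoms and declining",
      "lung function. Which of these variants is most likely disease-causing?"
    ),
    rsids = rsids,
    causal_rsid = "rs75527207",
    records = records,
    documents = normalize_records(records)
  )
}
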