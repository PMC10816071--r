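# Data model: controlled vocabularies, record validation and origin derivation.
# Variants, gene evidence and subjects are plain data.frames with one row per
# record; '.'-style missing values are real NAs after reading.

GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "hemizygous", "absent", "unknown")

VARIANT_CLASS_LEVELS <- c("SNV", "small_indel", "CNV_del", "CNV_dup", "mtDNA")

CONSEQUENCE_LEVELS <- c(
  "missense", "frameshift", "stop_gain", "inframe_indel",
  "splice_acceptor", "splice_donor", "splice_region",
  "synonymous", "noncoding", "whole_gene_del", "whole_gene_dup"
)

# Consequences that change the amino-acid code ("coding" in the Qualifying
# sense); splice acceptor/donor additionally need the splice-score gate and
# whole-gene duplications are config-gated.
CODING_CONSEQUENCES <- c(
  "missense", "frameshift", "stop_gain", "inframe_indel",
  "splice_acceptor", "splice_donor", "whole_gene_del", "whole_gene_dup"
)

# Protein-destroying ("null") consequences: conservation waiver + PVS1.
NULL_CONSEQUENCES <- c("frameshift", "stop_gain", "splice_acceptor",
                       "splice_donor", "whole_gene_del")

REGRESSION_LEVELS <- c("none", "single", "multiple")

ID_SEVERITY_LEVELS <- c("none", "mild", "moderate", "severe")

MITO_DOMAINS <- c(
  "neuromuscular", "neurodevelopmental", "neuropsychiatric", "functional",
  "endocrine", "immunological", "metabolic", "enzymological"
)

LAB_CLASSIFICATION_LEVELS <- c(
  "Pathogenic", "Likely_Pathogenic", "Uncertain", "Likely_Negative",
  "Candidate", "none"
)

CHROMOSOME_LEVELS <- c(as.character(1:22), "X", "Y", "MT")

VARIANT_COLUMNS <- c(
  "subject_id", "gene", "chromosome", "position", "end", "variant_class",
  "consequence", "proband_genotype", "mother_genotype", "father_genotype",
  "allele_frequency", "phylop", "phastcons", "splice_rf", "splice_ada",
  "manual_conserved", "igv_verified", "clinical_correlation",
  "heteroplasmy_fraction", "maternal_ratio", "maternal_inheritance_ratio",
  "maternal_pedigree_flag", "on_lab_report", "lab_report_classification"
)

EVIDENCE_COLUMNS <- c(
  "gene", "is_mtDNA", "sfari_rank", "syndromic", "autdb_stars",
  "de_novo_cadd20_in_other_ndd", "variant_reported_in_asd_case",
  "asd_cnv_count", "asd_like_animal_model", "lof_intolerant",
  "fxs_gene_asd_enriched", "brain_exon_dnm_accumulation",
  "direct_link_to_direct_gene", "linked_other_ndd_cadd20",
  "asd_pathway_member", "predominately_non_nervous", "ar_only_disease_gene"
)

SUBJECT_COLUMNS <- c(
  "subject_id", "sex", "age_years", "tics", "ocd", "absent_speech",
  "seizures", "regression", "id_severity", "affected_first_degree_relative",
  "mother_affected_significant_ndd", "father_affected_significant_ndd",
  "mito_domains", "lab_report_positive"
)

#' Derive variant origin from trio genotypes
#'
#' Pure function of the three genotypes. A variant is de novo when the
#' proband carries the allele (het, hom_alt or hemizygous) and neither parent
#' does (hom_ref, or absent for hemizygous de novo events); maternal or
#' paternal when exactly one parent carries it; biparental when both do;
#' unknown when any genotype is unknown or the proband does not carry the
#' allele.
#'
#' @param proband,mother,father character vectors of genotypes, drawn from
#'   hom_ref, het, hom_alt, hemizygous, absent, unknown.
#' @return Character vector: de_novo, maternal, paternal, biparental or
#'   unknown.
#' @export
#' @examples
#' derive_origin("het", "hom_ref", "hom_ref") # de_novo
#' derive_origin("het", "het", "hom_ref")     # maternal
derive_origin <- function(proband, mother, father) {
  stopifnot(length(mother) == length(proband), length(father) == length(proband))
  carries <- function(g) g %in% c("het", "hom_alt", "hemizygous")
  out <- character(length(proband))
  for (i in seq_along(proband)) {
    g <- c(proband[i], mother[i], father[i])
    if (any(is.na(g)) || any(g == "unknown") || !all(g %in% GENOTYPE_LEVELS)) {
      out[i] <- "unknown"
    } else if (!carries(g[1])) {
      out[i] <- "unknown"
    } else {
      m <- carries(g[2])
      f <- carries(g[3])
      out[i] <- if (m && f) "biparental" else if (m) "maternal" else if (f) "paternal" else "de_novo"
    }
  }
  out
}

#' Default (all-negative) gene-evidence record
#'
#' Used for genes absent from the evidence table; such genes fall to the
#' default B2 tier downstream.
#'
#' @param gene gene symbol.
#' @return One-row data.frame with every evidence field negative/absent.
#' @export
default_evidence <- function(gene) {
  data.frame(
    gene = gene, is_mtDNA = FALSE, sfari_rank = NA_integer_,
    syndromic = FALSE, autdb_stars = NA_integer_,
    de_novo_cadd20_in_other_ndd = FALSE, variant_reported_in_asd_case = FALSE,
    asd_cnv_count = 0L, asd_like_animal_model = FALSE, lof_intolerant = FALSE,
    fxs_gene_asd_enriched = FALSE, brain_exon_dnm_accumulation = FALSE,
    direct_link_to_direct_gene = FALSE, linked_other_ndd_cadd20 = FALSE,
    asd_pathway_member = FALSE, predominately_non_nervous = FALSE,
    ar_only_disease_gene = FALSE, stringsAsFactors = FALSE
  )
}

# Validate a variant table: returns list(variants = clean rows with derived
# origin, errors = data.frame(row, field, problem)). Structural problems
# (missing mandatory columns) are fatal; row-level problems are collected.
validate_variants <- function(df) {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  errors <- list()
  note <- function(row, field, problem) {
    errors[[length(errors) + 1L]] <<- data.frame(
      row = row, field = field, problem = problem, stringsAsFactors = FALSE
    )
  }
  in_unit <- function(x) is.na(x) | (x >= 0 & x <= 1)
  bad <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$subject_id) || !nzchar(r$subject_id)) {
      note(i, "subject_id", "missing subject identifier"); bad[i] <- TRUE
    }
    if (!r$chromosome %in% CHROMOSOME_LEVELS) {
      note(i, "chromosome", paste0("invalid chromosome '", r$chromosome, "'")); bad[i] <- TRUE
    }
    if (!r$variant_class %in% VARIANT_CLASS_LEVELS) {
      note(i, "variant_class", paste0("invalid variant class '", r$variant_class, "'")); bad[i] <- TRUE
    }
    if (!r$consequence %in% CONSEQUENCE_LEVELS) {
      note(i, "consequence", paste0("invalid consequence '", r$consequence, "'")); bad[i] <- TRUE
    }
    for (gcol in c("proband_genotype", "mother_genotype", "father_genotype")) {
      if (!df[[gcol]][i] %in% GENOTYPE_LEVELS) {
        note(i, gcol, paste0("invalid genotype '", df[[gcol]][i], "'")); bad[i] <- TRUE
      }
    }
    if (!is.na(r$position) && !is.na(r$end) && r$end < r$position) {
      note(i, "end", "end precedes position"); bad[i] <- TRUE
    }
    if (r$variant_class %in% c("CNV_del", "CNV_dup") &&
        (is.na(r$end) || is.na(r$position) || r$end <= r$position)) {
      note(i, "end", "CNV requires end > position"); bad[i] <- TRUE
    }
    if (!in_unit(r$allele_frequency)) {
      note(i, "allele_frequency", "allele frequency outside [0, 1]"); bad[i] <- TRUE
    }
    for (scol in c("phastcons", "splice_rf", "splice_ada", "heteroplasmy_fraction")) {
      if (!in_unit(r[[scol]])) {
        note(i, scol, paste0(scol, " outside [0, 1]")); bad[i] <- TRUE
      }
    }
    if (!is.na(r$heteroplasmy_fraction) && r$chromosome != "MT") {
      note(i, "heteroplasmy_fraction", "heteroplasmy on a non-mitochondrial variant"); bad[i] <- TRUE
    }
    if (r$chromosome == "MT" && is.na(r$heteroplasmy_fraction)) {
      note(i, "heteroplasmy_fraction", "mitochondrial variant without heteroplasmy"); bad[i] <- TRUE
    }
    if (!is.na(r$manual_conserved) && !r$manual_conserved %in% c("yes", "no")) {
      note(i, "manual_conserved", "manual_conserved must be yes, no or missing"); bad[i] <- TRUE
    }
    if (!is.na(r$lab_report_classification) &&
        !r$lab_report_classification %in% LAB_CLASSIFICATION_LEVELS) {
      note(i, "lab_report_classification", "invalid laboratory classification"); bad[i] <- TRUE
    }
  }
  clean <- df[!bad, , drop = FALSE]
  clean$origin <- derive_origin(
    clean$proband_genotype, clean$mother_genotype, clean$father_genotype
  )
  if (!"variant_id" %in% names(clean)) {
    clean$variant_id <- sprintf("%s:%s:%s", clean$subject_id, clean$gene,
                                seq_len(nrow(clean)) + sum(bad[seq_len(0)]))
    clean$variant_id <- make.unique(clean$variant_id, sep = "_")
  }
  errs <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(), field = character(), problem = character(),
               stringsAsFactors = FALSE)
  list(variants = clean, errors = errs)
}

validate_subjects <- function(df) {
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  probs <- character()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$sex %in% c("M", "F")) {
      probs <- c(probs, sprintf("row %d: invalid sex '%s'", i, r$sex))
    }
    if (!r$regression %in% REGRESSION_LEVELS) {
      probs <- c(probs, sprintf("row %d: invalid regression token '%s'", i, r$regression))
    }
    if (!r$id_severity %in% ID_SEVERITY_LEVELS) {
      probs <- c(probs, sprintf("row %d: invalid id_severity token '%s'", i, r$id_severity))
    }
    doms <- parse_mito_domains(r$mito_domains)
    extra <- setdiff(doms, MITO_DOMAINS)
    if (length(extra) > 0) {
      probs <- c(probs, sprintf("row %d: unknown mitochondrial domain(s): %s",
                                i, paste(extra, collapse = ", ")))
    }
  }
  if (anyDuplicated(df$subject_id)) {
    probs <- c(probs, "duplicate subject_id values")
  }
  if (length(probs) > 0) {
    stop("phenotype table validation failed:\n  ", paste(probs, collapse = "\n  "))
  }
  df
}

parse_mito_domains <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}
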