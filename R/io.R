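# Readers and writers for the three tab-separated input tables and the
# classified-variant output. All tables are UTF-8 TSV with '.' for missing.

read_tsv_dots <- function(path) {
  utils::read.table(
    path, header = TRUE, sep = "\t", quote = "", comment.char = "",
    na.strings = ".", stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = "character", fileEncoding = "UTF-8"
  )
}

as_num <- function(x) suppressWarnings(as.numeric(x))
as_int <- function(x) suppressWarnings(as.integer(x))
as_bool <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "yes")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "no")] <- FALSE
  out
}

#' Read an annotated variant table
#'
#' One row per variant per subject, tab-separated, `.` for missing values.
#' The header must name every mandatory column (see `triopdv:::VARIANT_COLUMNS`).
#' The derived `origin` column is computed from the trio genotypes; malformed
#' rows are collected into an error report rather than silently dropped.
#'
#' @param path TSV file path.
#' @return List with `variants` (clean rows, plus `origin` and `variant_id`)
#'   and `errors` (data.frame of row-level validation problems).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  raw <- read_tsv_dots(path)
  missing_cols <- setdiff(VARIANT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- raw
  for (col in c("position", "end")) df[[col]] <- as_num(df[[col]])
  for (col in c("allele_frequency", "phylop", "phastcons", "splice_rf",
                "splice_ada", "heteroplasmy_fraction", "maternal_ratio",
                "maternal_inheritance_ratio")) {
    df[[col]] <- as_num(df[[col]])
  }
  for (col in c("igv_verified", "clinical_correlation",
                "maternal_pedigree_flag", "on_lab_report")) {
    df[[col]] <- as_bool(df[[col]])
  }
  validate_variants(df)
}

#' Read a gene-evidence table
#'
#' Tab-separated, one row per gene, boolean columns encoded 0/1. Duplicate
#' gene symbols are a fatal error. Genes absent from the table are given an
#' all-negative default record on lookup (and so fall to tier B2).
#'
#' @param path TSV file path.
#' @return data.frame keyed by `gene`.
#' @export
read_gene_evidence <- function(path) {
  if (!file.exists(path)) stop("gene evidence table not found: ", path)
  raw <- read_tsv_dots(path)
  if (nrow(raw) == 0) {
    ev <- default_evidence(character(0))
    return(ev)
  }
  missing_cols <- setdiff(EVIDENCE_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("gene evidence table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$gene)) {
    stop("duplicate gene symbol(s) in evidence table: ",
         paste(unique(raw$gene[duplicated(raw$gene)]), collapse = ", "))
  }
  df <- raw
  df$sfari_rank <- as_int(df$sfari_rank)
  df$autdb_stars <- as_int(df$autdb_stars)
  df$asd_cnv_count <- as_int(df$asd_cnv_count)
  df$asd_cnv_count[is.na(df$asd_cnv_count)] <- 0L
  bool_cols <- setdiff(EVIDENCE_COLUMNS,
                       c("gene", "sfari_rank", "autdb_stars", "asd_cnv_count"))
  for (col in bool_cols) {
    v <- as_bool(df[[col]])
    v[is.na(v)] <- FALSE
    df[[col]] <- v
  }
  if (any(df$asd_cnv_count < 0)) stop("asd_cnv_count must be nonnegative")
  bad_rank <- !is.na(df$sfari_rank) & !df$sfari_rank %in% 1:3
  if (any(bad_rank)) stop("sfari_rank must be 1, 2, 3 or missing")
  bad_stars <- !is.na(df$autdb_stars) & !df$autdb_stars %in% 0:5
  if (any(bad_stars)) stop("autdb_stars must be 0-5 or missing")
  df[EVIDENCE_COLUMNS]
}

#' Look up evidence for one gene, with all-negative default
#'
#' @param evidence data.frame from [read_gene_evidence()].
#' @param gene gene symbol.
#' @return One-row evidence data.frame.
#' @export
evidence_for_gene <- function(evidence, gene) {
  hit <- evidence[evidence$gene == gene, , drop = FALSE]
  if (nrow(hit) == 0) default_evidence(gene) else hit[1, , drop = FALSE]
}

#' Read a phenotype/pedigree table
#'
#' One row per proband. Enumerated fields (`regression`, `id_severity`) must
#' use their controlled vocabularies; `mito_domains` is a comma-separated
#' subset of the eight mitochondrial clinical domains.
#'
#' @param path TSV file path.
#' @return Validated subject data.frame.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("phenotype table not found: ", path)
  raw <- read_tsv_dots(path)
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- raw
  df$age_years <- as_int(df$age_years)
  for (col in c("tics", "ocd", "absent_speech", "seizures",
                "affected_first_degree_relative",
                "mother_affected_significant_ndd",
                "father_affected_significant_ndd", "lab_report_positive")) {
    v <- as_bool(df[[col]])
    v[is.na(v)] <- FALSE
    df[[col]] <- v
  }
  df$mito_domains[is.na(df$mito_domains)] <- ""
  validate_subjects(df)
}

#' Write and re-read a classified variant table
#'
#' TSV round-trip for classification output: `.` encodes missing, booleans
#' are written as 0/1. `read_classified_table` reproduces the written records
#' field-for-field.
#'
#' @param classified data.frame from [classify_cohort()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_classified_table <- function(classified, path) {
  out <- classified
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- ifelse(is.na(out[[col]]), NA, as.integer(out[[col]]))
  }
  utils::write.table(
    out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".",
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_classified_table
#' @export
read_classified_table <- function(path) {
  df <- read_tsv_dots(path)
  num_cols <- c("position", "end", "allele_frequency", "phylop", "phastcons",
                "splice_rf", "splice_ada", "heteroplasmy_fraction",
                "maternal_ratio", "maternal_inheritance_ratio")
  bool_cols <- c("igv_verified", "clinical_correlation",
                 "maternal_pedigree_flag", "on_lab_report", "is_direct",
                 "is_cpm")
  for (col in intersect(num_cols, names(df))) df[[col]] <- as_num(df[[col]])
  for (col in intersect(bool_cols, names(df))) df[[col]] <- as_bool(df[[col]])
  df
}

#' Minimal VCF + PED trio ingestion
#'
#' Reads a VCF 4.x file with one trio and converts it to the package's
#' variant-table layout. Annotation values are taken from INFO keys named in
#' `info_map` (e.g. `list(allele_frequency = "AF_NFE", phylop = "PHYLOP")`);
#' unmapped annotations are missing. Trio roles are taken from a standard
#' 6-column PED file: the proband is the sample whose paternal and maternal
#' identifiers are both non-zero.
#'
#' @param vcf_path VCF file path (uncompressed or bgzipped).
#' @param ped_path 6-column PED file path.
#' @param info_map named list mapping variant-table annotation columns to
#'   INFO keys.
#' @return List as from [read_variant_table()].
#' @export
read_vcf_trio <- function(vcf_path, ped_path, info_map = list()) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingestion requires the 'vcfR' package")
  }
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ped) < 6) stop("PED file must have 6 columns")
  names(ped)[1:6] <- c("family_id", "individual_id", "father_id", "mother_id",
                       "sex", "phenotype")
  proband_row <- ped[ped$father_id != "0" & ped$mother_id != "0", , drop = FALSE]
  if (nrow(proband_row) != 1) stop("PED file must describe exactly one trio proband")
  proband <- proband_row$individual_id
  father <- proband_row$father_id
  mother <- proband_row$mother_id

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  for (s in c(proband, mother, father)) {
    if (!s %in% colnames(gt)) stop("sample '", s, "' not present in VCF")
  }
  gt_code <- function(g, chrom) {
    if (is.na(g)) return("unknown")
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)[[1]]
    alt <- sum(alleles != "0" & alleles != ".")
    if (length(alleles) == 1L) {
      return(if (alt > 0) "hemizygous" else "hom_ref")
    }
    if (any(alleles == ".")) return("unknown")
    if (alt == 0) "hom_ref" else if (alt == length(alleles)) "hom_alt" else "het"
  }
  info_val <- function(i, key) {
    if (is.null(key)) return(NA_real_)
    v <- vcfR::extract.info(vcf, element = key, as.numeric = TRUE)[i]
    if (length(v) == 0) NA_real_ else v
  }
  n <- nrow(fix)
  df <- data.frame(
    subject_id = rep(proband, n),
    gene = vapply(seq_len(n), function(i) {
      g <- vcfR::extract.info(vcf, element = info_map$gene %||% "GENE")[i]
      if (is.na(g)) "unknown" else g
    }, character(1)),
    chromosome = sub("^chr", "", fix$CHROM),
    position = as.numeric(fix$POS),
    end = as.numeric(fix$POS) + pmax(nchar(fix$REF) - 1, 0),
    variant_class = ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "SNV", "small_indel"),
    consequence = {
      key <- info_map$consequence %||% "CSQ"
      v <- vcfR::extract.info(vcf, element = key)
      ifelse(is.na(v), "noncoding", v)
    },
    proband_genotype = vapply(seq_len(n), function(i) gt_code(gt[i, proband], fix$CHROM[i]), character(1)),
    mother_genotype = vapply(seq_len(n), function(i) gt_code(gt[i, mother], fix$CHROM[i]), character(1)),
    father_genotype = vapply(seq_len(n), function(i) gt_code(gt[i, father], fix$CHROM[i]), character(1)),
    stringsAsFactors = FALSE
  )
  df$variant_class[df$chromosome == "MT"] <- "mtDNA"
  num_cols <- c("allele_frequency", "phylop", "phastcons", "splice_rf",
                "splice_ada", "heteroplasmy_fraction")
  for (col in num_cols) {
    df[[col]] <- vapply(seq_len(n), function(i) info_val(i, info_map[[col]]), numeric(1))
  }
  df$manual_conserved <- NA_character_
  df$igv_verified <- TRUE
  df$clinical_correlation <- FALSE
  df$maternal_ratio <- NA_real_
  df$maternal_inheritance_ratio <- NA_real_
  df$maternal_pedigree_flag <- FALSE
  df$on_lab_report <- FALSE
  df$lab_report_classification <- "none"
  validate_variants(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
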