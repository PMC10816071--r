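# End-to-end classification: gene tiers -> Qualifying decisions ->
# compound-het phasing -> inheritance-mode (PDV) assignment -> CPM
# designation -> reduced ACMG mapping.

#' Classify a cohort of annotated trio variants
#'
#' Runs the full pipeline over a variant table, a gene-evidence table and a
#' phenotype table, adding per-variant classification columns:
#' `gene_category`, `is_direct`, `reportable_gene` (the best-tier gene of a
#' multi-gene CNV), `qualifying_status`, `reason_codes`, `pdv_mode`,
#' `partner_variant`, `is_cpm`, `acmg_lite` and `pdv_rationale`. Both
#' variants of an in-trans compound-heterozygous PDV carry the
#' autosomal-recessive mode.
#'
#' @param variants variant data.frame (as from [read_variant_table()]; a raw
#'   table without derived columns is validated first).
#' @param subjects subject data.frame (as from [read_phenotype_table()]).
#' @param evidence gene-evidence data.frame (as from [read_gene_evidence()]).
#' @param config [thresholds()] object.
#' @return The classified variant data.frame.
#' @export
#' @examples
#' fx <- load_fixture_cohort("paper_cohort")
#' cls <- classify_cohort(fx$variants, fx$subjects, fx$evidence)
#' table(cls$pdv_mode)
classify_cohort <- function(variants, subjects, evidence,
                            config = thresholds()) {
  if (!"origin" %in% names(variants)) {
    variants <- validate_variants(variants)$variants
  }
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- make.unique(
      sprintf("%s:%s", variants$subject_id, variants$gene), sep = "_"
    )
  }
  orphan <- setdiff(unique(variants$subject_id), subjects$subject_id)
  if (length(orphan) > 0) {
    stop("variant table references subject(s) missing from the phenotype ",
         "table: ", paste(orphan, collapse = ", "))
  }

  n <- nrow(variants)
  cat_info <- lapply(variants$gene, best_gene_category, evidence = evidence)
  variants$reportable_gene <- vapply(cat_info, `[[`, character(1), "gene")
  variants$gene_category <- vapply(cat_info, `[[`, character(1), "gene_category")
  variants$is_direct <- vapply(cat_info, `[[`, logical(1), "is_direct")

  variants <- qualify_variants(variants, evidence, config)

  # in-trans phasing among each subject's qualifying autosomal hets per gene
  partner <- stats::setNames(rep(NA_character_, n), variants$variant_id)
  qual_het <- variants$qualifying_status == "qualifying" &
    variants$proband_genotype == "het" &
    variants$chromosome %in% AUTOSOMES
  if (any(qual_het)) {
    groups <- split(
      variants[qual_het, , drop = FALSE],
      paste(variants$subject_id[qual_het], variants$gene[qual_het], sep = "\r")
    )
    for (g in groups) {
      if (nrow(g) < 2) next
      ph <- phase_compound_het(g)
      for (k in seq_len(nrow(ph$pairs))) {
        a <- ph$pairs$variant_id_1[k]
        b <- ph$pairs$variant_id_2[k]
        if (is.na(partner[[a]])) partner[[a]] <- b
        if (is.na(partner[[b]])) partner[[b]] <- a
      }
    }
  }

  pdv_mode <- character(n)
  pdv_partner <- rep(NA_character_, n)
  pdv_rationale <- character(n)
  acmg <- character(n)
  for (i in seq_len(n)) {
    v <- variants[i, , drop = FALSE]
    subj <- subjects[subjects$subject_id == v$subject_id, , drop = FALSE]
    res <- assign_pdv(v, subj, partner_id = partner[[v$variant_id]],
                      config = config)
    pdv_mode[i] <- res$mode
    pdv_partner[i] <- if (res$mode == "autosomal_recessive") res$partner_variant else NA_character_
    pdv_rationale[i] <- paste(res$rationale, collapse = ";")
    acmg[i] <- acmg_lite(v, config)
  }
  variants$pdv_mode <- pdv_mode
  variants$partner_variant <- pdv_partner

  pdv_ids <- variants$variant_id[variants$pdv_mode != "none"]
  partner_of_pdv <- variants$variant_id %in%
    stats::na.omit(variants$partner_variant[variants$pdv_mode != "none"])
  variants$is_cpm <- vapply(seq_len(n), function(i) {
    assign_cpm(variants[i, , drop = FALSE], variants$pdv_mode[i],
               is_pdv_partner = partner_of_pdv[i] &&
                 !variants$variant_id[i] %in% pdv_ids)
  }, logical(1))
  variants$acmg_lite <- acmg
  variants$pdv_rationale <- pdv_rationale
  variants
}
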