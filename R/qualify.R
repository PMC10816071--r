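# Qualifying-variant determination: a variant is Qualifying when it is real
# (IGV-verified), coding (changes the amino-acid code), rare (population
# prevalence strictly below 1/100) and evolutionarily conserved, with a
# splice-score gate for splice acceptor/donor variants, a somatic-origin
# exclusion for low-heteroplasmy mitochondrial variants, and a carrier-status
# exclusion for single heterozygous variants in well-established
# autosomal-recessive-only disease genes.

#' Resolve conservation status from PhyloP/PhastCons and a manual call
#'
#' Both scores strictly above the upper gate imply conserved; both strictly
#' below the lower gate imply not conserved. In the ambiguous zone (or when
#' a score is missing) the manual call decides; with no manual call the
#' status is indeterminate and the variant can never silently pass.
#'
#' @param phylop,phastcons numeric scores (NA when missing).
#' @param manual_conserved `"yes"`, `"no"` or `NA` (unset).
#' @param config [thresholds()] object.
#' @return `"conserved"`, `"not_conserved"` or `"indeterminate"`.
#' @export
#' @examples
#' conservation_status(0.9, 0.85, NA)   # conserved
#' conservation_status(0.9, 0.3, NA)    # indeterminate
#' conservation_status(0.9, 0.3, "yes") # conserved
conservation_status <- function(phylop, phastcons, manual_conserved = NA,
                                config = thresholds()) {
  if (!is.na(phylop) && !is.na(phastcons)) {
    if (phylop > config$conserved_both_min && phastcons > config$conserved_both_min) {
      return("conserved")
    }
    if (phylop < config$not_conserved_both_max && phastcons < config$not_conserved_both_max) {
      return("not_conserved")
    }
  }
  if (!is.na(manual_conserved)) {
    return(if (manual_conserved == "yes") "conserved" else "not_conserved")
  }
  "indeterminate"
}

#' Decide Qualifying status for one variant
#'
#' Applies, in order: IGV verification; the coding-consequence requirement
#' (with the splice-score gate for splice acceptor/donor variants and a
#' config switch for whole-gene duplications); the rare-frequency gate
#' (strict `< rare_max`; a missing frequency fails closed); the
#' mitochondrial somatic-heteroplasmy exclusion; the conservation
#' requirement (waived for clearly protein-destroying events when
#' `waive_conservation_for_null` is set); and the carrier-status exclusion
#' for a single heterozygous variant in an autosomal-recessive-only disease
#' gene. Every failed gate contributes a reason code; a variant whose only
#' obstacle is an unresolved conservation call gets status
#' `needs_manual_conservation` rather than a silent pass or fail.
#'
#' @param variant one-row variant data.frame (with derived `origin`).
#' @param evidence gene-evidence data.frame (for the carrier exclusion).
#' @param config [thresholds()] object.
#' @param n_het_in_gene number of heterozygous candidate variants this
#'   subject carries in this gene (1 = single het, candidate carrier
#'   status).
#' @return List with `status` (`qualifying`, `not_qualifying` or
#'   `needs_manual_conservation`) and `reason_codes` (character vector,
#'   empty iff qualifying).
#' @export
qualifies <- function(variant, evidence, config = thresholds(),
                      n_het_in_gene = 1L) {
  v <- as.list(variant[1, ])
  reasons <- character()

  if (!isTRUE(v$igv_verified)) reasons <- c(reasons, "NOT_VERIFIED")

  cons_needed <- TRUE
  csq <- v$consequence
  coding <- csq %in% CODING_CONSEQUENCES
  if (csq == "whole_gene_dup" && !config$dup_counts_as_coding) coding <- FALSE
  if (!coding) {
    reasons <- c(reasons, "NOT_CODING")
  } else if (csq %in% c("splice_acceptor", "splice_donor")) {
    rf <- v$splice_rf
    ada <- v$splice_ada
    pass <- (!is.na(rf) && rf > config$splice_min) ||
      (!is.na(ada) && ada > config$splice_min)
    if (!pass) reasons <- c(reasons, "SPLICE_BELOW_MIN")
  }

  af <- v$allele_frequency
  if (is.na(af)) {
    reasons <- c(reasons, "FREQUENCY_MISSING")
  } else if (af >= config$rare_max) {
    reasons <- c(reasons, "COMMON")
  }

  if (identical(v$chromosome, "MT") && !is.na(v$heteroplasmy_fraction) &&
      v$heteroplasmy_fraction < config$heteroplasmy_somatic_exclusion) {
    reasons <- c(reasons, "SOMATIC_SUSPECT")
  }

  if (config$waive_conservation_for_null && csq %in% NULL_CONSEQUENCES) {
    cons_needed <- FALSE
  }
  if (csq %in% c("whole_gene_del", "whole_gene_dup")) cons_needed <- FALSE
  cons <- "conserved"
  if (coding && cons_needed) {
    cons <- conservation_status(v$phylop, v$phastcons, v$manual_conserved, config)
    if (cons == "not_conserved") reasons <- c(reasons, "NOT_CONSERVED")
  }

  ev <- evidence_for_gene(evidence, primary_gene(v$gene))
  if (isTRUE(ev$ar_only_disease_gene) && identical(v$proband_genotype, "het") &&
      n_het_in_gene <= 1L) {
    reasons <- c(reasons, "CARRIER_EXCLUDED")
  }

  if (length(reasons) == 0 && cons == "indeterminate") {
    return(list(status = "needs_manual_conservation",
                reason_codes = "CONSERVATION_INDETERMINATE"))
  }
  if (length(reasons) == 0) {
    list(status = "qualifying", reason_codes = character())
  } else {
    list(status = "not_qualifying", reason_codes = reasons)
  }
}

primary_gene <- function(gene_field) {
  g <- trimws(strsplit(gene_field, ";", fixed = TRUE)[[1]])
  g <- g[nzchar(g)]
  if (length(g) == 0) gene_field else g[1]
}

#' Decide Qualifying status for a whole variant table
#'
#' Applies [qualifies()] row-wise. The carrier-status exclusion is evaluated
#' with cohort context: a heterozygous variant in an
#' autosomal-recessive-only gene is excluded only when it is the subject's
#' sole heterozygous candidate in that gene.
#'
#' @param variants variant data.frame (with derived `origin`).
#' @param evidence gene-evidence data.frame.
#' @param config [thresholds()] object.
#' @return `variants` with `qualifying_status` and `reason_codes` columns.
#' @export
qualify_variants <- function(variants, evidence, config = thresholds()) {
  n <- nrow(variants)
  if (n == 0L) {
    variants$qualifying_status <- character(0)
    variants$reason_codes <- character(0)
    return(variants)
  }
  status <- character(n)
  codes <- character(n)
  het_counts <- stats::aggregate(
    rep(1L, n),
    by = list(subject_id = variants$subject_id, gene = variants$gene,
              het = variants$proband_genotype == "het"),
    FUN = sum
  )
  for (i in seq_len(n)) {
    v <- variants[i, , drop = FALSE]
    nh <- 1L
    if (v$proband_genotype == "het") {
      hit <- het_counts$x[het_counts$subject_id == v$subject_id &
                            het_counts$gene == v$gene & het_counts$het]
      if (length(hit)) nh <- hit[1]
    }
    q <- qualifies(v, evidence, config, n_het_in_gene = nh)
    status[i] <- q$status
    codes[i] <- paste(q$reason_codes, collapse = ";")
  }
  variants$qualifying_status <- status
  variants$reason_codes <- codes
  variants
}
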