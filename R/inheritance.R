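# Inheritance-mode assignment. A Primary Diagnostic Variant (PDV) is a
# Qualifying variant in a Direct-association gene meeting one of five
# inheritance-mode rules plus clinical correlation; Qualifying variants in
# nuclear Direct genes that fall short are Candidate Polygenic Modifiers.

PDV_MODES <- c("de_novo", "x_linked", "autosomal_recessive",
               "autosomal_dominant", "maternal_mtDNA")

AUTOSOMES <- as.character(1:22)

#' Mitochondrial clinical correlation: the four-domain rule
#'
#' Mitochondrial disease presentations are too protean for gene-level
#' phenotype matching, so correlation for mtDNA variants is counted instead:
#' true iff the subject has mitochondrial-related clinical findings in at
#' least `mito_domains_min` (default 4) of the 8 recognized domains
#' (neuromuscular, neurodevelopmental, neuropsychiatric, functional,
#' endocrine, immunological, metabolic, enzymological).
#'
#' @param subject one-row subject data.frame.
#' @param config [thresholds()] object.
#' @return Logical.
#' @export
mito_clinical_correlation <- function(subject, config = thresholds()) {
  doms <- parse_mito_domains(subject$mito_domains[1])
  length(intersect(doms, MITO_DOMAINS)) >= config$mito_domains_min
}

#' Phase candidate compound heterozygotes in one gene
#'
#' Among a subject's heterozygous Qualifying variants in one autosomal gene,
#' a pair is in trans iff one variant is of maternal origin and the other of
#' paternal origin. Pairs involving unknown-origin variants are not phased;
#' they are reported in the `unphased` element rather than silently dropped.
#'
#' @param variants data.frame of one subject's variants in one gene
#'   (requires `variant_id` and derived `origin`).
#' @return List with `pairs` (data.frame `variant_id_1`, `variant_id_2`) and
#'   `unphased` (variant ids whose origin prevented phasing).
#' @export
phase_compound_het <- function(variants) {
  hets <- variants[variants$proband_genotype == "het", , drop = FALSE]
  mat <- hets$variant_id[hets$origin == "maternal"]
  pat <- hets$variant_id[hets$origin == "paternal"]
  unk <- hets$variant_id[!hets$origin %in% c("maternal", "paternal")]
  pairs <- if (length(mat) && length(pat)) {
    expand.grid(variant_id_1 = mat, variant_id_2 = pat,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id_1 = character(), variant_id_2 = character(),
               stringsAsFactors = FALSE)
  }
  list(pairs = pairs, unphased = unk)
}

# Clinical correlation for one variant: expert-judgment input flag for
# nuclear variants; the computed four-domain rule for mtDNA variants.
variant_clinical_correlation <- function(v, subject, config) {
  if (identical(v$chromosome, "MT")) {
    mito_clinical_correlation(subject, config)
  } else {
    isTRUE(v$clinical_correlation)
  }
}

#' Assign the inheritance mode of a Primary Diagnostic Variant
#'
#' Modes are tested in the fixed order de novo, X-linked, autosomal
#' recessive, autosomal dominant, maternal mitochondrial; the first rule
#' satisfied wins (precedence makes the function total and deterministic; in
#' practice a variant can satisfy at most one rule). Every mode requires a
#' Qualifying variant in a Direct gene with clinical correlation, plus:
#' \describe{
#'   \item{de_novo}{de novo origin, allele frequency < 1/10,000.}
#'   \item{x_linked}{X chromosome, inherited from a heterozygous mother,
#'     hemizygous (male) proband, frequency < 1/10,000. Heterozygous female
#'     probands are rejected with reason `XL_FEMALE_UNSPECIFIED`.}
#'   \item{autosomal_recessive}{autosome, frequency < 1/100, inherited
#'     homozygous with both parents heterozygous (otherwise
#'     `MENDELIAN_INCONSISTENT`), or heterozygous with an in-trans partner
#'     from [phase_compound_het()].}
#'   \item{autosomal_dominant}{autosome, frequency < 1/10,000, inherited,
#'     with the transmitting parent affected by significant
#'     neurodevelopmental disease.}
#'   \item{maternal_mtDNA}{mitochondrial genome, frequency < 1/10,000,
#'     mitochondrial clinical correlation (four-domain rule), and
#'     heteroplasmy within [40%, 98%] and/or a pedigree highly suggestive
#'     of maternal inheritance (input flag).}
#' }
#'
#' @param variant one-row classified variant (requires `qualifying_status`,
#'   `gene_category`, `is_direct`, derived `origin`).
#' @param subject matching one-row subject data.frame.
#' @param partner_id in-trans partner variant id from phasing, or `NA`.
#' @param config [thresholds()] object.
#' @return List with `mode` (one of the five modes or `"none"`),
#'   `partner_variant` and `rationale` (fired rules, or per-mode failure
#'   reasons when `mode == "none"`).
#' @export
assign_pdv <- function(variant, subject, partner_id = NA_character_,
                       config = thresholds()) {
  v <- as.list(variant[1, ])
  fails <- character()
  done <- function(mode, why) list(mode = mode, partner_variant = partner_id,
                                   rationale = why)

  if (!identical(v$qualifying_status, "qualifying")) {
    return(done("none", "NOT_QUALIFYING"))
  }
  if (!isTRUE(v$is_direct)) {
    return(done("none", "NOT_DIRECT_GENE"))
  }
  corr <- variant_clinical_correlation(v, subject, config)
  af <- v$allele_frequency
  very_rare <- !is.na(af) && af < config$very_rare_max
  rare <- !is.na(af) && af < config$rare_max

  # de novo
  if (identical(v$origin, "de_novo") && !identical(v$chromosome, "MT")) {
    if (very_rare && corr) {
      return(list(mode = "de_novo", partner_variant = NA_character_,
                  rationale = "de_novo_very_rare_direct_correlated"))
    }
    if (!very_rare) fails <- c(fails, "de_novo:NOT_VERY_RARE")
    if (!corr) fails <- c(fails, "de_novo:NO_CLINICAL_CORRELATION")
  }

  # X-linked
  if (identical(v$chromosome, "X") && identical(v$origin, "maternal")) {
    if (identical(v$proband_genotype, "hemizygous") &&
        identical(v$mother_genotype, "het")) {
      if (very_rare && corr) {
        return(list(mode = "x_linked", partner_variant = NA_character_,
                    rationale = "x_linked_hemizygous_carrier_mother"))
      }
      if (!very_rare) fails <- c(fails, "x_linked:NOT_VERY_RARE")
      if (!corr) fails <- c(fails, "x_linked:NO_CLINICAL_CORRELATION")
    } else if (identical(v$proband_genotype, "het") &&
               identical(subject$sex[1], "F")) {
      fails <- c(fails, "x_linked:XL_FEMALE_UNSPECIFIED")
    }
  }

  # autosomal recessive
  if (v$chromosome %in% AUTOSOMES) {
    if (identical(v$proband_genotype, "hom_alt") && v$origin != "de_novo") {
      if (identical(v$mother_genotype, "het") && identical(v$father_genotype, "het")) {
        if (rare && corr) {
          return(list(mode = "autosomal_recessive", partner_variant = NA_character_,
                      rationale = "ar_homozygous_both_parents_het"))
        }
        if (!rare) fails <- c(fails, "autosomal_recessive:NOT_RARE")
        if (!corr) fails <- c(fails, "autosomal_recessive:NO_CLINICAL_CORRELATION")
      } else {
        fails <- c(fails, "autosomal_recessive:MENDELIAN_INCONSISTENT")
      }
    }
    if (identical(v$proband_genotype, "het") && !is.na(partner_id)) {
      if (rare && corr) {
        return(list(mode = "autosomal_recessive", partner_variant = partner_id,
                    rationale = "ar_compound_het_in_trans"))
      }
      if (!rare) fails <- c(fails, "autosomal_recessive:NOT_RARE")
      if (!corr) fails <- c(fails, "autosomal_recessive:NO_CLINICAL_CORRELATION")
    }
  }

  # autosomal dominant
  if (v$chromosome %in% AUTOSOMES && v$origin %in% c("maternal", "paternal")) {
    parent_affected <- if (v$origin == "maternal") {
      isTRUE(subject$mother_affected_significant_ndd[1])
    } else {
      isTRUE(subject$father_affected_significant_ndd[1])
    }
    if (parent_affected) {
      if (very_rare && corr) {
        return(list(mode = "autosomal_dominant", partner_variant = NA_character_,
                    rationale = paste0("ad_inherited_", v$origin, "_parent_affected")))
      }
      if (!very_rare) fails <- c(fails, "autosomal_dominant:NOT_VERY_RARE")
      if (!corr) fails <- c(fails, "autosomal_dominant:NO_CLINICAL_CORRELATION")
    } else {
      fails <- c(fails, "autosomal_dominant:PARENT_NOT_AFFECTED")
    }
  }

  # maternal mitochondrial
  if (identical(v$chromosome, "MT")) {
    het_ok <- !is.na(v$heteroplasmy_fraction) &&
      v$heteroplasmy_fraction >= config$heteroplasmy_pdv_low &&
      v$heteroplasmy_fraction <= config$heteroplasmy_pdv_high
    pedigree_ok <- isTRUE(v$maternal_pedigree_flag)
    if (very_rare && corr && (het_ok || pedigree_ok)) {
      why <- c(if (het_ok) "heteroplasmy_in_pdv_band",
               if (pedigree_ok) "maternal_pedigree_suggestive")
      return(list(mode = "maternal_mtDNA", partner_variant = NA_character_,
                  rationale = paste(why, collapse = ";")))
    }
    if (!very_rare) fails <- c(fails, "maternal_mtDNA:NOT_VERY_RARE")
    if (!corr) fails <- c(fails, "maternal_mtDNA:NO_MITO_CORRELATION")
    if (!het_ok && !pedigree_ok) fails <- c(fails, "maternal_mtDNA:NO_HETEROPLASMY_OR_PEDIGREE")
  }

  if (length(fails) == 0) fails <- "NO_MODE_CONDITIONS_MET"
  done("none", paste(fails, collapse = ";"))
}

#' Candidate Polygenic Modifier designation
#'
#' A variant is a CPM iff it is Qualifying, in a nuclear (non-mitochondrial)
#' Direct gene, and is neither a PDV nor the in-trans partner of one. PDV
#' and CPM are disjoint by construction.
#'
#' @param variant one-row classified variant.
#' @param pdv_mode the variant's assigned mode (`"none"` if not a PDV).
#' @param is_pdv_partner whether the variant partners a compound-het PDV.
#' @return Logical.
#' @export
assign_cpm <- function(variant, pdv_mode, is_pdv_partner = FALSE) {
  identical(variant$qualifying_status[1], "qualifying") &&
    isTRUE(variant$is_direct[1]) &&
    !identical(variant$chromosome[1], "MT") &&
    identical(pdv_mode, "none") &&
    !isTRUE(is_pdv_partner)
}

#' Reduced ACMG-style classification of de novo variants
#'
#' Maps three evidence codes: PS2 (confirmed de novo origin), PM2 (allele
#' frequency strictly below `pm2_max`, default 1/100,000 -- nonzero but
#' ultra-rare frequencies are accepted because modern control databases
#' cannot exclude mildly-affected carriers), and PVS1 (null variant:
#' frameshift, stop gain, splice acceptor/donor, whole-gene deletion). A de
#' novo variant with PS2 and PM2 is Likely_Pathogenic; adding PVS1 makes it
#' Pathogenic; anything else is VUS.
#'
#' @param variant one-row variant data.frame with derived `origin`.
#' @param config [thresholds()] object.
#' @return `"Pathogenic"`, `"Likely_Pathogenic"` or `"VUS"`.
#' @export
acmg_lite <- function(variant, config = thresholds()) {
  v <- as.list(variant[1, ])
  ps2 <- identical(v$origin, "de_novo")
  pm2 <- !is.na(v$allele_frequency) && v$allele_frequency < config$pm2_max
  pvs1 <- v$consequence %in% NULL_CONSEQUENCES
  if (ps2 && pm2) {
    if (pvs1) "Pathogenic" else "Likely_Pathogenic"
  } else {
    "VUS"
  }
}
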