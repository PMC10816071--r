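# Builders for small in-code fixtures.

make_variant <- function(subject_id = "S1", gene = "GENE1", chromosome = "1",
                         position = 1000, end = position,
                         variant_class = "SNV", consequence = "missense",
                         proband = "het", mother = "hom_ref",
                         father = "hom_ref", af = 1e-6, phylop = 0.95,
                         phastcons = 0.9, splice_rf = NA_real_,
                         splice_ada = NA_real_,
                         manual_conserved = NA_character_, igv = TRUE,
                         corr = TRUE, heteroplasmy = NA_real_,
                         pedigree_flag = FALSE, on_lab_report = FALSE,
                         lab_class = "none", variant_id = NULL) {
  df <- data.frame(
    subject_id = subject_id, gene = gene, chromosome = chromosome,
    position = position, end = end, variant_class = variant_class,
    consequence = consequence, proband_genotype = proband,
    mother_genotype = mother, father_genotype = father,
    allele_frequency = af, phylop = phylop, phastcons = phastcons,
    splice_rf = splice_rf, splice_ada = splice_ada,
    manual_conserved = manual_conserved, igv_verified = igv,
    clinical_correlation = corr, heteroplasmy_fraction = heteroplasmy,
    maternal_ratio = NA_real_, maternal_inheritance_ratio = NA_real_,
    maternal_pedigree_flag = pedigree_flag, on_lab_report = on_lab_report,
    lab_report_classification = lab_class, stringsAsFactors = FALSE
  )
  df$variant_id <- if (is.null(variant_id)) {
    paste0(subject_id, ":", gene, ":", position)
  } else {
    variant_id
  }
  df$origin <- derive_origin(df$proband_genotype, df$mother_genotype,
                             df$father_genotype)
  df
}

make_subject <- function(subject_id = "S1", sex = "M", age = 10,
                         tics = FALSE, ocd = FALSE, absent_speech = FALSE,
                         seizures = FALSE, regression = "none",
                         id_severity = "mild", afdr = FALSE,
                         mother_ndd = FALSE, father_ndd = FALSE,
                         mito_domains = "neurodevelopmental",
                         lab_positive = FALSE) {
  data.frame(
    subject_id = subject_id, sex = sex, age_years = age, tics = tics,
    ocd = ocd, absent_speech = absent_speech, seizures = seizures,
    regression = regression, id_severity = id_severity,
    affected_first_degree_relative = afdr,
    mother_affected_significant_ndd = mother_ndd,
    father_affected_significant_ndd = father_ndd,
    mito_domains = mito_domains, lab_report_positive = lab_positive,
    stringsAsFactors = FALSE
  )
}

make_evidence <- function(gene = "GENE1", ...) {
  ev <- default_evidence(gene)
  args <- list(...)
  for (nm in names(args)) ev[[nm]] <- args[[nm]]
  ev
}

# Independent two-sided Fisher oracle: enumeration over the support using
# R's hypergeometric density (a different code path from the package's
# log-binomial implementation).
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  k <- max(0, c1 - r2):min(r1, c1)
  p <- stats::dhyper(k, r1, r2, c1)
  po <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(p[p <= po * (1 + 1e-7)])
}

tbl <- function(a, b, c, d) matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
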