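test_that("conservation resolution follows the two-gate-plus-manual rule", {
  expect_equal(conservation_status(0.9, 0.85, NA), "conserved")
  expect_equal(conservation_status(0.3, 0.2, NA), "not_conserved")
  expect_equal(conservation_status(0.9, 0.3, NA), "indeterminate")
  expect_equal(conservation_status(0.9, 0.3, "yes"), "conserved")
  expect_equal(conservation_status(0.9, 0.3, "no"), "not_conserved")
  expect_equal(conservation_status(NA, 0.9, NA), "indeterminate")
  expect_equal(conservation_status(NA, NA, "yes"), "conserved")
  # boundary: exactly at the gates the automatic rules abstain
  expect_equal(conservation_status(0.7, 0.7, NA), "indeterminate")
  expect_equal(conservation_status(0.4, 0.4, NA), "indeterminate")
})

test_that("the Qualifying gates fire with the right reason codes", {
  ev <- make_evidence("GENE1")
  q <- function(v, evd = ev, nh = 1L) qualifies(v, evd, n_het_in_gene = nh)

  # all gates pass
  res <- q(make_variant(af = 1e-5))
  expect_equal(res$status, "qualifying")
  expect_length(res$reason_codes, 0)

  # synonymous and noncoding are never Qualifying
  expect_true("NOT_CODING" %in% q(make_variant(consequence = "synonymous"))$reason_codes)
  expect_true("NOT_CODING" %in% q(make_variant(consequence = "noncoding"))$reason_codes)

  # common variant
  expect_true("COMMON" %in% q(make_variant(af = 0.02))$reason_codes)
  # strictly below the gate passes; exactly at it fails
  expect_equal(q(make_variant(af = 0.00999))$status, "qualifying")
  expect_true("COMMON" %in% q(make_variant(af = 0.01))$reason_codes)
  # missing frequency fails closed
  expect_true("FREQUENCY_MISSING" %in% q(make_variant(af = NA_real_))$reason_codes)

  # unverified
  expect_true("NOT_VERIFIED" %in% q(make_variant(igv = FALSE))$reason_codes)

  # splice gate: > 0.6 on either score suffices, missing scores fail
  sp <- make_variant(consequence = "splice_acceptor", phylop = NA, phastcons = NA,
                     splice_ada = 0.7)
  expect_equal(q(sp)$status, "qualifying")
  sp_rf <- make_variant(consequence = "splice_donor", phylop = NA, phastcons = NA,
                        splice_rf = 0.61)
  expect_equal(q(sp_rf)$status, "qualifying")
  sp_low <- make_variant(consequence = "splice_acceptor", phylop = NA,
                         phastcons = NA, splice_ada = 0.6)
  expect_true("SPLICE_BELOW_MIN" %in% q(sp_low)$reason_codes)
  sp_na <- make_variant(consequence = "splice_acceptor", phylop = NA,
                        phastcons = NA)
  expect_true("SPLICE_BELOW_MIN" %in% q(sp_na)$reason_codes)

  # not conserved
  expect_true("NOT_CONSERVED" %in%
                q(make_variant(phylop = 0.2, phastcons = 0.1))$reason_codes)
  # conservation waived for protein-destroying events
  fs <- make_variant(consequence = "frameshift", variant_class = "small_indel",
                     phylop = NA, phastcons = NA)
  expect_equal(q(fs)$status, "qualifying")
  del <- make_variant(consequence = "whole_gene_del", variant_class = "CNV_del",
                      end = 2000, phylop = NA, phastcons = NA)
  expect_equal(q(del)$status, "qualifying")
  # ... but the waiver is config-switchable
  strict <- thresholds(waive_conservation_for_null = FALSE)
  expect_equal(qualifies(fs, ev, strict)$status, "needs_manual_conservation")

  # whole-gene duplications are coding by default, config-gated
  dup <- make_variant(consequence = "whole_gene_dup", variant_class = "CNV_dup",
                      end = 2000, phylop = NA, phastcons = NA)
  expect_equal(q(dup)$status, "qualifying")
  no_dup <- thresholds(dup_counts_as_coding = FALSE)
  expect_true("NOT_CODING" %in% qualifies(dup, ev, no_dup)$reason_codes)

  # unresolved conservation is surfaced, never silently passed
  amb <- make_variant(phylop = 0.9, phastcons = 0.5)
  expect_equal(q(amb)$status, "needs_manual_conservation")
  expect_equal(q(make_variant(phylop = 0.9, phastcons = 0.5,
                              manual_conserved = "yes"))$status, "qualifying")
})

test_that("low-heteroplasmy mitochondrial variants are excluded as somatic", {
  mt <- make_variant(gene = "MT-CO1", chromosome = "MT", variant_class = "mtDNA",
                     mother = "het", heteroplasmy = 0.15)
  res <- qualifies(mt, make_evidence("MT-CO1", is_mtDNA = TRUE))
  expect_true("SOMATIC_SUSPECT" %in% res$reason_codes)
  ok <- make_variant(gene = "MT-CO1", chromosome = "MT", variant_class = "mtDNA",
                     mother = "het", heteroplasmy = 0.20)
  expect_equal(qualifies(ok, make_evidence("MT-CO1", is_mtDNA = TRUE))$status,
               "qualifying")
})

test_that("single heterozygotes in recessive-only disease genes are carrier-excluded", {
  ev <- make_evidence("ARGENE", sfari_rank = 3L, ar_only_disease_gene = TRUE)
  v <- make_variant(gene = "ARGENE", af = 1e-3)
  expect_true("CARRIER_EXCLUDED" %in% qualifies(v, ev)$reason_codes)
  # a second het in the same gene lifts the exclusion (possible comp-het)
  expect_equal(qualifies(v, ev, n_het_in_gene = 2L)$status, "qualifying")
  # homozygotes are not carriers
  hom <- make_variant(gene = "ARGENE", proband = "hom_alt", mother = "het",
                      father = "het", af = 1e-3)
  expect_equal(qualifies(hom, ev)$status, "qualifying")

  # cohort-level wrapper sees both hets
  two <- rbind(make_variant(gene = "ARGENE", mother = "het", af = 1e-3,
                            variant_id = "a"),
               make_variant(gene = "ARGENE", father = "het", af = 1e-3,
                            position = 2000, variant_id = "b"))
  got <- qualify_variants(two, ev)
  expect_equal(got$qualifying_status, c("qualifying", "qualifying"))
  one <- qualify_variants(make_variant(gene = "ARGENE", af = 1e-3), ev)
  expect_match(one$reason_codes, "CARRIER_EXCLUDED")
})

test_that("the decision is monotone in allele frequency", {
  set.seed(7)
  ev <- make_evidence("GENE1")
  for (i in 1:100) {
    af_hi <- 10^runif(1, -6, -0.5)
    af_lo <- af_hi * 10^runif(1, -4, 0)
    v_hi <- make_variant(af = af_hi, phylop = runif(1), phastcons = runif(1),
                         manual_conserved = sample(c("yes", "no"), 1))
    v_lo <- v_hi
    v_lo$allele_frequency <- af_lo
    s_hi <- qualifies(v_hi, ev)$status
    s_lo <- qualifies(v_lo, ev)$status
    if (s_hi == "qualifying") expect_equal(s_lo, "qualifying")
  }
})

test_that("fixture de novo table partitions exactly as published", {
  fx <- load_fixture_cohort("paper_cohort")
  cls <- classify_cohort(fx$variants, fx$subjects, fx$evidence)
  dnv <- cls[cls$origin == "de_novo", ]
  expect_equal(nrow(dnv), 46)
  expect_equal(sum(dnv$qualifying_status == "qualifying"), 34)
  expect_equal(sum(dnv$is_direct), 31)
  expect_equal(sum(dnv$is_direct & dnv$qualifying_status == "qualifying"), 29)
  expect_equal(sum(!dnv$is_direct), 15)
  expect_equal(sum(!dnv$is_direct & dnv$qualifying_status == "qualifying"), 5)
})
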