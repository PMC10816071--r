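# Classify a one-variant (or few-variant) micro-cohort and return rows.
classify_one <- function(variants, subject, evidence) {
  classify_cohort(variants, subject, evidence)
}

test_that("compound-het phasing pairs exactly one maternal with one paternal", {
  vm <- make_variant(gene = "IVD", mother = "het", variant_id = "m")
  vp <- make_variant(gene = "IVD", father = "het", position = 2000,
                     variant_id = "p")
  vu <- make_variant(gene = "IVD", mother = "unknown", position = 3000,
                     variant_id = "u")
  ph <- phase_compound_het(rbind(vm, vp))
  expect_equal(nrow(ph$pairs), 1)
  expect_setequal(unlist(ph$pairs[1, ]), c("m", "p"))

  # two maternal hets are cis by construction
  vm2 <- make_variant(gene = "IVD", mother = "het", position = 4000,
                      variant_id = "m2")
  expect_equal(nrow(phase_compound_het(rbind(vm, vm2))$pairs), 0)

  # unknown-origin variants are logged, not paired
  ph_u <- phase_compound_het(rbind(vm, vu))
  expect_equal(nrow(ph_u$pairs), 0)
  expect_equal(ph_u$unphased, "u")
})

test_that("the five inheritance-mode rules assign PDVs as published", {
  ev <- rbind(make_evidence("KCNB1", sfari_rank = 1L),
              make_evidence("THOC2", sfari_rank = 3L),
              make_evidence("SLC1A4", sfari_rank = 3L),
              make_evidence("TCF20", sfari_rank = 1L),
              make_evidence("MT-CO1", is_mtDNA = TRUE),
              make_evidence("B1GENE", asd_pathway_member = TRUE))
  subj <- make_subject()

  # de novo: very rare, Direct, correlated
  dn <- classify_one(make_variant(gene = "KCNB1", chromosome = "20", af = 0),
                     subj, ev)
  expect_equal(dn$pdv_mode, "de_novo")

  # de novo in a non-Direct gene is never a PDV
  b1 <- classify_one(make_variant(gene = "B1GENE", af = 0), subj, ev)
  expect_equal(b1$pdv_mode, "none")
  expect_match(b1$pdv_rationale, "NOT_DIRECT_GENE")

  # de novo above the very-rare gate is rejected even though Qualifying
  freqy <- classify_one(make_variant(gene = "KCNB1", af = 5e-4), subj, ev)
  expect_equal(freqy$qualifying_status, "qualifying")
  expect_equal(freqy$pdv_mode, "none")
  expect_match(freqy$pdv_rationale, "NOT_VERY_RARE")

  # X-linked: hemizygous proband, carrier mother
  xl <- classify_one(
    make_variant(gene = "THOC2", chromosome = "X", proband = "hemizygous",
                 mother = "het", af = 5e-5),
    subj, ev
  )
  expect_equal(xl$pdv_mode, "x_linked")

  # heterozygous female probands are rejected with the explicit reason
  xf <- classify_one(
    make_variant(gene = "THOC2", chromosome = "X", proband = "het",
                 mother = "het", af = 5e-5),
    make_subject(sex = "F"), ev
  )
  expect_equal(xf$pdv_mode, "none")
  expect_match(xf$pdv_rationale, "XL_FEMALE_UNSPECIFIED")

  # autosomal recessive, homozygous, both parents het; rare (not very rare)
  ar <- classify_one(
    make_variant(gene = "SLC1A4", chromosome = "2", proband = "hom_alt",
                 mother = "het", father = "het", af = 2e-3),
    subj, ev
  )
  expect_equal(ar$pdv_mode, "autosomal_recessive")

  # homozygote without both parents het is Mendelian-inconsistent
  bad_ar <- classify_one(
    make_variant(gene = "SLC1A4", chromosome = "2", proband = "hom_alt",
                 mother = "het", father = "hom_ref", af = 2e-3),
    subj, ev
  )
  expect_equal(bad_ar$pdv_mode, "none")
  expect_match(bad_ar$pdv_rationale, "MENDELIAN_INCONSISTENT")

  # autosomal recessive, in-trans compound het: both variants get the mode
  ch <- classify_one(
    rbind(make_variant(gene = "SLC1A4", chromosome = "2", mother = "het",
                       af = 1e-3, variant_id = "a"),
          make_variant(gene = "SLC1A4", chromosome = "2", father = "het",
                       af = 2e-3, position = 2000, variant_id = "b")),
    subj, ev
  )
  expect_equal(ch$pdv_mode, c("autosomal_recessive", "autosomal_recessive"))
  expect_equal(ch$partner_variant, c("b", "a"))

  # autosomal dominant requires the transmitting parent to be affected
  ad <- classify_one(
    make_variant(gene = "TCF20", chromosome = "22", father = "het", af = 0),
    make_subject(father_ndd = TRUE), ev
  )
  expect_equal(ad$pdv_mode, "autosomal_dominant")
  ad_no <- classify_one(
    make_variant(gene = "TCF20", chromosome = "22", father = "het", af = 0),
    make_subject(father_ndd = FALSE), ev
  )
  expect_equal(ad_no$pdv_mode, "none")
  expect_match(ad_no$pdv_rationale, "PARENT_NOT_AFFECTED")
  # the affected parent must be the transmitting one
  ad_wrong <- classify_one(
    make_variant(gene = "TCF20", chromosome = "22", father = "het", af = 0),
    make_subject(mother_ndd = TRUE), ev
  )
  expect_equal(ad_wrong$pdv_mode, "none")

  # maternal mitochondrial: heteroplasmy band + four-domain correlation
  mito_subj <- make_subject(
    mito_domains = "neurodevelopmental,neuropsychiatric,functional,metabolic"
  )
  mt <- classify_one(
    make_variant(gene = "MT-CO1", chromosome = "MT", variant_class = "mtDNA",
                 mother = "het", af = 0, heteroplasmy = 0.58),
    mito_subj, ev
  )
  expect_equal(mt$pdv_mode, "maternal_mtDNA")

  # three domains are not enough
  mt3 <- classify_one(
    make_variant(gene = "MT-CO1", chromosome = "MT", variant_class = "mtDNA",
                 mother = "het", af = 0, heteroplasmy = 0.58),
    make_subject(mito_domains = "neurodevelopmental,functional,metabolic"), ev
  )
  expect_equal(mt3$pdv_mode, "none")

  # heteroplasmy outside the band still passes via the pedigree flag
  mt_ped <- classify_one(
    make_variant(gene = "MT-CO1", chromosome = "MT", variant_class = "mtDNA",
                 mother = "het", af = 0, heteroplasmy = 0.99,
                 pedigree_flag = TRUE),
    mito_subj, ev
  )
  expect_equal(mt_ped$pdv_mode, "maternal_mtDNA")

  # 15% heteroplasmy was already excluded upstream as somatic
  mt_som <- classify_one(
    make_variant(gene = "MT-CO1", chromosome = "MT", variant_class = "mtDNA",
                 mother = "het", af = 0, heteroplasmy = 0.15),
    mito_subj, ev
  )
  expect_equal(mt_som$qualifying_status, "not_qualifying")
  expect_match(mt_som$reason_codes, "SOMATIC_SUSPECT")
  expect_equal(mt_som$pdv_mode, "none")
})

test_that("the four-domain rule is an exact threshold", {
  cfg <- thresholds()
  expect_false(mito_clinical_correlation(
    make_subject(mito_domains = "neurodevelopmental,functional,metabolic"), cfg))
  expect_true(mito_clinical_correlation(
    make_subject(mito_domains = "neurodevelopmental,functional,metabolic,endocrine"),
    cfg))
  expect_true(mito_clinical_correlation(
    make_subject(mito_domains = paste(
      c("neuromuscular", "neurodevelopmental", "neuropsychiatric", "functional",
        "endocrine", "immunological", "metabolic", "enzymological"),
      collapse = ",")), cfg))
})

test_that("CPMs are Qualifying nuclear Direct non-PDVs, disjoint from PDVs", {
  ev <- rbind(make_evidence("RYR2", sfari_rank = 3L),
              make_evidence("MT-TW", is_mtDNA = TRUE),
              make_evidence("B1GENE", asd_pathway_member = TRUE))
  subj <- make_subject()

  # inherited Direct qualifying variant without PDV conditions -> CPM
  cpm <- classify_one(
    make_variant(gene = "RYR2", mother = "het", af = 1e-3, corr = FALSE),
    subj, ev
  )
  expect_equal(cpm$pdv_mode, "none")
  expect_true(cpm$is_cpm)

  # mitochondrial variants are never CPMs (non-nuclear)
  mt <- classify_one(
    make_variant(gene = "MT-TW", chromosome = "MT", variant_class = "mtDNA",
                 mother = "het", af = 1e-3, heteroplasmy = 0.5, corr = FALSE),
    subj, ev
  )
  expect_equal(mt$pdv_mode, "none")
  expect_false(mt$is_cpm)

  # non-Direct genes are never CPMs
  b1 <- classify_one(
    make_variant(gene = "B1GENE", mother = "het", af = 1e-3, corr = FALSE),
    subj, ev
  )
  expect_false(b1$is_cpm)

  # a PDV is never simultaneously a CPM (fixture-wide check)
  fx <- load_fixture_cohort("paper_cohort")
  cls <- classify_cohort(fx$variants, fx$subjects, fx$evidence)
  expect_false(any(cls$is_cpm & cls$pdv_mode != "none"))
  # every Qualifying nuclear Direct non-PDV is a CPM (completeness)
  should_be_cpm <- cls$qualifying_status == "qualifying" & cls$is_direct &
    cls$chromosome != "MT" & cls$pdv_mode == "none"
  expect_equal(cls$is_cpm, should_be_cpm)
  # and every PDV is Qualifying
  expect_true(all(cls$qualifying_status[cls$pdv_mode != "none"] == "qualifying"))
})

test_that("mode assignment is order-stable and pure", {
  fx <- load_fixture_cohort("paper_cohort")
  a <- classify_cohort(fx$variants, fx$subjects, fx$evidence)
  b <- classify_cohort(fx$variants, fx$subjects, fx$evidence)
  expect_identical(a, b)
  # shuffling input rows does not change any variant's assignment
  set.seed(1)
  perm <- sample(nrow(fx$variants))
  c2 <- classify_cohort(fx$variants[perm, ], fx$subjects, fx$evidence)
  c2 <- c2[order(match(c2$variant_id, a$variant_id)), ]
  expect_equal(c2$pdv_mode, a$pdv_mode)
  expect_equal(c2$is_cpm, a$is_cpm)
})

test_that("the reduced ACMG mapping follows PS2/PM2/PVS1", {
  expect_equal(acmg_lite(make_variant(af = 0)), "Likely_Pathogenic")
  expect_equal(acmg_lite(make_variant(af = 0, consequence = "frameshift",
                                      variant_class = "small_indel")),
               "Pathogenic")
  expect_equal(acmg_lite(make_variant(af = 0, consequence = "whole_gene_del",
                                      variant_class = "CNV_del", end = 2000)),
               "Pathogenic")
  # inherited variants stay VUS regardless of rarity
  expect_equal(acmg_lite(make_variant(af = 0, mother = "het")), "VUS")
  # PM2 is a strict ultra-rare gate
  expect_equal(acmg_lite(make_variant(af = 2e-5)), "VUS")
  expect_equal(acmg_lite(make_variant(af = 9e-6)), "Likely_Pathogenic")
})
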