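test_that("hypergeometric support sums to one and matches dhyper", {
  set.seed(3)
  for (i in 1:50) {
    m <- matrix(rpois(4, 8), 2)
    if (sum(m) == 0) next
    supp <- hypergeom_support(m)
    expect_equal(sum(supp$prob), 1, tolerance = 1e-12)
    r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
    expect_equal(supp$prob, dhyper(supp$k, r1, r2, c1), tolerance = 1e-12)
  }
})

test_that("the exact test equals an independent enumeration oracle", {
  # exhaustive over all tables with small margins
  for (r1 in 0:7) for (r2 in 0:7) for (a in 0:r1) for (c in 0:r2) {
    m <- matrix(c(a, r1 - a, c, r2 - c), 2, byrow = TRUE)
    if (sum(m) == 0) next
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_two_tailed(m), oracle_fisher(m),
                 tolerance = 1e-12)
  }
  # random tables up to n = 60, cross-checked against the oracle and
  # against R's fisher.test
  set.seed(11)
  for (i in 1:300) {
    n <- sample(4:60, 1)
    cells <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    m <- matrix(cells, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- fisher_exact_two_tailed(m)
    expect_equal(p, oracle_fisher(m), tolerance = 1e-12)
    expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("the exact test honours its symmetries and conventions", {
  set.seed(5)
  for (i in 1:50) {
    m <- matrix(rpois(4, 6) + 1, 2)
    p <- fisher_exact_two_tailed(m)
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, fisher_exact_two_tailed(m[2:1, ]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_two_tailed(m[, 2:1]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_two_tailed(t(m)), tolerance = 1e-12)
    # two-sided >= one-sided
    supp <- hypergeom_support(m)
    one_sided <- min(sum(supp$prob[supp$k <= m[1, 1]]),
                     sum(supp$prob[supp$k >= m[1, 1]]))
    expect_gte(p + 1e-12, one_sided)
  }
  # fixed points
  expect_equal(fisher_exact_two_tailed(tbl(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact_two_tailed(tbl(0, 5, 5, 0)), 2 / 252,
               tolerance = 1e-12)
  expect_warning(p_deg <- fisher_exact_two_tailed(tbl(0, 0, 3, 4)),
                 "degenerate")
  expect_equal(p_deg, 1)
})

test_that("odds ratios and log-method intervals match the published values", {
  o1 <- odds_ratio_with_ci(tbl(29, 2, 5, 10))
  expect_equal(o1$or, 29)
  expect_equal(round(o1$lower, 1), 4.8)
  expect_false(o1$corrected)

  o2 <- odds_ratio_with_ci(tbl(22, 4, 12, 12))
  expect_equal(o2$or, 5.5)
  expect_equal(round(o2$lower, 1), 1.5)
  expect_equal(round(o2$upper), 21)

  o3 <- odds_ratio_with_ci(tbl(13, 21, 3, 13))
  expect_equal(round(o3$or, 1), 2.7)
  expect_equal(round(o3$lower, 1), 0.6)
  expect_equal(round(o3$upper), 11)

  # neutral table: OR 1, interval spans 1
  o4 <- odds_ratio_with_ci(tbl(1, 1, 1, 1))
  expect_equal(o4$or, 1)
  expect_lt(o4$lower, 1); expect_gt(o4$upper, 1)

  # reciprocal invariance for positive cells
  set.seed(9)
  for (i in 1:30) {
    m <- matrix(rpois(4, 5) + 1, 2, byrow = TRUE)
    a <- odds_ratio_with_ci(m)$or
    b <- odds_ratio_with_ci(m[, 2:1])$or
    expect_equal(a * b, 1, tolerance = 1e-12)
  }

  # zero cells: Haldane-Anscombe applied and flagged, or Inf signalled
  oz <- odds_ratio_with_ci(tbl(5, 0, 2, 7))
  expect_true(oz$corrected)
  expect_true(is.finite(oz$or))
  expect_equal(odds_ratio_with_ci(tbl(5, 0, 2, 7), correct = FALSE)$or, Inf)
})

test_that("the expected de novo burden model is linear and hits 0.3/0.2", {
  r <- expected_dnv_rate(1e-8, 3e7, 1 / 3)
  expect_equal(r$raw_rate, 0.3)
  expect_equal(r$nonsilent_rate, 0.2)
  expect_equal(expected_dnv_rate(0, 3e7, 0.5), list(raw_rate = 0, nonsilent_rate = 0))
  r2 <- expected_dnv_rate(2e-8, 3e7, 0.5)
  expect_equal(r2$raw_rate, 0.6)
  expect_equal(r2$nonsilent_rate, 0.3)
})

test_that("cohort summary counts subjects once per stratum", {
  fx <- load_fixture_cohort("paper_cohort")
  cls <- classify_cohort(fx$variants, fx$subjects, fx$evidence)
  s <- summarize_cohort(cls, fx$subjects)
  expect_equal(s$n_subjects, 50)
  expect_equal(s$n_any_pdv_subjects, 34)
  # subject 48 carries both a de novo and a mitochondrial PDV but is one
  # subject in the union
  expect_lte(s$n_any_pdv_subjects,
             s$n_denovo_pdv_subjects + s$n_inherited_pdv_subjects)
  expect_true(all(c(s$yield_denovo, s$yield_inherited, s$yield_any,
                    s$yield_lab) >= 0))
  expect_true(all(c(s$yield_denovo, s$yield_inherited, s$yield_any,
                    s$yield_lab) <= 1))

  # empty cohort: all-zero summary
  empty <- cls[0, ]
  s0 <- summarize_cohort(empty, fx$subjects[0, ])
  expect_equal(s0$n_subjects, 0)
  expect_equal(s0$n_any_pdv_subjects, 0)
  expect_equal(s0$dnv_total, 0)

  # a variant referencing an unknown subject is a fatal consistency error
  bad <- cls[1, ]; bad$subject_id <- "missing_subject"
  expect_error(summarize_cohort(bad, fx$subjects), "unknown subject")
})

test_that("phenotype associations rebuild the published 2x2 tables", {
  fx <- load_fixture_cohort("paper_cohort")
  cls <- classify_cohort(fx$variants, fx$subjects, fx$evidence)

  # neither tics nor OCD 22/26 with a PDV vs either 12/24
  t1 <- phenotype_association(fx$subjects, cls, "tics_or_ocd")
  expect_equal(unname(t1$table), tbl(22, 4, 12, 12))
  expect_equal(round(t1$p, 2), 0.01)

  # absent speech 6/13 vs present 28/37
  t2 <- phenotype_association(fx$subjects, cls, "absent_speech")
  expect_equal(unname(t2$table["flag_present", ]), c(6, 7))
  expect_equal(unname(t2$table["flag_absent", ]), c(28, 9))
  expect_equal(round(t2$p, 2), 0.08)

  # affected first-degree relative: 13/34 of PDV subjects, 3/16 without
  t3 <- phenotype_association(fx$subjects, cls, "affected_first_degree_relative")
  expect_equal(unname(t3$table), tbl(21, 13, 13, 3))
  expect_equal(round(1 / t3$or, 1), 2.7)  # OR 2.7 for PDV ~ relative

  # a constant flag yields the degenerate convention
  all_false <- fx$subjects
  all_false$seizures <- FALSE
  t4 <- phenotype_association(all_false, cls, "seizures")
  expect_equal(t4$p, 1)
})
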