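#!/usr/bin/env Rscript
# Step 2: cohort statistics -- Qualifying-variant enrichment in Direct
# genes, phenotype-PDV associations, and the expected de novo burden.
#
# Writes results/statistics.tsv (one row per test).

suppressPackageStartupMessages(library(triopdv))

fx <- load_fixture_cohort("paper_cohort")
cls <- classify_cohort(fx$variants, fx$subjects, fx$evidence)
s <- summarize_cohort(cls, fx$subjects)

rows <- list()
note <- function(name, a, b, c, d, p, or) {
  rows[[length(rows) + 1L]] <<- data.frame(
    comparison = name, a = a, b = b, c = c, d = d,
    p = p, odds_ratio = or$or, ci_lower = or$lower, ci_upper = or$upper
  )
}

cat("== Qualifying enrichment of de novo variants in Direct genes ==\n")
enrich <- matrix(c(s$dnv_direct_qualifying,
                   s$dnv_direct_total - s$dnv_direct_qualifying,
                   s$dnv_nondirect_qualifying,
                   s$dnv_nondirect_total - s$dnv_nondirect_qualifying),
                 2, byrow = TRUE)
p <- fisher_exact_two_tailed(enrich)
o <- odds_ratio_with_ci(enrich)
note("qualifying_enrichment_direct_vs_nondirect",
     enrich[1, 1], enrich[1, 2], enrich[2, 1], enrich[2, 2], p, o)
cat(sprintf("  29/31 vs 5/15 Qualifying: p = %.2g, OR = %.0f (95%% CI %.1f-%.0f)\n",
            p, o$or, o$lower, o$upper))
cat("  (an exact two-sided test gives ~3.7e-5 for this table)\n\n")

cat("== Phenotype associations with PDV status ==\n")
for (flag in c("tics_or_ocd", "tics", "ocd", "absent_speech",
               "regression_any", "affected_first_degree_relative", "sex",
               "seizures", "severe_id")) {
  res <- phenotype_association(fx$subjects, cls, flag)
  t <- res$table
  note(paste0("pdv_vs_", flag), t[1, 1], t[1, 2], t[2, 1], t[2, 2], res$p,
       list(or = res$or, lower = res$lower, upper = res$upper))
  cat(sprintf("  %-32s p = %.2f  OR(no-flag vs flag) = %.2f\n",
              flag, res$p, res$or))
}
cat("  A PDV is found significantly more often in subjects with neither\n")
cat("  tics nor OCD (22/26 vs 12/24, p = 0.01); absent speech shows a\n")
cat("  negative trend (6/13 vs 28/37, p = 0.08).\n\n")

cat("== Expected de novo coding burden ==\n")
burden <- expected_dnv_rate(1e-8, 3e7, 1 / 3)
cat(sprintf("  expected: %.1f coding DNVs/person, %.1f non-silent\n",
            burden$raw_rate, burden$nonsilent_rate))
cat(sprintf("  observed unlikely-disease DNVs: %.2f per individual\n",
            s$dnv_unlikely_disease_rate))

dir.create("results", showWarnings = FALSE)
stats <- do.call(rbind, rows)
write.table(stats, "results/statistics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nwrote results/statistics.tsv\n")
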