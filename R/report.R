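# High-level drivers used by the analysis scripts: classify-and-write,
# simulate-and-write, and a printed contingency-table report. All runs are
# deterministic given identical inputs and configuration; a JSON manifest
# records what produced each output.

write_manifest <- function(out_dir, inputs, config_snapshot, seed = NULL) {
  manifest <- list(
    tool = paste0("triopdv ", as.character(utils::packageVersion("triopdv"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    seed = seed,
    config = config_snapshot
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Classify a cohort and write the standard outputs
#'
#' Runs [classify_cohort()] and [summarize_cohort()] and writes
#' `classified_variants.tsv`, `cohort_summary.json`, an exclusion log
#' (`excluded_variants.tsv`: every non-Qualifying or mode-less variant with
#' its reason codes) and a run manifest into `out_dir`.
#'
#' @param variants,subjects,evidence cohort tables (see [classify_cohort()]).
#' @param out_dir output directory (created if needed).
#' @param config [thresholds()] object.
#' @return The cohort summary, invisibly.
#' @export
run_classify <- function(variants, subjects, evidence, out_dir,
                         config = thresholds()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  classified <- classify_cohort(variants, subjects, evidence, config)
  summary <- summarize_cohort(classified, subjects)
  write_classified_table(classified,
                         file.path(out_dir, "classified_variants.tsv"))
  excluded <- classified[
    classified$qualifying_status != "qualifying" | classified$pdv_mode == "none",
    c("variant_id", "subject_id", "gene", "qualifying_status", "reason_codes",
      "pdv_mode", "pdv_rationale")
  ]
  utils::write.table(excluded, file.path(out_dir, "excluded_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  scalars <- unclass(summary)
  scalars <- scalars[vapply(scalars, length, integer(1)) == 1L]
  jsonlite::write_json(
    scalars, file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(out_dir, inputs = list(n_variants = nrow(variants),
                                        n_subjects = nrow(subjects)),
                 config_snapshot = unclass(config))
  invisible(summary)
}

#' Simulate a cohort and write its tables
#'
#' Writes the three cohort TSVs (same formats the readers consume), the
#' ground-truth table and a manifest recording the seed.
#'
#' @param config [sim_config()] object.
#' @param out_dir output directory.
#' @return The simulated cohort, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  wt <- function(df, f) {
    utils::write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  wt(sim$subjects, "subjects.tsv")
  wt(sim$variants[setdiff(names(sim$variants), "origin")], "variants.tsv")
  wt(sim$evidence, "gene_evidence.tsv")
  wt(sim$ground_truth, "ground_truth.tsv")
  write_manifest(out_dir, inputs = list(), config_snapshot = unclass(config),
                 seed = config$seed)
  invisible(sim)
}

#' Exact-test report for one 2x2 table
#'
#' @param a,b,c,d cell counts, row-major.
#' @param confidence confidence level for the odds-ratio interval.
#' @return List with `p`, `or`, `lower`, `upper`; printed compactly.
#' @export
#' @examples
#' run_stats(29, 2, 5, 10) # OR 29
run_stats <- function(a, b, c, d, confidence = 0.95) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p <- fisher_exact_two_tailed(tab)
  or <- odds_ratio_with_ci(tab, confidence)
  cat(sprintf("table [[%d,%d],[%d,%d]]  p = %.4g (%.2f)  OR = %.3g (%.0f%% CI %.3g-%.3g)%s\n",
              a, b, c, d, p, round(p, 2), or$or, 100 * confidence, or$lower,
              or$upper, if (or$corrected) "  [Haldane-Anscombe corrected]" else ""))
  invisible(list(p = p, or = or$or, lower = or$lower, upper = or$upper))
}
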