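# Cohort statistics: exact contingency-table tests implemented by direct
# hypergeometric enumeration, odds ratios with log-method confidence
# intervals, the expected de novo coding burden, and cohort summaries.

as_table2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("a 2x2 table is required")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("cell counts must be nonnegative integers")
  }
  if (sum(m) == 0) stop("table total must be positive")
  storage.mode(m) <- "double"
  m
}

#' Hypergeometric support of a 2x2 table with fixed margins
#'
#' Enumerates every value of the top-left cell compatible with the observed
#' margins and its point probability under the central hypergeometric
#' distribution (computed via log-binomial coefficients). The probabilities
#' sum to 1.
#'
#' @param table 2x2 matrix of counts.
#' @return data.frame with `k` (top-left cell) and `prob`.
#' @export
hypergeom_support <- function(table) {
  m <- as_table2x2(table)
  r1 <- m[1, 1] + m[1, 2]
  r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]
  n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  data.frame(k = k, prob = exp(logp))
}

#' Two-tailed Fisher exact test by hypergeometric enumeration
#'
#' Exact two-sided p-value with margins fixed: the sum of point
#' probabilities of every table in the support whose probability does not
#' exceed that of the observed table (the standard two-sided rule, with a
#' 1e-7 relative tolerance on the comparison to absorb floating-point ties).
#' Degenerate margins (an empty row or column) return p = 1 by convention,
#' with a warning. The p-value is invariant under row swap, column swap and
#' transpose.
#'
#' @param table 2x2 matrix (or anything coercible) of counts; rows are
#'   groups, columns outcomes.
#' @return The p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_tailed(matrix(c(22, 4, 12, 12), 2, byrow = TRUE)) # ~0.0145
fisher_exact_two_tailed <- function(table) {
  m <- as_table2x2(table)
  margins <- c(rowSums(m), colSums(m))
  if (any(margins == 0)) {
    warning("degenerate margin: no association is testable; p = 1 by convention")
    return(1)
  }
  supp <- hypergeom_support(m)
  p_obs <- supp$prob[supp$k == m[1, 1]]
  p <- sum(supp$prob[supp$prob <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Odds ratio with log-method confidence interval
#'
#' OR = (a d)/(b c) with the Woolf (log) interval
#' exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero
#' the Haldane-Anscombe correction (0.5 added to every cell) is applied and
#' flagged; with `correct = FALSE` a zero in b or c yields an infinite OR,
#' signalled explicitly.
#'
#' @param table 2x2 matrix of counts `[[a, b], [c, d]]`.
#' @param confidence confidence level (default 0.95).
#' @param correct apply the Haldane-Anscombe correction to zero-cell tables.
#' @return List with `or`, `lower`, `upper`, `confidence` and `corrected`.
#' @export
#' @examples
#' odds_ratio_with_ci(matrix(c(29, 2, 5, 10), 2, byrow = TRUE)) # OR 29
odds_ratio_with_ci <- function(table, confidence = 0.95, correct = TRUE) {
  m <- as_table2x2(table)
  corrected <- FALSE
  if (any(m == 0)) {
    if (!correct) {
      if (m[1, 2] * m[2, 1] == 0) {
        return(list(or = Inf, lower = NA_real_, upper = NA_real_,
                    confidence = confidence, corrected = FALSE))
      }
    } else {
      m <- m + 0.5
      corrected <- TRUE
    }
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       confidence = confidence, corrected = corrected)
}

#' Expected de novo coding burden per individual
#'
#' With a de novo mutation rate `mu_per_bp` per base pair per generation and
#' a coding target of `coding_bp` base pairs, the expected number of coding
#' de novo variants per person is `mu_per_bp * coding_bp`; removing the
#' silent fraction gives the non-silent (amino-acid-changing) expectation.
#' At the defaults (1e-8/bp, 3e7 bp, silent fraction 1/3) this is 0.3 and
#' 0.2 per person.
#'
#' @param mu_per_bp per-base-pair de novo mutation rate.
#' @param coding_bp coding target size in base pairs.
#' @param silent_fraction fraction of coding de novo variants that are
#'   silent.
#' @return List with `raw_rate` and `nonsilent_rate`.
#' @export
expected_dnv_rate <- function(mu_per_bp = 1e-8, coding_bp = 3e7,
                              silent_fraction = 1 / 3) {
  raw <- mu_per_bp * coding_bp
  list(raw_rate = raw, nonsilent_rate = raw * (1 - silent_fraction))
}

#' Per-subject and cohort aggregates after classification
#'
#' Counts each subject once per stratum regardless of how many variants it
#' carries. Lab-identified counts use the `on_lab_report` flag of PDV
#' variants. The de novo tallies cover variants of de novo origin:
#' total, Qualifying, the Direct/non-Direct split of both, and the number
#' unlikely to be disease-associated (non-Qualifying, or Qualifying in a
#' B2/B3 gene with no published ASD association).
#'
#' @param classified data.frame from [classify_cohort()].
#' @param subjects subject data.frame.
#' @return List of class `"triopdv_summary"`.
#' @export
summarize_cohort <- function(classified, subjects) {
  orphan <- setdiff(unique(classified$subject_id), subjects$subject_id)
  if (length(orphan) > 0) {
    stop("classified variants reference unknown subject(s): ",
         paste(orphan, collapse = ", "))
  }
  n_subjects <- nrow(subjects)
  pdv <- classified[classified$pdv_mode != "none", , drop = FALSE]
  denovo_pdv_subj <- unique(pdv$subject_id[pdv$pdv_mode == "de_novo"])
  inherited_pdv_subj <- unique(pdv$subject_id[pdv$pdv_mode != "de_novo"])
  any_pdv_subj <- unique(pdv$subject_id)
  lab_pdv_subj <- unique(pdv$subject_id[pdv$on_lab_report %in% TRUE])

  dnv <- classified[classified$origin == "de_novo", , drop = FALSE]
  dnv_q <- dnv$qualifying_status == "qualifying"
  dnv_direct <- dnv$is_direct
  unlikely <- !dnv_q | (dnv_q & dnv$gene_category %in% c("B2", "B3"))

  cpm <- classified[classified$is_cpm %in% TRUE, , drop = FALSE]
  cpm_subj <- unique(cpm$subject_id)
  qual_subj_counts <- table(factor(
    classified$subject_id[classified$qualifying_status == "qualifying"],
    levels = subjects$subject_id
  ))

  frac <- function(k) if (n_subjects > 0) k / n_subjects else 0
  out <- list(
    n_subjects = n_subjects,
    n_denovo_pdv_subjects = length(denovo_pdv_subj),
    n_inherited_pdv_subjects = length(inherited_pdv_subj),
    n_any_pdv_subjects = length(any_pdv_subj),
    n_lab_identified_pdv_subjects = length(lab_pdv_subj),
    yield_denovo = frac(length(denovo_pdv_subj)),
    yield_inherited = frac(length(inherited_pdv_subj)),
    yield_any = frac(length(any_pdv_subj)),
    yield_lab = frac(length(lab_pdv_subj)),
    denovo_pdv_subjects = denovo_pdv_subj,
    inherited_pdv_subjects = inherited_pdv_subj,
    any_pdv_subjects = any_pdv_subj,
    dnv_total = nrow(dnv),
    dnv_qualifying = sum(dnv_q),
    dnv_direct_total = sum(dnv_direct),
    dnv_direct_qualifying = sum(dnv_q & dnv_direct),
    dnv_nondirect_total = sum(!dnv_direct),
    dnv_nondirect_qualifying = sum(dnv_q & !dnv_direct),
    dnv_unlikely_disease = sum(unlikely),
    dnv_unlikely_disease_rate = frac(sum(unlikely)),
    n_cpm_variants = nrow(cpm),
    n_cpm_subjects = length(cpm_subj),
    n_cpm_subjects_with_pdv = length(intersect(cpm_subj, any_pdv_subj)),
    n_cpm_subjects_without_pdv = length(setdiff(cpm_subj, any_pdv_subj)),
    qualifying_per_subject = as.numeric(mean(qual_subj_counts))
  )
  class(out) <- "triopdv_summary"
  out
}

#' @export
print.triopdv_summary <- function(x, ...) {
  pct <- function(f) sprintf("%.0f%%", 100 * f)
  cat("Cohort of", x$n_subjects, "subjects\n")
  cat("  de novo PDV:  ", x$n_denovo_pdv_subjects, " (", pct(x$yield_denovo), ")\n", sep = "")
  cat("  inherited PDV:", x$n_inherited_pdv_subjects, " (", pct(x$yield_inherited), ")\n", sep = "")
  cat("  any PDV:      ", x$n_any_pdv_subjects, " (", pct(x$yield_any), ")\n", sep = "")
  cat("  lab-identified PDV:", x$n_lab_identified_pdv_subjects,
      " (", pct(x$yield_lab), ")\n", sep = "")
  cat("  de novo variants:", x$dnv_total, "(", x$dnv_qualifying, "Qualifying;",
      x$dnv_direct_qualifying, "/", x$dnv_direct_total, "Direct,",
      x$dnv_nondirect_qualifying, "/", x$dnv_nondirect_total, "non-Direct )\n")
  invisible(x)
}

PHENOTYPE_FLAGS <- c("tics_or_ocd", "tics", "ocd", "absent_speech",
                     "regression_any", "affected_first_degree_relative",
                     "sex", "seizures", "severe_id")

subject_flag <- function(subjects, flag) {
  switch(flag,
    tics_or_ocd = subjects$tics | subjects$ocd,
    tics = subjects$tics,
    ocd = subjects$ocd,
    absent_speech = subjects$absent_speech,
    regression_any = subjects$regression != "none",
    affected_first_degree_relative = subjects$affected_first_degree_relative,
    sex = subjects$sex == "F",
    seizures = subjects$seizures,
    severe_id = subjects$id_severity %in% c("moderate", "severe"),
    stop("unsupported phenotype flag: ", flag)
  )
}

#' Phenotype-PDV association
#'
#' Builds the 2x2 table of a phenotype flag against the presence of at least
#' one PDV and applies the exact test and odds-ratio operations. Rows are
#' (flag absent, flag present) -- the published comparisons are narrated in
#' varying orders, but the p-value is invariant and the odds ratio of the
#' reversed table is the reciprocal. Constant flags produce a degenerate
#' margin and p = 1 by convention.
#'
#' @param subjects subject data.frame.
#' @param classified data.frame from [classify_cohort()].
#' @param flag one of tics_or_ocd, tics, ocd, absent_speech, regression_any,
#'   affected_first_degree_relative, sex (female), seizures, severe_id.
#' @return List with `table` (2x2: rows flag absent/present, columns PDV
#'   yes/no), `p`, `or`, `lower`, `upper`.
#' @export
phenotype_association <- function(subjects, classified, flag) {
  flag_val <- subject_flag(subjects, flag)
  pdv_subj <- unique(classified$subject_id[classified$pdv_mode != "none"])
  has_pdv <- subjects$subject_id %in% pdv_subj
  tab <- matrix(
    c(sum(!flag_val & has_pdv), sum(!flag_val & !has_pdv),
      sum(flag_val & has_pdv), sum(flag_val & !has_pdv)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("flag_absent", "flag_present"), c("pdv", "no_pdv"))
  )
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    1
  } else {
    fisher_exact_two_tailed(tab)
  }
  or <- odds_ratio_with_ci(tab)
  list(table = tab, p = p, or = or$or, lower = or$lower, upper = or$upper)
}
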