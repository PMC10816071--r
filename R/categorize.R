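# Gene categorization: six evidence tiers. A1-A3 carry a published direct
# association with ASD ("Direct" genes); B1-B3 do not. Tiers are evaluated
# strongest-first and the first tier whose clauses fire wins, so conflicting
# evidence resolves to the stronger claim.

TIER_ORDER <- c("A1", "A2", "A3", "B1", "B2", "B3")

#' Assign a gene to one of the six evidence tiers
#'
#' Tier rules, evaluated A1 -> A2 -> A3 -> B1 -> B3 -> B2 (first match wins):
#' \describe{
#'   \item{A1}{SFARI rank 1 (or 1S) or a 4- or 5-star AutDB evidence score.}
#'   \item{A2}{SFARI rank 2 (2S) or a 3-star AutDB score.}
#'   \item{A3}{SFARI rank 3 (3S) or a 2-star AutDB score; or an exonic de
#'     novo variant with CADD > 20 reported in another neurodevelopmental
#'     disorder; or a variant reported in an ASD case in a gene associated
#'     with another NDD; or >= 10 ASD copy-number-variant reports; or an
#'     ASD-like animal model. A B1-eligible gene is promoted to A3 when it
#'     is loss-of-function intolerant and either enriched among Fragile-X
#'     target genes in ASD or accumulates de novo mutations in
#'     brain-expressed exons. Mitochondrial-encoded genes default to A3
#'     (rationale tag `mtDNA_default`), overridable by explicit evidence.}
#'   \item{B1}{published direct association with a Direct gene, association
#'     with another ASD-linked NDD phenotype (CADD >= 20), or membership in
#'     an established ASD pathway.}
#'   \item{B3}{known effects predominately in non-nervous tissues (only when
#'     nothing stronger fires).}
#'   \item{B2}{default: unknown association.}
#' }
#' Syndromic SFARI flags (1S/2S/3S) map to the same numeric tier.
#'
#' @param evidence one-row data.frame as returned by
#'   [read_gene_evidence()]/[default_evidence()].
#' @return List with `label` (tier), `is_direct` (label in A1-A3) and
#'   `rationale` (character vector of fired clauses; `"default"` for B2).
#' @export
#' @examples
#' ev <- default_evidence("EHMT1"); ev$sfari_rank <- 1L
#' categorize_gene(ev)$label # "A1"
categorize_gene <- function(evidence) {
  stopifnot(nrow(evidence) == 1)
  e <- as.list(evidence)
  rank <- e$sfari_rank
  stars <- e$autdb_stars

  b1_clauses <- c(
    if (isTRUE(e$direct_link_to_direct_gene)) "direct_link_to_direct_gene",
    if (isTRUE(e$linked_other_ndd_cadd20)) "linked_other_ndd_cadd20",
    if (isTRUE(e$asd_pathway_member)) "asd_pathway_member"
  )

  a1 <- c(
    if (!is.na(rank) && rank == 1L) "sfari_rank_1",
    if (!is.na(stars) && stars >= 4L) "autdb_4_5_star"
  )
  if (length(a1)) return(tier_result("A1", a1))

  a2 <- c(
    if (!is.na(rank) && rank == 2L) "sfari_rank_2",
    if (!is.na(stars) && stars == 3L) "autdb_3_star"
  )
  if (length(a2)) return(tier_result("A2", a2))

  a3 <- c(
    if (!is.na(rank) && rank == 3L) "sfari_rank_3",
    if (!is.na(stars) && stars == 2L) "autdb_2_star",
    if (isTRUE(e$de_novo_cadd20_in_other_ndd)) "de_novo_cadd20_in_other_ndd",
    if (isTRUE(e$variant_reported_in_asd_case)) "variant_reported_in_asd_case",
    if (!is.na(e$asd_cnv_count) && e$asd_cnv_count >= 10L) "asd_cnv_count_ge_10",
    if (isTRUE(e$asd_like_animal_model)) "asd_like_animal_model"
  )
  if (length(b1_clauses) && isTRUE(e$lof_intolerant) &&
      (isTRUE(e$fxs_gene_asd_enriched) || isTRUE(e$brain_exon_dnm_accumulation))) {
    a3 <- c(a3, "b1_promotion_lof_intolerant")
  }
  if (isTRUE(e$is_mtDNA) && length(a3) == 0L) {
    a3 <- "mtDNA_default"
  }
  if (length(a3)) return(tier_result("A3", a3))

  if (length(b1_clauses)) return(tier_result("B1", b1_clauses))

  if (isTRUE(e$predominately_non_nervous)) {
    return(tier_result("B3", "predominately_non_nervous"))
  }
  tier_result("B2", "default")
}

tier_result <- function(label, rationale) {
  list(label = label, is_direct = label %in% c("A1", "A2", "A3"),
       rationale = rationale)
}

#' Categorize every gene in an evidence table
#'
#' @param evidence data.frame from [read_gene_evidence()].
#' @return data.frame with `gene`, `gene_category`, `is_direct`, `rationale`
#'   (clauses joined by `;`).
#' @export
categorize_genes <- function(evidence) {
  if (nrow(evidence) == 0) {
    return(data.frame(gene = character(), gene_category = character(),
                      is_direct = logical(), rationale = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    res <- categorize_gene(evidence[i, , drop = FALSE])
    data.frame(gene = evidence$gene[i], gene_category = res$label,
               is_direct = res$is_direct,
               rationale = paste(res$rationale, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Category (and directness) for a possibly multi-gene record: a contiguous
# CNV spanning several genes is evaluated once per overlapped gene and the
# best tier wins; that gene becomes the reportable unit.
best_gene_category <- function(gene_field, evidence) {
  genes <- trimws(strsplit(gene_field, ";", fixed = TRUE)[[1]])
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) genes <- gene_field
  labels <- vapply(genes, function(g) {
    categorize_gene(evidence_for_gene(evidence, g))$label
  }, character(1))
  best <- which.min(match(labels, TIER_ORDER))
  list(gene = unname(genes[best]), gene_category = unname(labels[best]),
       is_direct = unname(labels[best]) %in% c("A1", "A2", "A3"))
}
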