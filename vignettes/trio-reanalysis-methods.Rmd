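---
title: "Methods: trio-WGS reanalysis and diagnostic variant classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-WGS reanalysis and diagnostic variant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triopdv)
```

## The problem

Commercial laboratory reports for trio whole-genome sequencing (proband
plus both biological parents) in autism spectrum disorder deliberately
restrict themselves to established disease genes. A substantial fraction
of plausibly causal variants — above all de novo variants in genes with
published ASD association but no prior clinical case — never reach the
report. `triopdv` implements a reanalysis rule set that re-examines every
annotated variant in a trio against explicit, auditable criteria and
aggregates the per-subject outcomes into cohort-level diagnostic yields
and association statistics.

The pipeline has four stages, each a pure function of its inputs:

1. **Gene categorization** — six evidence tiers from a curated
   gene-evidence table.
2. **Qualifying determination** — is the variant real, coding, rare and
   conserved?
3. **Inheritance-mode assignment** — five rules designate Primary
   Diagnostic Variants (PDVs); Qualifying nuclear Direct-gene variants
   that fall short become Candidate Polygenic Modifiers (CPMs).
4. **Cohort analytics** — yields, exact 2×2 tests, odds ratios, and the
   expected de novo coding burden.

## Gene tiers

Genes are ranked A1–A3 ("Direct": a published direct association with
ASD) or B1–B3 ("non-Direct") from a static evidence table — SFARI ranks,
AutDB star scores, CNV report counts, animal models, pathway membership
and related flags. Tiers are evaluated strongest-first and the first tier
whose clauses fire wins, so conflicting evidence resolves to the stronger
claim. Two special rules: a B1-eligible gene that is loss-of-function
intolerant and either Fragile-X-target enriched in ASD or accumulating de
novo mutations in brain-expressed exons is promoted to A3; and
mitochondrial-encoded genes default to A3 (Direct but hard to
subclassify), overridable by explicit evidence. B3 (predominately
non-nervous tissue effects) is applied only when nothing stronger fires,
and a gene that is both B1-eligible and non-nervous stays B1 — an
indirect ASD link outranks a tissue heuristic. Only Direct genes can host
a PDV or CPM; this restriction is the principal guard against false
positives when all 23 000+ genes are in scope.

## Qualifying variants

A variant is **Qualifying** iff it is:

* **real** — IGV-verified (consumed as an input flag; review is upstream);
* **coding** — it changes the amino-acid code: missense, in-frame indel,
  frameshift, stop gain, whole-gene deletion; splice acceptor/donor
  variants count only when SpliceRF *or* SpliceADA exceeds 0.6; whole-gene
  duplications count by default (config-gated, since duplications are
  reported as modifiers but their gene-disruptive status is input data);
* **rare** — comparison-population allele frequency strictly below 1/100
  (the supplier chooses the population; the study used gnomAD non-Finnish
  Europeans). A missing frequency fails closed with `FREQUENCY_MISSING`;
* **conserved** — both PhyloP and PhastCons above 0.7 ⇒ conserved, both
  below 0.4 ⇒ not conserved; anything else is decided by the
  `manual_conserved` input, and with no manual call the status is
  `needs_manual_conservation` — never a silent pass or fail.

Two exclusions: mitochondrial variants below 20% heteroplasmy are
rejected as likely recent somatic events (`SOMATIC_SUSPECT`), and a
*single* heterozygous variant in a well-established
autosomal-recessive-only disease gene is set aside as probable carrier
status (`CARRIER_EXCLUDED`); a second heterozygous candidate in the same
gene lifts that exclusion, since a compound heterozygote is then
possible.

**Conservation waiver.** The source rule set applies conservation to
substitution-type variants; for clearly protein-destroying events
(frameshift, stop gain, whole-gene deletion) per-base conservation is
undefined or irrelevant, so it is waived by default. The waiver is a
config switch (`waive_conservation_for_null`) because the source
methodology never states the frameshift case explicitly — we prefer an
explicit switch over a guess presented as fact.

Every failed gate contributes a machine-readable reason code; decisions
are auditable row by row in the classified TSV.

## Inheritance modes

PDVs require a Qualifying variant in a Direct gene *plus* clinical
correlation *plus* one of five mode rules, tested in a fixed order
(de novo, X-linked, autosomal recessive, autosomal dominant, maternal
mitochondrial). The order mirrors the pipeline flow; in practice a
variant satisfies at most one rule, but fixed precedence makes the
function total and deterministic.

| mode | frequency gate | genotype/pedigree conditions |
|---|---|---|
| de novo | < 1/10 000 | absent from both parents |
| X-linked | < 1/10 000 | hemizygous male proband, heterozygous mother |
| autosomal recessive | < 1/100 | inherited homozygote with both parents het, or in-trans compound het |
| autosomal dominant | < 1/10 000 | transmitting parent affected with significant NDD |
| maternal (mtDNA) | < 1/10 000 | 4-of-8-domain mitochondrial correlation, heteroplasmy in [40%, 98%] and/or suggestive maternal pedigree |

Compound-heterozygote phasing is trio-based: a pair is in trans iff one
variant is maternal-origin and the other paternal-origin; unknown-origin
candidates are reported as unphased, never guessed. Both partners of an
in-trans pair carry the recessive mode. Homozygotes whose parents are not
both heterozygous are flagged `MENDELIAN_INCONSISTENT` (uniparental
events are out of scope). Heterozygous female probands at X-linked loci
are rejected with `XL_FEMALE_UNSPECIFIED`: the source rules only state
the hemizygous-male case, and we refuse to invent one.

Clinical correlation is expert judgment and therefore an *input* flag —
with one exception: for mitochondrial variants the protean phenotype
makes gene-level matching impossible, so correlation is *computed* as
"mitochondrial-related findings in ≥ 4 of 8 domains" (neuromuscular,
neurodevelopmental, neuropsychiatric, functional, endocrine,
immunological, metabolic, enzymological). The quantitative-pedigree
maternal-inheritance analysis is likewise out of scope; its ratios are
stored for reporting and a boolean `maternal_pedigree_flag` carries its
conclusion.

A **CPM** is any Qualifying variant in a *nuclear* Direct gene that is
neither a PDV nor the partner of one; PDV ∩ CPM = ∅ by construction.

A reduced ACMG mapping is provided for context: PS2 (de novo), PM2
(frequency < 1/100 000 — nonzero ultra-rare frequencies are accepted
because modern control databases cannot exclude mildly affected
carriers), PVS1 (null variant). PS2+PM2 ⇒ Likely Pathogenic, +PVS1 ⇒
Pathogenic, else VUS.

## Thresholds

All gates live in one `thresholds()` object: `rare_max` 1/100,
`very_rare_max` 1/10 000 (frequencies as population fractions),
`conserved_both_min` 0.7 / `not_conserved_both_max` 0.4 (score units),
`splice_min` 0.6, heteroplasmy band 0.40–0.98 with somatic exclusion
below 0.20 (minor-allele fractions), `mito_domains_min` 4 (count),
`pm2_max` 1/100 000, plus the two behavioural switches. Frequency gates
are strict (`<`): a variant at exactly 1/100 is common. A plain
`key = value` file can override any field (`read_thresholds()`).

## Cohort statistics

The two-tailed Fisher exact test is implemented from first principles:
with margins fixed, the support of the top-left cell is enumerated, point
probabilities are computed from log-binomial coefficients, and the
two-sided p is the sum of all point probabilities not exceeding the
observed one (with a 1e-7 relative tolerance for floating-point ties —
the same convention R's `fisher.test` uses, so the two agree to numerical
precision; tests cross-check both against a `dhyper`-based enumerator on
every margin configuration up to n = 60). Degenerate margins return p = 1
with a warning. Odds ratios use the Woolf log method,
exp(log OR ± z·√(1/a+1/b+1/c+1/d)), with the Haldane–Anscombe 0.5
correction applied (and flagged) only for zero-cell tables. The expected
de novo coding burden is the linear model μ·L (default 1e-8/bp × 3e7 bp
= 0.3 per person; 0.2 after removing the silent third).

One published statistic is deliberately not reproduced: the enrichment
table [[29,2],[5,10]] is printed with p = 0.0002, but every standard
two-sided exact computation gives 3.7e-5. The source calculator is
unknown; we report the enumerated value and note the discrepancy rather
than matching the print.

## The synthetic cohort generator

`simulate_cohort()` exists so every pipeline stage is testable without
external data. Its defaults are the study conditions and are not tuning
knobs: 50 trios, 24% female; background coding de novo count per subject
~ Poisson(0.3) (μ = 1e-8/bp over 3e7 bp), one third silent; Qualifying
probabilities 29/31 (Direct) and 5/15 (non-Direct); planted PDVs in 25
de novo and 10 inherited subjects (3 X-linked, 2+2 recessive, 2 dominant,
1 maternal) with one dual-PDV subject; phenotype-flag prevalences at the
cohort marginals (tics/OCD 24/50, absent speech 13/50, regression 27/50).
Annotation values are drawn in the *decisive zones* of the rules —
very-rare frequencies log-uniform below 1e-5, common ones over
(1e-2, 0.5], conservation scores in (0.75, 0.99) or (0.01, 0.35) — so
every intended label is recoverable by construction, and
`manual_zone_rate` can deliberately degrade conservation scores into the
manual zone to verify that recovery then fails *only* into
`needs_manual_conservation`. Each subject has its own RNG stream derived
from (seed, index), so cohorts are stable under subsetting; the seed is
mandatory.

`regenerate_fixture_like()` additionally pins the printed marginals
exactly (46 de novo variants, 31/15 and 29/5 splits, 25/10/34 PDV
subjects, 14 lab-identified) while gene assignments vary with the seed.

What the generator deliberately does **not** emulate: realistic genome
coordinates, linkage and sequence context, annotation-tool noise
(scores are drawn in unambiguous zones unless degraded), recurrent genes,
or correlated phenotypes. Passing recovery tests therefore demonstrates
that the classifier inverts its own rules exactly — a correctness
property — not that the rules are robust to messy real-world annotation,
which is precisely why ambiguous conservation is routed to a human.

## The packaged cohort transcription

`load_fixture_cohort("paper_cohort")` ships a transcription of the
50-subject study: phenotypes, per-subject Qualifying variants with
PDV/lab-report status, and evidence rows reproducing the published gene
categories. Fields the printed tables do not pin down — coordinates,
scores, and filler gene symbols for the unnamed non-Qualifying de novo
variants — are synthetic but rule-consistent and flagged `synthetic = 1`.
Two reconciliations were needed where the printed per-row detail
(conveyed by table shading) conflicts with the printed aggregates: one
OCD flag was moved between two subjects so the tics/OCD 2×2 matches its
printed cells, and one ambiguous family-history entry was counted as
affected to match the printed first-degree-relative split. Anonymous
CNVs in the inherited-variant column are omitted, so per-subject CPM
tallies slightly under-count the printed ones; all subject-level PDV
counts are exact.

## Numerical and degenerate-input choices

* Frequencies, heteroplasmy and conservation gates are strict
  inequalities except the heteroplasmy PDV band, which is inclusive.
* Missing annotation values are explicit NAs, never zeros; rules that
  need them fail closed with a reason code.
* Coordinates are 1-based inclusive; CNVs require `end > position`.
* Malformed variant rows are collected into an error report, not
  silently dropped; structural problems (missing columns, duplicate
  genes, unknown enum tokens) are fatal.
* Empty cohorts summarize to zeros; constant phenotype flags give p = 1
  by the degenerate-margin convention.
* Multi-gene CNVs are one record; classification evaluates every
  overlapped gene and reports the best tier.

## Problem sizes

The test suite exercises exhaustive enumerations where they are cheap
(all trio-genotype combinations; all 2×2 margins up to 7+7) and sampled
checks elsewhere (300 random tables up to n = 60 against two independent
oracles; 200–600-subject simulated cohorts for recovery, subsetting and
dispersion; one 1 000-subject cohort for the at-scale invariants). The
analysis scripts use a 500-trio synthetic cohort. These sizes give
Monte-Carlo standard errors comfortably below the asserted tolerances
while keeping the full suite under a minute of compute.

## Limitations

Alignment, variant calling, annotation (CADD, PhyloP, splice scores),
IGV review, repeat-expansion genotyping and the quantitative pedigree
analysis are all consumed as inputs, never computed. Clinical correlation
for nuclear genes is expert input; two experts may disagree and the
pipeline will faithfully amplify that disagreement into yield
differences. X-linked heterozygous females, uniparental disomy and
loss-of-heterozygosity events are recognized and refused, not resolved.
The evidence table is a snapshot; tiers move as SFARI/AutDB evolve, and
yields with them.
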