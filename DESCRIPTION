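Package: triopdv
Title: Trio Whole-Genome Reanalysis and Diagnostic Variant Classification for Autism Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reanalysis workflow for trio whole-genome sequencing in autism
    spectrum disorder cohorts. Ranks genes into six evidence tiers (A1-A3
    "Direct", B1-B3 "non-Direct") from curated gene-evidence tables, decides
    Qualifying status for annotated variants (verified, coding, rare,
    conserved, with splice-score and carrier-status gates), assigns Primary
    Diagnostic Variants under five inheritance-mode rules (de novo, X-linked,
    autosomal recessive with trio-based compound-heterozygote phasing,
    autosomal dominant, maternal mitochondrial with heteroplasmy bounds),
    designates Candidate Polygenic Modifiers, and computes cohort statistics:
    diagnostic yields, two-tailed Fisher exact tests by hypergeometric
    enumeration, odds ratios with log-method confidence intervals, and the
    expected de novo coding burden. Includes a synthetic trio-cohort
    generator with planted ground truth and a transcription of the study
    cohort for end-to-end reproduction of the reported results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
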