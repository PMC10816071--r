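#' Classification thresholds
#'
#' Bundle of the numeric gates used by Qualifying-variant determination and
#' inheritance-mode assignment. Defaults mirror the published rule set:
#' variants are "rare" below a population prevalence of 1/100 and "very rare"
#' below 1/10,000; conservation is assumed present when both PhyloP and
#' PhastCons exceed 0.7 and absent when both are below 0.4 (the zone between
#' requires a manual call); splice variants pass at > 0.6 on either splice
#' score; mitochondrial heteroplasmy below 20% is treated as likely somatic,
#' while the maternal inheritance mode accepts minor-allele fractions in
#' [40%, 98%]; mitochondrial clinical correlation requires findings in at
#' least 4 of 8 domains; the PM2 evidence code applies below 1/100,000.
#'
#' @param rare_max strict upper bound on allele frequency for "rare".
#' @param very_rare_max strict upper bound for "very rare" (all inheritance
#'   modes except autosomal recessive, which uses `rare_max`).
#' @param conserved_both_min both conservation scores strictly above this
#'   imply conserved.
#' @param not_conserved_both_max both scores strictly below this imply not
#'   conserved.
#' @param splice_min strict lower bound on SpliceRF or SpliceADA for splice
#'   acceptor/donor variants.
#' @param heteroplasmy_pdv_low,heteroplasmy_pdv_high inclusive heteroplasmy
#'   band for the maternal mitochondrial mode.
#' @param heteroplasmy_somatic_exclusion heteroplasmy strictly below this is
#'   excluded as likely recent somatic.
#' @param mito_domains_min minimum number of mitochondrial clinical domains.
#' @param pm2_max strict allele-frequency bound for the PM2 evidence code.
#' @param waive_conservation_for_null waive the conservation requirement for
#'   clearly protein-destroying events (frameshift, stop gain, whole-gene
#'   deletion), for which per-base conservation is undefined.
#' @param dup_counts_as_coding treat whole-gene duplications as coding.
#' @return A named list with class `"triopdv_thresholds"`.
#' @export
#' @examples
#' cfg <- thresholds()
#' cfg$rare_max
thresholds <- function(rare_max = 1 / 100,
                       very_rare_max = 1 / 10000,
                       conserved_both_min = 0.7,
                       not_conserved_both_max = 0.4,
                       splice_min = 0.6,
                       heteroplasmy_pdv_low = 0.40,
                       heteroplasmy_pdv_high = 0.98,
                       heteroplasmy_somatic_exclusion = 0.20,
                       mito_domains_min = 4,
                       pm2_max = 1 / 100000,
                       waive_conservation_for_null = TRUE,
                       dup_counts_as_coding = TRUE) {
  cfg <- list(
    rare_max = rare_max,
    very_rare_max = very_rare_max,
    conserved_both_min = conserved_both_min,
    not_conserved_both_max = not_conserved_both_max,
    splice_min = splice_min,
    heteroplasmy_pdv_low = heteroplasmy_pdv_low,
    heteroplasmy_pdv_high = heteroplasmy_pdv_high,
    heteroplasmy_somatic_exclusion = heteroplasmy_somatic_exclusion,
    mito_domains_min = mito_domains_min,
    pm2_max = pm2_max,
    waive_conservation_for_null = isTRUE(waive_conservation_for_null),
    dup_counts_as_coding = isTRUE(dup_counts_as_coding)
  )
  fracs <- c(
    "rare_max", "very_rare_max", "conserved_both_min",
    "not_conserved_both_max", "splice_min", "heteroplasmy_pdv_low",
    "heteroplasmy_pdv_high", "heteroplasmy_somatic_exclusion", "pm2_max"
  )
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("threshold '", f, "' must be a single fraction in [0, 1]")
    }
  }
  if (cfg$not_conserved_both_max >= cfg$conserved_both_min) {
    stop("not_conserved_both_max must be below conserved_both_min")
  }
  if (cfg$heteroplasmy_somatic_exclusion >= cfg$heteroplasmy_pdv_low) {
    stop("heteroplasmy_somatic_exclusion must be below heteroplasmy_pdv_low")
  }
  if (cfg$heteroplasmy_pdv_low > cfg$heteroplasmy_pdv_high) {
    stop("heteroplasmy band is empty")
  }
  if (cfg$mito_domains_min < 0 || cfg$mito_domains_min != round(cfg$mito_domains_min)) {
    stop("mito_domains_min must be a nonnegative integer")
  }
  structure(cfg, class = "triopdv_thresholds")
}

#' Read a key=value threshold configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments
#' allowed. Unknown keys are an error; omitted keys keep their defaults.
#'
#' @param path file path.
#' @return A `triopdv_thresholds` object.
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed configuration line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    defaults <- formals(thresholds)
    if (!key %in% names(defaults)) stop("unknown threshold key: ", key)
    args[[key]] <- if (val %in% c("TRUE", "FALSE", "true", "false")) {
      toupper(val) == "TRUE"
    } else {
      as.numeric(val)
    }
  }
  do.call(thresholds, args)
}
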