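.FUNCTIONAL_CLASSES <- c("exonic_nonsynonymous", "exonic_synonymous",
                         "splicing", "other")

#' Tumor-only somatic variant filter cascade
#'
#' Applies, in order, the post-calling filters of a tumor-only exome
#' design: (1) keep only exonic non-synonymous and splice-site variants;
#' (2) drop variants seen in `recurrence_cutoff` or more of the sequenced
#' samples (likely sequencing artifacts); (3) drop variants with a minor
#' allele frequency of at least `maf_cutoff` in any of the 1000 Genomes,
#' ESP6500 or gnomAD columns (likely germline polymorphisms; a missing
#' MAF counts as rare — absence from population databases is the signal
#' this filter exploits); (4) drop small insertions/deletions in
#' interspersed repeats or low-complexity sequence. The rules are
#' independent predicates; each removal is attributed to the first
#' triggering rule so tallies are reproducible and conserve counts.
#'
#' @param variants Data frame with columns `functional_class` (one of
#'   `exonic_nonsynonymous`, `exonic_synonymous`, `splicing`, `other`),
#'   `variant_type` (`snv`/`indel`), `n_samples_with_variant`,
#'   `maf_1000g`, `maf_esp6500`, `maf_gnomad` (in \[0, 1\] or `NA`), and
#'   `in_repeat_or_low_complexity`.
#' @param recurrence_cutoff Drop variants present in at least this many
#'   samples (default 5).
#' @param maf_cutoff Population-frequency cutoff (default 0.01).
#' @return List of class `variant_filter_result`: `survivors` (rows
#'   passing every rule), `removed` (with a `rule` column), and `tally`
#'   (named removals per rule plus `kept`; sums to `nrow(variants)`).
#' @examples
#' vt <- gen_variant_table(sim_config(seed = 3))
#' filter_cascade(vt)$tally
#' @export
filter_cascade <- function(variants, recurrence_cutoff = 5L,
                           maf_cutoff = 0.01) {
  bad <- !variants$functional_class %in% .FUNCTIONAL_CLASSES
  if (any(bad))
    stop_oncomir("unknown functional_class '",
                 variants$functional_class[which(bad)[1]],
                 "' in record ", which(bad)[1])
  mafs <- cbind(variants$maf_1000g, variants$maf_esp6500,
                variants$maf_gnomad)
  if (any(mafs < 0 | mafs > 1, na.rm = TRUE))
    stop_oncomir("MAF values must lie in [0, 1]")
  rules <- list(
    functional_class = !variants$functional_class %in%
      c("exonic_nonsynonymous", "splicing"),
    recurrence = variants$n_samples_with_variant >= recurrence_cutoff,
    population_maf = apply(mafs >= maf_cutoff, 1, any, na.rm = TRUE),
    repeat_indel = variants$variant_type == "indel" &
      variants$in_repeat_or_low_complexity
  )
  hit <- rep(NA_character_, nrow(variants))
  for (nm in rev(names(rules))) hit[rules[[nm]]] <- nm
  tally <- vapply(names(rules), function(nm)
    sum(hit == nm, na.rm = TRUE), integer(1))
  tally <- c(tally, kept = sum(is.na(hit)))
  removed <- variants[!is.na(hit), , drop = FALSE]
  removed$rule <- hit[!is.na(hit)]
  structure(list(
    survivors = variants[is.na(hit), , drop = FALSE],
    removed = removed,
    tally = tally
  ), class = "variant_filter_result")
}

#' @export
print.variant_filter_result <- function(x, ...) {
  cat("Variant filter cascade:\n")
  print(x$tally)
  invisible(x)
}

#' Classify copy-number segments as gain, loss or neutral
#'
#' A segment is a `gain` when its log2 ratio exceeds `log2_cutoff` and a
#' `loss` when it falls below `-log2_cutoff`, in both cases requiring
#' `p_value < p_cutoff`; everything else is `neutral`. All inequalities
#' are strict, so a segment exactly on a boundary stays neutral.
#'
#' @param log2_ratio Numeric vector of segment log2 copy ratios.
#' @param p_value Segment p-values in \[0, 1\].
#' @param log2_cutoff Magnitude threshold (default 0.5).
#' @param p_cutoff Significance threshold (default 0.05).
#' @return Character vector in `gain`/`loss`/`neutral`.
#' @examples
#' classify_cnv(c(0.6, -0.6, 0.5, -0.7), c(0.01, 0.01, 0.01, 0.2))
#' @export
classify_cnv <- function(log2_ratio, p_value, log2_cutoff = 0.5,
                         p_cutoff = 0.05) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    stop_oncomir("`p_value` must lie in [0, 1]")
  ifelse(log2_ratio > log2_cutoff & p_value < p_cutoff, "gain",
  ifelse(log2_ratio < -log2_cutoff & p_value < p_cutoff, "loss",
         "neutral"))
}

#' Read an annotated variant table from TSV
#'
#' Reads the annotated tab-separated export of an upstream annotation
#' pipeline into the column layout [filter_cascade()] expects. The TSV
#' path bypasses VCF parsing entirely, keeping the cascade testable
#' without external annotators.
#'
#' @param path TSV file with a header matching the [filter_cascade()]
#'   columns.
#' @return Data frame of variant records.
#' @export
read_variant_tsv <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("functional_class", "variant_type", "n_samples_with_variant",
            "maf_1000g", "maf_esp6500", "maf_gnomad",
            "in_repeat_or_low_complexity")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop_oncomir(path, " lacks columns: ", paste(miss, collapse = ", "))
  v$in_repeat_or_low_complexity <- as.logical(v$in_repeat_or_low_complexity)
  v
}
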