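#' Merge per-core cell tables and flag intensity outliers
#'
#' Merges cell-level tables from all cores and computes, for every
#' median-intensity channel (columns ending in `_median`), z-scores over
#' the merged cohort. A cell is flagged `excluded` when its |z| exceeds
#' `z_threshold` in any median channel (symmetric by default: staining
#' dropouts and saturations both occur; `mode = "high_only"` restricts to
#' the upper tail). Excluded cells are retained with the flag set, never
#' dropped. A zero-variance channel yields no exclusions and a warning.
#'
#' @param tables A single merged cell data frame or a list of per-core
#'   data frames with identical headers (see [gen_tma_cohort()]).
#' @param z_threshold Exclusion threshold on the z-score (default 3).
#' @param mode `"two_sided"` or `"high_only"`.
#' @param quiet Suppress the exclusion-fraction message.
#' @return The merged data frame with `excluded` set; the per-channel
#'   exclusion counts are in attribute `exclusion_tally` and the overall
#'   fraction in `exclusion_fraction`.
#' @export
merge_and_filter <- function(tables, z_threshold = 3,
                             mode = c("two_sided", "high_only"),
                             quiet = FALSE) {
  mode <- match.arg(mode)
  if (is.data.frame(tables)) {
    cells <- tables
  } else {
    hdrs <- lapply(tables, names)
    if (!all(vapply(hdrs, identical, logical(1), hdrs[[1]])))
      stop_oncomir("per-core tables have inconsistent headers")
    cells <- do.call(rbind, tables)
  }
  channels <- grep("_median$", names(cells), value = TRUE)
  channels <- channels[!is_truth_col(channels)]
  if (length(channels) == 0L)
    stop_oncomir("no `*_median` intensity channels found")
  excl <- rep(FALSE, nrow(cells))
  tally <- stats::setNames(integer(length(channels)), channels)
  for (ch in channels) {
    v <- cells[[ch]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("channel '", ch, "' has zero variance; no exclusions applied",
              call. = FALSE)
      next
    }
    z <- (v - mean(v)) / s
    hit <- if (mode == "two_sided") abs(z) > z_threshold else z > z_threshold
    tally[ch] <- sum(hit)
    excl <- excl | hit
  }
  cells$excluded <- excl
  frac <- mean(excl)
  if (!quiet)
    message(sprintf("excluded %d of %d cells (%.2f%%) at |z| > %s",
                    sum(excl), length(excl), 100 * frac,
                    format(z_threshold)))
  attr(cells, "exclusion_tally") <- tally
  attr(cells, "exclusion_fraction") <- frac
  cells
}

#' Summarize TMA cores over their tumor compartment
#'
#' For each core, averages the median cellular intensities (median
#' cytoplasmic miR-21, median nuclear CDK2AP1) across non-excluded tumor
#' cells, and computes the cell-level Pearson correlation between the two
#' channels. Cores with fewer than `min_tumor_cells` non-excluded tumor
#' cells are flagged `included = FALSE` (never dropped). A constant
#' channel leaves `pearson_r` undefined (`NA`).
#'
#' @param cells Output of [merge_and_filter()] (the `excluded` flag must
#'   be set).
#' @param min_tumor_cells Minimum non-excluded tumor cells for inclusion
#'   (default 500).
#' @param pearson_cells `"tumor"` (default; core aggregates are
#'   tumor-compartment) or `"all"`.
#' @return Data frame, one row per core: `core_id`, `patient_id`,
#'   `n_tumor_cells`, `n_stroma_cells`, `mir21_tumor`, `cdk2ap1_tumor`,
#'   `pearson_r`, `included`.
#' @export
summarize_cores <- function(cells, min_tumor_cells = 500L,
                            pearson_cells = c("tumor", "all")) {
  pearson_cells <- match.arg(pearson_cells)
  if (!"excluded" %in% names(cells))
    stop_oncomir("`cells` lacks the `excluded` flag; run merge_and_filter() first")
  keep <- !cells$excluded
  split_idx <- split(seq_len(nrow(cells)), cells$core_id)
  rows <- lapply(names(split_idx), function(cid) {
    i <- split_idx[[cid]]
    tum <- i[keep[i] & cells$compartment[i] == "tumor"]
    str <- i[keep[i] & cells$compartment[i] == "stroma"]
    ci <- if (pearson_cells == "tumor") tum else i[keep[i]]
    mir <- cells$mir21_cyto_median[ci]
    cdk <- cells$cdk2ap1_nuc_median[ci]
    r <- if (length(ci) >= 2L && stats::sd(mir) > 0 && stats::sd(cdk) > 0)
      stats::cor(mir, cdk) else NA_real_
    data.frame(
      core_id = cid,
      patient_id = cells$patient_id[i][1],
      n_tumor_cells = length(tum),
      n_stroma_cells = length(str),
      mir21_tumor = if (length(tum)) mean(cells$mir21_cyto_median[tum]) else NA_real_,
      cdk2ap1_tumor = if (length(tum)) mean(cells$cdk2ap1_nuc_median[tum]) else NA_real_,
      pearson_r = r,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$included <- out$n_tumor_cells >= min_tumor_cells
  rownames(out) <- NULL
  out
}

#' Rank cores by inverse miR-21/CDK2AP1 correlation
#'
#' Orders the included cores by ascending Pearson correlation (strongest
#' anti-correlation first). Cores with undefined correlation rank last;
#' ties break by `core_id`. Excluded cores never appear.
#'
#' @param summaries Output of [summarize_cores()].
#' @return The included subset of `summaries`, ordered, with a `rank`
#'   column.
#' @export
rank_cores <- function(summaries) {
  s <- summaries[summaries$included, , drop = FALSE]
  ord <- order(is.na(s$pearson_r), s$pearson_r, s$core_id)
  s <- s[ord, , drop = FALSE]
  s$rank <- seq_len(nrow(s))
  rownames(s) <- NULL
  s
}

#' Tumor-versus-stroma compartment comparison
#'
#' Per core, averages the median cytoplasmic miR-21 and median nuclear
#' CDK2AP1 of non-excluded cells separately in the tumor and stroma
#' compartments and forms stroma/tumor ratios; cohort-level inference is
#' run on the per-core log2 ratios. Cores missing a compartment are
#' skipped with a warning.
#'
#' @param cells Output of [merge_and_filter()].
#' @param test `"one_sample_t"` (default; per-core log2 ratios against
#'   0), `"welch"` (unpaired t between per-core tumor and stroma means)
#'   or `"wilcoxon"` (paired signed-rank on per-core means).
#' @return List of class `compartment_comparison`: `per_core` data frame
#'   and `tests`, a data frame with per-marker mean stroma/tumor ratio
#'   and p-value.
#' @export
compare_compartments <- function(cells,
                                 test = c("one_sample_t", "welch", "wilcoxon")) {
  test <- match.arg(test)
  keep <- !cells$excluded
  markers <- c(mir21 = "mir21_cyto_median", cdk2ap1 = "cdk2ap1_nuc_median")
  split_idx <- split(seq_len(nrow(cells))[keep], cells$core_id[keep])
  rows <- lapply(names(split_idx), function(cid) {
    i <- split_idx[[cid]]
    tum <- i[cells$compartment[i] == "tumor"]
    str <- i[cells$compartment[i] == "stroma"]
    if (!length(tum) || !length(str)) return(NULL)
    data.frame(
      core_id = cid,
      marker = names(markers),
      tumor_mean = vapply(markers, function(m) mean(cells[[m]][tum]), numeric(1)),
      stroma_mean = vapply(markers, function(m) mean(cells[[m]][str]), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped)
    warning(skipped, " core(s) missing a compartment were skipped",
            call. = FALSE)
  per_core <- do.call(rbind, rows)
  if (is.null(per_core) || nrow(per_core) == 0L)
    stop_oncomir("no core has both compartments")
  per_core$ratio <- per_core$stroma_mean / per_core$tumor_mean
  tests <- do.call(rbind, lapply(split(per_core, per_core$marker), function(d) {
    p <- if (nrow(d) < 2L) NA_real_ else switch(test,
      one_sample_t = stats::t.test(log2(d$ratio), mu = 0)$p.value,
      welch = stats::t.test(d$stroma_mean, d$tumor_mean)$p.value,
      wilcoxon = stats::wilcox.test(d$stroma_mean, d$tumor_mean,
                                    paired = TRUE, exact = FALSE)$p.value
    )
    data.frame(marker = d$marker[1], mean_ratio = mean(d$ratio),
               log2_ratio = mean(log2(d$ratio)), p_value = p, test = test,
               n_cores = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  structure(list(per_core = per_core, tests = tests),
            class = "compartment_comparison")
}

#' @export
print.compartment_comparison <- function(x, ...) {
  cat("Tumor-vs-stroma compartment comparison\n")
  print(x$tests, ...)
  invisible(x)
}

#' Stratify cores by tumor miR-21 and test CDK2AP1 separation
#'
#' Included cores are labeled `high` when their mean tumor-cell
#' cytoplasmic miR-21 median exceeds `mir21_cutoff` (raw intensity
#' scale), `low` otherwise (exact equality counts as low); non-included
#' cores are labeled `excluded`. Mean tumor-cell nuclear CDK2AP1 is then
#' compared between the groups: Welch's t when `pairing = "unpaired"`,
#' or, with `pairing = "patient_paired"`, per-patient group means are
#' paired within patients represented in both groups and tested by a
#' paired t.
#'
#' @param summaries Output of [summarize_cores()].
#' @param mir21_cutoff Stratification cutoff on the raw intensity scale
#'   (default 150).
#' @param pairing `"unpaired"` (default) or `"patient_paired"`.
#' @return List of class `tma_strat`: `summaries` with `strat_group`,
#'   and `test` (method, per-group means/sizes, statistic, p_value,
#'   status). An empty group sets `status` to `"skipped"` with `NA`
#'   statistics.
#' @export
stratify_and_test <- function(summaries, mir21_cutoff = 150,
                              pairing = c("unpaired", "patient_paired")) {
  pairing <- match.arg(pairing)
  s <- summaries
  s$strat_group <- ifelse(!s$included, "excluded",
                          ifelse(s$mir21_tumor > mir21_cutoff, "high", "low"))
  inc <- s[s$included, , drop = FALSE]
  hi <- inc[inc$strat_group == "high", , drop = FALSE]
  lo <- inc[inc$strat_group == "low", , drop = FALSE]
  test <- list(method = pairing, cutoff = mir21_cutoff,
               n_high = nrow(hi), n_low = nrow(lo),
               mean_cdk2ap1_high = if (nrow(hi)) mean(hi$cdk2ap1_tumor) else NA_real_,
               mean_cdk2ap1_low = if (nrow(lo)) mean(lo$cdk2ap1_tumor) else NA_real_,
               statistic = NA_real_, p_value = NA_real_, status = "ok")
  if (nrow(hi) == 0L || nrow(lo) == 0L) {
    test$status <- sprintf("skipped: empty %s group",
                           if (nrow(hi) == 0L) "high" else "low")
  } else if (pairing == "unpaired" && (nrow(hi) < 2L || nrow(lo) < 2L)) {
    test$status <- "skipped: fewer than 2 cores in a group"
  } else if (pairing == "unpaired") {
    tt <- stats::t.test(hi$cdk2ap1_tumor, lo$cdk2ap1_tumor)
    test$statistic <- unname(tt$statistic)
    test$p_value <- tt$p.value
  } else {
    ph <- tapply(hi$cdk2ap1_tumor, hi$patient_id, mean)
    pl <- tapply(lo$cdk2ap1_tumor, lo$patient_id, mean)
    both <- intersect(names(ph), names(pl))
    test$n_pairs <- length(both)
    if (length(both) < 2L) {
      test$status <- "skipped: fewer than 2 patients in both groups"
    } else {
      tt <- stats::t.test(ph[both], pl[both], paired = TRUE)
      test$statistic <- unname(tt$statistic)
      test$p_value <- tt$p.value
    }
  }
  structure(list(summaries = s, test = test), class = "tma_strat")
}

#' @export
print.tma_strat <- function(x, ...) {
  t <- x$test
  cat(sprintf("miR-21 stratification at cutoff %s: %d high / %d low cores\n",
              format(t$cutoff), t$n_high, t$n_low))
  if (t$status == "ok")
    cat(sprintf("  CDK2AP1 %s vs %s (%s t: %.2f, p = %.3g)\n",
                format(t$mean_cdk2ap1_high, digits = 4),
                format(t$mean_cdk2ap1_low, digits = 4),
                t$method, t$statistic, t$p_value))
  else cat("  ", t$status, "\n")
  invisible(x)
}

#' Digital reconstruction of TMA cells
#'
#' Scatter of cells at their (x, y) centroids. With `channel = NULL` the
#' compartment is rendered (tumor red, stroma gray); otherwise cells are
#' colored by the (optionally log2-normalized) median intensity of the
#' requested channel.
#'
#' @param cells Cell data frame (one or more cores).
#' @param channel `NULL` for the compartment view, or a channel stem such
#'   as `"mir21_cyto"` / full column name `"mir21_cyto_median"`.
#' @param log2 Log2-normalize the intensity color scale (default TRUE).
#' @param file Optional output path (`.png`, `.pdf`, `.svg`); written via
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly if `file` is given.
#' @export
reconstruct <- function(cells, channel = NULL, log2 = TRUE, file = NULL) {
  if (!is.null(channel)) {
    col <- if (channel %in% names(cells)) channel else paste0(channel, "_median")
    if (!col %in% names(cells) || is_truth_col(col)) {
      opts <- grep("_median$", names(cells), value = TRUE)
      stop_oncomir("unknown channel '", channel, "'; available: ",
                   paste(sub("_median$", "", opts[!is_truth_col(opts)]),
                         collapse = ", "))
    }
    v <- cells[[col]]
    if (log2) v <- base::log2(v + 1)
    p <- ggplot2::ggplot(cells, ggplot2::aes(x = x, y = y)) +
      ggplot2::geom_point(ggplot2::aes(colour = v), size = 0.3) +
      ggplot2::scale_colour_viridis_c(
        name = paste0(if (log2) "log2 " else "", sub("_median$", "", col))) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  } else {
    p <- ggplot2::ggplot(cells, ggplot2::aes(x = x, y = y)) +
      ggplot2::geom_point(ggplot2::aes(colour = compartment),
                          size = 0.3) +
      ggplot2::scale_colour_manual(values = c(tumor = "red3",
                                              stroma = "grey60")) +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 6, dpi = 150)
    return(invisible(p))
  }
  p
}
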