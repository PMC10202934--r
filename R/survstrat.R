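#' Classify tumors by their fraction of CDK2AP1-negative cells
#'
#' Immunohistochemistry-based dichotomization: a tumor with at least
#' `threshold` (default 45%) of its cancer cells negative for CDK2AP1 is
#' `low_neg`, otherwise `positive`. The boundary is inclusive by default
#' (a tumor exactly at 45% is `low_neg`); `inclusive = FALSE` switches to
#' a strict cut.
#'
#' @param frac_negative Proportion(s) of CDK2AP1-negative tumor cells in
#'   \[0, 1\].
#' @param threshold Classification threshold (default 0.45).
#' @param inclusive Count the boundary as `low_neg` (default TRUE).
#' @return Character vector in `positive`/`low_neg`.
#' @examples
#' ihc_classify(c(0.44, 0.45, 0.46))
#' @export
ihc_classify <- function(frac_negative, threshold = 0.45, inclusive = TRUE) {
  if (any(frac_negative < 0 | frac_negative > 1, na.rm = TRUE))
    stop_oncomir("`frac_negative` must lie in [0, 1]")
  check_proportion(threshold, "threshold")
  low <- if (inclusive) frac_negative >= threshold else
    frac_negative > threshold
  ifelse(low, "low_neg", "positive")
}

#' Kaplan-Meier curves and log-rank test for labeled patients
#'
#' Thin, validated front end to [survival::survfit()] and
#' [survival::survdiff()] on disease-free survival.
#'
#' @param patients Data frame with `dfs_time` (months) and `dfs_event`
#'   (logical or 0/1).
#' @param labels Group label per patient (any number of groups >= 2).
#' @return List of class `strat_result`: `labels`, `n` per group,
#'   `statistic` (log-rank chi-square), `df`, `p_value`, and `km`, a data
#'   frame of per-group step curves (`group`, `time`, `surv`, `n_risk`,
#'   `n_event`).
#' @examples
#' cfg <- sim_config(seed = 4, n_patients = 80)
#' pts <- gen_survival_cohort(cfg)
#' km_logrank(pts, ihc_classify(pts$frac_cdk2ap1_negative))$p_value
#' @export
km_logrank <- function(patients, labels) {
  if (length(labels) != nrow(patients))
    stop_oncomir("`labels` must have one entry per patient")
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2L)
    stop_oncomir("need at least two groups with patients")
  if (any(counts == 0L))
    stop_oncomir("group(s) with zero patients: ",
                 paste(names(counts)[counts == 0], collapse = ", "))
  if (any(patients$dfs_time < 0))
    stop_oncomir("`dfs_time` must be non-negative")
  d <- data.frame(time = patients$dfs_time,
                  event = as.integer(patients$dfs_event),
                  group = labels)
  df <- length(counts) - 1L
  if (sum(d$event) == 0L) {
    # no events: the log-rank statistic carries no information
    chisq <- 0
  } else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    chisq <- unname(sd_$chisq)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  km <- data.frame(group = strata, time = fit$time, surv = fit$surv,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   stringsAsFactors = FALSE)
  structure(list(
    labels = labels,
    n = as.integer(counts),
    groups = names(counts),
    statistic = chisq,
    df = df,
    p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
    km = km
  ), class = "strat_result")
}

#' @export
print.strat_result <- function(x, ...) {
  cat(sprintf("Log-rank over %d groups (%s): chi-square = %.3f, df = %d, p = %.4g\n",
              length(x$groups),
              paste(sprintf("%s n=%d", x$groups, x$n), collapse = ", "),
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Scan a grid of IHC thresholds for the best survival separation
#'
#' For each candidate threshold, patients are split by
#' `frac_cdk2ap1_negative >= t` and the log-rank chi-square between the
#' groups is recorded; the threshold maximizing the statistic is
#' returned together with the whole profile. Because the maximum is
#' selected post hoc, its nominal p-value is optimistic; a permutation
#' check (relabeling `frac_cdk2ap1_negative` against the survival
#' columns and re-running the scan) yields an honest p-value for the
#' maximal statistic.
#'
#' @param patients Data frame with `dfs_time`, `dfs_event`,
#'   `frac_cdk2ap1_negative`.
#' @param grid Candidate thresholds; grid points producing an empty group
#'   are skipped.
#' @param n_perm Permutation replicates for the selection-adjusted
#'   p-value (0 disables).
#' @return List of class `threshold_scan`: `threshold`, `statistic`,
#'   `p_nominal`, `p_permutation` (`NA` when disabled), `profile` data
#'   frame.
#' @export
scan_optimal_threshold <- function(patients,
                                   grid = seq(0.1, 0.9, by = 0.05),
                                   n_perm = 200L) {
  scan_once <- function(frac) {
    stat <- rep(NA_real_, length(grid))
    for (k in seq_along(grid)) {
      g <- frac >= grid[k]
      if (!any(g) || all(g)) next
      d <- data.frame(time = patients$dfs_time,
                      event = as.integer(patients$dfs_event), g = g)
      stat[k] <- survival::survdiff(
        survival::Surv(time, event) ~ g, data = d)$chisq
    }
    stat
  }
  stat <- scan_once(patients$frac_cdk2ap1_negative)
  if (all(is.na(stat)))
    stop_oncomir("every grid point produced an empty group")
  best <- which.max(stat)
  p_perm <- NA_real_
  if (n_perm > 0L) {
    obs <- stat[best]
    null_max <- vapply(seq_len(n_perm), function(b) {
      max(scan_once(sample(patients$frac_cdk2ap1_negative)), na.rm = TRUE)
    }, numeric(1))
    p_perm <- (1 + sum(null_max >= obs)) / (1 + n_perm)
  }
  message("threshold chosen by maximizing the log-rank statistic; ",
          "nominal p is optimistic, use the permutation p")
  structure(list(
    threshold = grid[best],
    statistic = stat[best],
    p_nominal = stats::pchisq(stat[best], 1, lower.tail = FALSE),
    p_permutation = p_perm,
    profile = data.frame(threshold = grid, statistic = stat)
  ), class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Best IHC threshold %.2f (log-rank chi-square %.2f, nominal p %.3g, permutation p %s)\n",
              x$threshold, x$statistic, x$p_nominal,
              format(x$p_permutation, digits = 3)))
  invisible(x)
}

#' Dichotomize patients on a marker
#'
#' Deterministic high/low labeling of a numeric marker. The median rule
#' (default; also the `quantile` rule at `q`) sends values equal to the
#' cutpoint to `low`; a `fixed` cutpoint `c` labels values above `c` as
#' `high`. A split leaving either group empty is an error.
#'
#' @param patients Data frame holding the marker column.
#' @param marker Column name, e.g. `"miR-21-5p"`.
#' @param rule `"median"`, `"quantile"` or `"fixed"`.
#' @param q Quantile for the quantile rule (default 0.5 = median).
#' @param cutoff Cutpoint for the fixed rule.
#' @return Character vector `"high"`/`"low"` per patient.
#' @examples
#' d <- data.frame(m = c(1, 2, 3, 4))
#' dichotomize(d, "m")  # low low high high
#' @export
dichotomize <- function(patients, marker,
                        rule = c("median", "quantile", "fixed"),
                        q = 0.5, cutoff = NULL) {
  rule <- match.arg(rule)
  if (!marker %in% names(patients))
    stop_oncomir("marker column '", marker, "' not found")
  v <- patients[[marker]]
  if (length(unique(v)) < 2L)
    stop_oncomir("all '", marker, "' values identical; no split possible")
  cut <- switch(rule,
    median = stats::median(v),
    quantile = stats::quantile(v, q, names = FALSE),
    fixed = {
      if (is.null(cutoff)) stop_oncomir("fixed rule requires `cutoff`")
      cutoff
    })
  labels <- ifelse(v > cut, "high", "low")
  if (length(unique(labels)) < 2L)
    stop_oncomir("cutpoint ", format(cut), " leaves a group empty for '",
                 marker, "'; no split possible")
  labels
}

#' Four-group survival stratification on two markers
#'
#' Dichotomizes two markers (see [dichotomize()]) and crosses the labels
#' into `high/high`, `high/low`, `low/high`, `low/low`. Reports the
#' overall log-rank across the populated groups and the pairwise
#' contrast of `high/high` against all remaining patients, plus the
#' per-group Kaplan-Meier curves. An empty joint group is tolerated: it
#' is dropped from the overall test and flagged in `status`.
#'
#' @inheritParams dichotomize
#' @param marker_a,marker_b Marker column names.
#' @return List of class `two_marker_strat`: `groups` per patient,
#'   `overall` (`strat_result`), `contrast` (`strat_result` for
#'   high/high vs rest, or `NULL`), `status`.
#' @export
stratify_two_markers <- function(patients, marker_a, marker_b,
                                 rule = c("median", "quantile", "fixed"),
                                 q = 0.5, cutoff = NULL) {
  rule <- match.arg(rule)
  la <- dichotomize(patients, marker_a, rule, q, cutoff)
  lb <- dichotomize(patients, marker_b, rule, q, cutoff)
  groups <- paste(la, lb, sep = "/")
  all_groups <- c("high/high", "high/low", "low/high", "low/low")
  empty <- setdiff(all_groups, unique(groups))
  status <- if (length(empty))
    paste0("empty group(s) dropped: ", paste(empty, collapse = ", "))
  else "ok"
  overall <- if (length(unique(groups)) >= 2L)
    km_logrank(patients, groups) else NULL
  contrast <- if (any(groups == "high/high") && any(groups != "high/high"))
    km_logrank(patients,
               ifelse(groups == "high/high", "high/high", "rest"))
  else NULL
  if (is.null(contrast))
    status <- paste(status, "high/high contrast skipped", sep = "; ")
  structure(list(groups = groups, overall = overall, contrast = contrast,
                 status = status),
            class = "two_marker_strat")
}

#' @export
print.two_marker_strat <- function(x, ...) {
  cat("Two-marker stratification (", x$status, ")\n", sep = "")
  if (!is.null(x$overall)) { cat("overall: "); print(x$overall) }
  if (!is.null(x$contrast)) { cat("high/high vs rest: "); print(x$contrast) }
  invisible(x)
}
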