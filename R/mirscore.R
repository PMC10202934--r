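#' Expression-quantile group score of a miRNA
#'
#' Bins a miR's mean expression into the empirical quartiles of the
#' cohort of per-miR means: 0 for the first quartile, 1 between the first
#' and second, 2 between the second and third, 3 above the third.
#' Quartile boundaries use linear-interpolation empirical quantiles
#' (R type 7); a value exactly on a boundary falls in the lower group, so
#' a degenerate all-ties cohort scores 0 everywhere.
#'
#' @param mean_value Mean expression of the miR being scored.
#' @param all_means Numeric vector of the per-miR means defining the
#'   cohort distribution (should contain `mean_value`).
#' @return Integer score in 0..3 (vectorized over `mean_value`).
#' @examples
#' quantile_group_score(5, 1:8)  # 2: between the second and third quartile
#' @export
quantile_group_score <- function(mean_value, all_means) {
  if (length(all_means) == 0L || all(is.na(all_means)))
    stop_oncomir("`all_means` must be a non-empty numeric vector")
  q <- stats::quantile(all_means, probs = c(0.25, 0.5, 0.75),
                       na.rm = TRUE, names = FALSE, type = 7)
  vapply(mean_value, function(v) sum(v > q), numeric(1))
}

#' Interaction-evidence tier score of a miRNA-target pair
#'
#' Three-tier ranking of the evidence that a miR targets a transcript:
#' tier 1 when the pair is neither experimentally validated nor predicted
#' by at least `min_algorithms` of the 12 prediction programs; tier 5
#' when it is both; tier 3 otherwise (exactly one kind of support). The
#' odd-step mapping \{1, 3, 5\} combined with the 0-3 expression group
#' spans the combined score range 1-8.
#'
#' @param validated Logical; is the interaction experimentally validated
#'   in at least one curated database?
#' @param n_algorithms Integer count of predicting algorithms, 0-12.
#' @param min_algorithms Prediction-support cutoff (default 6).
#' @param tier_values Length-3 increasing numeric mapping for the three
#'   tiers.
#' @return Tier score (vectorized over `validated`/`n_algorithms`).
#' @examples
#' evidence_tier_score(FALSE, 3)   # 1
#' evidence_tier_score(TRUE, 0)    # 3
#' evidence_tier_score(TRUE, 10)   # 5
#' @export
evidence_tier_score <- function(validated, n_algorithms,
                                min_algorithms = 6L,
                                tier_values = c(1L, 3L, 5L)) {
  if (length(tier_values) != 3L || is.unsorted(tier_values))
    stop_oncomir("`tier_values` must be 3 increasing numbers")
  if (any(is.na(n_algorithms)) ||
      any(n_algorithms < 0L) || any(n_algorithms > 12L))
    stop_oncomir("`n_algorithms` must lie in [0, 12]")
  predicted <- n_algorithms >= min_algorithms
  tier_values[1L + as.integer(validated) + as.integer(predicted)]
}

#' Combined miRNA priority score and candidate selection
#'
#' Sums the expression-quantile group score (0-3) with the
#' interaction-evidence tier (1/3/5) for every miR of an expression
#' matrix, giving a combined score in 1-8, and selects miRs whose score
#' meets `threshold` (default >= 7: validated, widely predicted, and
#' expressed in the upper half of the cohort).
#'
#' Per-miR means are taken across the CDK2AP1-deficient samples by
#' default (`expr_samples = "deficient"`), since the screen profiles
#' deficient lines; `"all"` uses every sample. miRs without an evidence
#' record fall to tier 1 with a warning.
#'
#' @param x A `mir_expr` object (see [gen_expression_matrix()]) or a
#'   numeric matrix with `groups` supplied.
#' @param evidence Data frame with columns `mir_id`, `validated`,
#'   `n_predicting_algorithms` (at most one row per miR).
#' @param threshold Selection cutoff in 1..8.
#' @param expr_samples `"deficient"` or `"all"`.
#' @param groups Sample group labels, required when `x` is a bare matrix.
#' @param min_algorithms,tier_values Passed to [evidence_tier_score()].
#' @return Data frame of class `mir_score_table`, one row per miR:
#'   `mir_id`, `mean_expr`, `expr_group`, `evidence_tier`, `combined`,
#'   `selected`; sorted by `combined` descending with ties broken by
#'   `mir_id`.
#' @examples
#' cfg <- sim_config(seed = 2, n_mirs = 30)
#' scores <- combine_and_select(gen_expression_matrix(cfg),
#'                              gen_evidence_table(cfg))
#' head(scores)
#' @export
combine_and_select <- function(x, evidence, threshold = 7L,
                               expr_samples = c("deficient", "all"),
                               groups = NULL,
                               min_algorithms = 6L,
                               tier_values = c(1L, 3L, 5L)) {
  expr_samples <- match.arg(expr_samples)
  if (threshold < 1 || threshold > 8)
    stop_oncomir("`threshold` must lie in [1, 8]")
  if (inherits(x, "mir_expr")) {
    values <- x$values
    groups <- x$groups
  } else {
    values <- as.matrix(x)
    if (is.null(groups)) stop_oncomir("`groups` required for a bare matrix")
  }
  if (anyDuplicated(evidence$mir_id))
    stop_oncomir("`evidence` has more than one row for some miR")
  if (nrow(values) == 0L) {
    out <- data.frame(mir_id = character(0), mean_expr = numeric(0),
                      expr_group = integer(0), evidence_tier = integer(0),
                      combined = integer(0), selected = logical(0))
    class(out) <- c("mir_score_table", class(out))
    return(out)
  }
  cols <- if (expr_samples == "deficient") groups == "deficient" else
    rep(TRUE, ncol(values))
  if (!any(cols)) stop_oncomir("no samples in the requested group")
  means <- rowMeans(values[, cols, drop = FALSE])
  expr_group <- quantile_group_score(means, means)

  m <- match(rownames(values), evidence$mir_id)
  if (anyNA(m))
    warning(sum(is.na(m)), " miR(s) lack an evidence record; assigned tier ",
            tier_values[1], call. = FALSE)
  validated <- ifelse(is.na(m), FALSE, evidence$validated[m])
  n_alg <- ifelse(is.na(m), 0L, evidence$n_predicting_algorithms[m])
  tier <- evidence_tier_score(validated, n_alg, min_algorithms, tier_values)

  out <- data.frame(
    mir_id = rownames(values),
    mean_expr = unname(means),
    expr_group = as.integer(expr_group),
    evidence_tier = tier,
    combined = as.integer(expr_group + tier),
    stringsAsFactors = FALSE
  )
  out$selected <- out$combined >= threshold
  out <- out[order(-out$combined, out$mir_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mir_score_table", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.mir_score_table <- function(x, ...) {
  cat(sprintf("miRNA priority scores: %d miRs, %d selected at combined >= %s\n",
              nrow(x), sum(x$selected), format(attr(x, "threshold"))))
  NextMethod()
}
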