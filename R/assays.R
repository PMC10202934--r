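#' Relative expression from qPCR Ct values
#'
#' Implements the standard 2^-dCt / 2^-ddCt quantification. In `"dct"`
#' mode each row yields `2^-(ct_target - ct_reference)` (reference gene:
#' GAPDH for mRNA, U6 snRNA for miRs). In `"ddct"` mode the per-sample
#' delta-Ct is referenced to a calibrator sample per target, giving the
#' fold change `2^-ddCt`; the calibrator's own fold change is exactly 1.
#'
#' @param records Data frame with columns `sample_id`, `target_id`,
#'   `ct_target`, `ct_reference` (positive, finite cycles). Replicate
#'   calibrator rows are averaged on the delta-Ct scale.
#' @param mode `"ddct"` (default) or `"dct"`.
#' @param calibrator Sample id of the calibrator (required for
#'   `"ddct"`).
#' @return `records` with added columns `delta_ct`, and for ddct mode
#'   `delta_delta_ct` and `fold_change`; dct mode adds `rel_expr`.
#' @examples
#' qpcr <- data.frame(sample_id = c("mock", "treated"), target_id = "miR-21-5p",
#'                    ct_target = c(24, 25), ct_reference = c(20, 20))
#' fold_change(qpcr, calibrator = "mock")$fold_change  # 1.0, 0.5
#' @export
fold_change <- function(records, mode = c("ddct", "dct"), calibrator = NULL) {
  mode <- match.arg(mode)
  need <- c("sample_id", "target_id", "ct_target", "ct_reference")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_oncomir("`records` lacks columns: ", paste(miss, collapse = ", "))
  ct <- c(records$ct_target, records$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop_oncomir("Ct values must be positive and finite")
  records$delta_ct <- records$ct_target - records$ct_reference
  if (mode == "dct") {
    records$rel_expr <- 2^(-records$delta_ct)
    return(records)
  }
  if (is.null(calibrator))
    stop_oncomir("ddct mode requires a `calibrator` sample id")
  cal <- records[records$sample_id == calibrator, , drop = FALSE]
  if (nrow(cal) == 0L)
    stop_oncomir("calibrator sample '", calibrator, "' not present in `records`")
  cal_dct <- tapply(cal$delta_ct, cal$target_id, mean)
  ref <- cal_dct[records$target_id]
  if (anyNA(ref))
    stop_oncomir("calibrator lacks measurements for target(s): ",
                 paste(unique(records$target_id[is.na(ref)]), collapse = ", "))
  records$delta_delta_ct <- as.vector(records$delta_ct - unname(ref))
  records$fold_change <- 2^(-records$delta_delta_ct)
  records
}

#' Per-condition relative luciferase activity
#'
#' Each well's firefly counts are normalized to its renilla counts; well
#' ratios are then normalized to the mean mock-well ratio of the same
#' plate (transfection batches differ, so mock normalization is
#' per-plate). Per condition the function reports the mean relative
#' activity, its standard error, and the well count. The mock condition
#' is exactly 1 by construction.
#'
#' @param wells Data frame with columns `plate_id`, `condition`,
#'   `firefly`, `renilla` (renilla > 0). The mock condition must be
#'   present on every plate.
#' @param mock Label of the mock/empty-vector condition.
#' @return Data frame with `condition`, `activity`, `sem`, `n_wells`,
#'   plus the per-well normalized ratios in attribute `wells`.
#' @export
normalize_luciferase <- function(wells, mock = "mock") {
  need <- c("plate_id", "condition", "firefly", "renilla")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop_oncomir("`wells` lacks columns: ", paste(miss, collapse = ", "))
  if (any(wells$renilla <= 0))
    stop_oncomir("renilla counts must be positive")
  ratio <- wells$firefly / wells$renilla
  mock_mean <- tapply(ratio[wells$condition == mock],
                      wells$plate_id[wells$condition == mock], mean)
  plates <- unique(wells$plate_id)
  no_mock <- setdiff(plates, names(mock_mean))
  if (length(no_mock))
    stop_oncomir("plate(s) without mock wells: ",
                 paste(no_mock, collapse = ", "))
  wells$rel_activity <- ratio / unname(mock_mean[as.character(wells$plate_id)])
  agg <- do.call(rbind, lapply(split(wells$rel_activity, wells$condition),
                               function(v) {
    data.frame(activity = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_wells = length(v))
  }))
  out <- data.frame(condition = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$condition != mock, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "wells") <- wells
  out
}

#' Coefficient of Drug Interaction for a miR/drug combination
#'
#' Quantifies cooperativity between two treatments on a shared readout
#' (here: relative luciferase activity of a 3'-UTR reporter). The
#' default follows the average convention, `CDI = combo / ((a + b) / 2)`;
#' the conventional product form `CDI = combo / (a * b)` is available via
#' `method = "product"` for comparison. For an inhibitory readout a CDI
#' below the lower threshold indicates synergy, above the upper threshold
#' antagonism, and in between an additive-like interaction. The 0.9/1.1
#' defaults are a reporting convention, not a universal constant; the raw
#' CDI is always returned.
#'
#' @param combo_activity Readout of the combination treatment (> 0).
#' @param activity_a,activity_b Readouts of the single treatments (> 0).
#' @param thresholds Length-2 increasing pair (synergy, antagonism).
#' @param method `"average"` (default) or `"product"`.
#' @param label Optional combination label.
#' @return Data frame of class `cdi_result` with `combination`, `cdi`,
#'   `classification`.
#' @examples
#' cdi(0.25, 0.25, 0.45)  # 0.714..., synergistic at default thresholds
#' @export
cdi <- function(combo_activity, activity_a, activity_b,
                thresholds = c(0.9, 1.1),
                method = c("average", "product"),
                label = NULL) {
  method <- match.arg(method)
  acts <- c(combo_activity, activity_a, activity_b)
  if (any(!is.finite(acts)) || any(acts <= 0))
    stop_oncomir("all activities must be positive and finite")
  if (length(thresholds) != 2L || thresholds[1] >= thresholds[2])
    stop_oncomir("`thresholds` must be an increasing pair")
  value <- switch(method,
    average = combo_activity / ((activity_a + activity_b) / 2),
    product = combo_activity / (activity_a * activity_b)
  )
  classification <- ifelse(value < thresholds[1], "synergistic",
                    ifelse(value > thresholds[2], "antagonistic",
                           "additive-like"))
  out <- data.frame(
    combination = if (is.null(label)) NA_character_ else label,
    cdi = value,
    classification = classification,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cdi_result", class(out))
  out
}

#' CDI table for every combination condition on a normalized plate
#'
#' Convenience wrapper: given per-condition activities (output of
#' [normalize_luciferase()]) and combination conditions named
#' `"a+b"` after their constituent single conditions, computes the CDI of
#' every combination.
#'
#' @param activities Output of [normalize_luciferase()].
#' @param sep Separator splitting a combination label into its singles.
#' @inheritParams cdi
#' @return A `cdi_result` data frame, one row per combination condition.
#' @export
cdi_table <- function(activities, sep = "+", thresholds = c(0.9, 1.1),
                      method = c("average", "product")) {
  method <- match.arg(method)
  act <- stats::setNames(activities$activity, activities$condition)
  combos <- grep(sep, activities$condition, fixed = TRUE, value = TRUE)
  rows <- lapply(combos, function(cc) {
    parts <- strsplit(cc, sep, fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% names(act)))
      stop_oncomir("combination '", cc,
                   "' does not resolve to two measured single conditions")
    cdi(act[[cc]], act[[parts[1]]], act[[parts[2]]],
        thresholds = thresholds, method = method, label = cc)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- structure(data.frame(combination = character(0), cdi = numeric(0),
                                classification = character(0)),
                     class = c("cdi_result", "data.frame"))
  out
}
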