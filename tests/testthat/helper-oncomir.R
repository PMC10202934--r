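# Small configurations and toy fixtures shared across test files.

tiny_cfg <- function(seed = 1, cells_per_core_range = c(60L, 80L), ...) {
  sim_config(seed = seed, n_patients = 4, cores_per_patient = 2,
             cells_per_core_range = cells_per_core_range, n_mirs = 30, ...)
}

# Minimal cell table with explicit median intensities; enough columns for
# merge_and_filter / summarize_cores / compare_compartments.
toy_cells <- function(mir21, cdk2ap1, core_id = "core-1",
                      patient_id = "pt-1", compartment = "tumor",
                      excluded = FALSE) {
  n <- length(mir21)
  data.frame(
    core_id = rep_len(core_id, n),
    patient_id = rep_len(patient_id, n),
    x = seq_len(n), y = seq_len(n),
    compartment = rep_len(compartment, n),
    mir21_cyto_median = mir21,
    cdk2ap1_nuc_median = cdk2ap1,
    excluded = rep_len(excluded, n),
    stringsAsFactors = FALSE
  )
}

# Minimal core-summary table for stratify_and_test / rank_cores.
toy_summaries <- function(mir21_tumor, cdk2ap1_tumor = NULL,
                          pearson_r = NULL, included = TRUE,
                          patient_id = NULL) {
  n <- length(mir21_tumor)
  data.frame(
    core_id = sprintf("core-%02d", seq_len(n)),
    patient_id = if (is.null(patient_id)) sprintf("pt-%02d", seq_len(n))
                 else rep_len(patient_id, n),
    n_tumor_cells = 600L,
    n_stroma_cells = 300L,
    mir21_tumor = mir21_tumor,
    cdk2ap1_tumor = if (is.null(cdk2ap1_tumor)) rep(100, n) else cdk2ap1_tumor,
    pearson_r = if (is.null(pearson_r)) rep(0, n) else pearson_r,
    included = rep_len(included, n),
    stringsAsFactors = FALSE
  )
}

# Independent type-7 (linear interpolation) quantile, used as an oracle.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}
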