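#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every parameter used by the `gen_*` generators into a single
#' validated object. The defaults mirror the study design the package
#' models: a tissue-microarray cohort of 144 patients sampled at 3 cores
#' each (432 cores), a 7-cell-line expression screen with 4
#' CDK2AP1-deficient and 3 proficient lines, stroma-elevated miR-21, an
#' anti-correlation of -0.6 between tumor-cell cytoplasmic miR-21 and
#' nuclear CDK2AP1, and reporter knockdown activities spanning 0.25-0.58
#' of mock.
#'
#' Identical configurations (including `seed`) yield byte-identical
#' generator outputs; the global RNG state is left untouched.
#'
#' @param seed Integer root seed; every generator derives its own stream
#'   from it.
#' @param n_patients Number of patients in the TMA/survival cohorts.
#' @param cores_per_patient TMA cores sampled per patient (>= 1).
#' @param cells_per_core_range Length-2 integer vector; cells per core are
#'   drawn uniformly from this range.
#' @param tumor_fraction Proportion of cells per core in the tumor
#'   compartment, strictly inside (0, 1).
#' @param target_pearson_r Target Pearson correlation (raw intensity
#'   scale) between tumor-cell cytoplasmic miR-21 and nuclear CDK2AP1
#'   medians, in \[-1, 1\].
#' @param stroma_mir21_shift Multiplicative elevation (>= 1) of stromal
#'   miR-21 relative to tumor cells of the same core.
#' @param outlier_fraction Proportion of cells displaced as planted
#'   staining artifacts.
#' @param outlier_magnitude_sd Displacement magnitude in channel standard
#'   deviations (>= 8 so a z > 3 filter captures essentially all of them).
#' @param core_log_sd,cell_log_sd Log-scale standard deviations of the
#'   between-core and within-core intensity variation.
#' @param mir_effects Named vector of expected relative reporter
#'   activities in (0, 1\]; must contain `mock = 1`.
#' @param luc_replicates Wells per condition per plate.
#' @param luc_cv Multiplicative coefficient of variation of the luciferase
#'   counts.
#' @param hazard_ratios Named positive vector of group hazard ratios for
#'   the survival generator.
#' @param censoring_rate Expected proportion of censored patients.
#' @param baseline_median_dfs Median disease-free survival (months) of the
#'   baseline hazard group.
#' @param n_mirs Number of miRNAs on the synthetic array.
#' @param n_samples Named integer vector `c(deficient = , proficient = )`
#'   of samples per expression group.
#' @param upregulated_set miR identifiers planted as upregulated in the
#'   deficient group; defaults to the first 12 miRs.
#' @param effect_size Planted deficient-minus-proficient log-scale group
#'   mean difference for the upregulated set.
#' @param tier_proportions Length-3 proportions (summing to 1) of evidence
#'   records in the three interaction-evidence classes.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7, n_patients = 4, cores_per_patient = 2,
#'                   cells_per_core_range = c(50, 60))
#' cells <- gen_tma_cohort(cfg)
#' length(unique(cells$core_id))
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 144L,
                       cores_per_patient = 3L,
                       cells_per_core_range = c(800L, 1100L),
                       tumor_fraction = 0.65,
                       target_pearson_r = -0.6,
                       stroma_mir21_shift = 2.0,
                       outlier_fraction = 0.03,
                       outlier_magnitude_sd = 8,
                       core_log_sd = 0.08,
                       cell_log_sd = 0.08,
                       mir_effects = c(mock = 1,
                                       "miR-21-5p"  = 0.25,
                                       "miR-23b-3p" = 0.45,
                                       "miR-26b-5p" = 0.50,
                                       "miR-93-5p"  = 0.40,
                                       "miR-155-5p" = 0.58),
                       luc_replicates = 3L,
                       luc_cv = 0.05,
                       hazard_ratios = c(positive = 1, low_neg = 2.5),
                       censoring_rate = 0.3,
                       baseline_median_dfs = 36,
                       n_mirs = 100L,
                       n_samples = c(deficient = 4L, proficient = 3L),
                       upregulated_set = NULL,
                       effect_size = 2.0,
                       tier_proportions = c(0.5, 0.3, 0.2)) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    cores_per_patient = as.integer(cores_per_patient),
    cells_per_core_range = as.integer(cells_per_core_range),
    tumor_fraction = tumor_fraction,
    target_pearson_r = target_pearson_r,
    stroma_mir21_shift = stroma_mir21_shift,
    outlier_fraction = outlier_fraction,
    outlier_magnitude_sd = outlier_magnitude_sd,
    core_log_sd = core_log_sd,
    cell_log_sd = cell_log_sd,
    mir_effects = mir_effects,
    luc_replicates = as.integer(luc_replicates),
    luc_cv = luc_cv,
    hazard_ratios = hazard_ratios,
    censoring_rate = censoring_rate,
    baseline_median_dfs = baseline_median_dfs,
    n_mirs = as.integer(n_mirs),
    n_samples = n_samples,
    upregulated_set = upregulated_set,
    effect_size = effect_size,
    tier_proportions = tier_proportions
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$seed)) stop_oncomir("`seed` must be a finite integer")
  if (cfg$n_patients < 1L) stop_oncomir("`n_patients` must be >= 1")
  if (cfg$cores_per_patient < 1L)
    stop_oncomir("`cores_per_patient` must be >= 1")
  if (length(cfg$cells_per_core_range) != 2L ||
      any(cfg$cells_per_core_range < 1L) ||
      cfg$cells_per_core_range[1] > cfg$cells_per_core_range[2])
    stop_oncomir("`cells_per_core_range` must be an increasing pair of positive counts")
  if (cfg$tumor_fraction <= 0 || cfg$tumor_fraction >= 1)
    stop_oncomir("`tumor_fraction` must lie strictly inside (0, 1)")
  if (abs(cfg$target_pearson_r) > 1)
    stop_oncomir("`target_pearson_r` must lie in [-1, 1]")
  if (cfg$stroma_mir21_shift < 1)
    stop_oncomir("`stroma_mir21_shift` must be >= 1")
  check_proportion(cfg$outlier_fraction, "outlier_fraction")
  if (cfg$outlier_magnitude_sd < 8)
    stop_oncomir("`outlier_magnitude_sd` must be >= 8")
  if (!"mock" %in% names(cfg$mir_effects) ||
      cfg$mir_effects[["mock"]] != 1)
    stop_oncomir("`mir_effects` must contain the mock condition with expected activity 1.0")
  if (any(cfg$mir_effects <= 0) || any(cfg$mir_effects > 1))
    stop_oncomir("all `mir_effects` must lie in (0, 1]")
  if (cfg$luc_replicates < 1L) stop_oncomir("`luc_replicates` must be >= 1")
  if (is.null(names(cfg$hazard_ratios)) || any(cfg$hazard_ratios <= 0))
    stop_oncomir("`hazard_ratios` must be a named vector of positive numbers")
  check_proportion(cfg$censoring_rate, "censoring_rate")
  if (cfg$n_mirs < 0L) stop_oncomir("`n_mirs` must be >= 0")
  if (any(cfg$tier_proportions < 0))
    stop_oncomir("`tier_proportions` must be non-negative")
  if (abs(sum(cfg$tier_proportions) - 1) > 1e-8)
    stop_oncomir("`tier_proportions` must sum to 1")
  if (is.null(cfg$upregulated_set))
    cfg$upregulated_set <- sim_mir_ids(cfg$n_mirs)[seq_len(min(12L, cfg$n_mirs))]
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat(sprintf("  TMA: %d patients x %d cores, %d-%d cells/core, tumor fraction %.2f\n",
              x$n_patients, x$cores_per_patient,
              x$cells_per_core_range[1], x$cells_per_core_range[2],
              x$tumor_fraction))
  cat(sprintf("  target Pearson r (tumor miR-21 vs CDK2AP1): %.2f\n",
              x$target_pearson_r))
  cat(sprintf("  expression: %d miRs, %s samples, effect size %.1f\n",
              x$n_mirs,
              paste(sprintf("%d %s", x$n_samples, names(x$n_samples)),
                    collapse = " + "),
              x$effect_size))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override the [sim_config()] defaults; unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file whose keys match [sim_config()]
#'   arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(sim_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop_oncomir("unknown sim_config keys in ", path, ": ",
                 paste(bad, collapse = ", "))
  for (nm in c("mir_effects", "hazard_ratios", "n_samples"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}

sim_mir_ids <- function(n) {
  if (n == 0L) return(character(0))
  sprintf("miR-sim-%03d", seq_len(n))
}

# Seed offsets keep the generator streams independent of one another
# while remaining a pure function of the root seed.
stage_seed <- function(cfg, stage) {
  offsets <- c(expression = 101L, evidence = 202L, luciferase = 303L,
               tma = 404L, survival = 505L, variants = 606L,
               qpcr = 707L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}
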