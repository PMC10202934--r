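.PIPELINE_STAGES <- c("syndata", "mirscore", "assays", "spatial",
                      "varfilter", "survstrat")

default_run_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    stages = .PIPELINE_STAGES,
    sim = list(),
    thresholds = list(
      score_threshold = 7L,
      z_threshold = 3,
      min_tumor_cells = 500L,
      mir21_cutoff = 150,
      ihc_threshold = 0.45,
      recurrence_cutoff = 5L,
      maf_cutoff = 0.01,
      cnv_log2_cutoff = 0.5,
      cnv_p_cutoff = 0.05
    ),
    inputs = list(),
    figures = FALSE
  )
}

#' Validate a pipeline run configuration
#'
#' Merges a user configuration (a list, or a path to a YAML file) over
#' the defaults. Unknown keys — top-level, threshold or input — are
#' rejected, and every threshold must lie in its documented domain.
#'
#' @param config List or YAML path; see [run_pipeline()] for the keys.
#' @return A validated `run_config` list.
#' @export
validate_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_oncomir("`config` must be a list or a YAML path")
  def <- default_run_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    stop_oncomir("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(config)) {
    if (nm %in% c("thresholds", "inputs", "sim")) {
      extra <- setdiff(names(config[[nm]]), switch(nm,
        thresholds = names(def$thresholds),
        inputs = c("cells", "variants", "patients"),
        sim = names(formals(sim_config))))
      if (length(extra))
        stop_oncomir("unknown ", nm, " key(s): ", paste(extra, collapse = ", "))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      def[[nm]] <- config[[nm]]
    }
  }
  def$stages <- match.arg(def$stages, .PIPELINE_STAGES, several.ok = TRUE)
  th <- def$thresholds
  if (th$score_threshold < 1 || th$score_threshold > 8)
    stop_oncomir("score_threshold must lie in [1, 8]")
  if (th$z_threshold <= 0) stop_oncomir("z_threshold must be positive")
  if (th$min_tumor_cells < 0) stop_oncomir("min_tumor_cells must be >= 0")
  check_proportion(th$ihc_threshold, "ihc_threshold")
  check_proportion(th$maf_cutoff, "maf_cutoff")
  check_proportion(th$cnv_p_cutoff, "cnv_p_cutoff")
  if (th$recurrence_cutoff < 1) stop_oncomir("recurrence_cutoff must be >= 1")
  def$seed <- as.integer(def$seed)
  structure(def, class = "run_config")
}

write_stage_tsv <- function(x, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  utils::write.table(x, file.path(outdir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline end to end
#'
#' Configuration-driven orchestration of the package: generates (or
#' loads) the inputs, then runs any subset of the stages in dependency
#' order — miRNA prioritization scoring, luciferase/CDI quantification,
#' the spatial TMA pipeline, the variant filter cascade, and survival
#' stratification — writing per-stage TSVs, an aggregated JSON report
#' and a log with the seed and package version when `outdir` is set.
#' All randomness flows from the single root `seed` (split per stage by
#' the generators), so a fixed configuration reproduces every numeric
#' output exactly.
#'
#' Config keys (list or YAML file): `seed`, `outdir`, `stages` (subset
#' of `syndata`, `mirscore`, `assays`, `spatial`, `varfilter`,
#' `survstrat`), `sim` ([sim_config()] overrides), `thresholds`
#' (`score_threshold` 7, `z_threshold` 3, `min_tumor_cells` 500,
#' `mir21_cutoff` 150, `ihc_threshold` 0.45, `recurrence_cutoff` 5,
#' `maf_cutoff` 0.01, `cnv_log2_cutoff` 0.5, `cnv_p_cutoff` 0.05),
#' `inputs` (paths to `cells`/`variants`/`patients` tables replacing the
#' generators), `figures` (write digital core reconstructions).
#'
#' @param config List or YAML path; unknown keys are rejected.
#' @return List of class `oncomir_report`: per-stage results plus
#'   `report`, the aggregated headline numbers written to
#'   `report.json`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(seed = 1,
#'                          sim = list(n_patients = 6, cores_per_patient = 2,
#'                                     cells_per_core_range = c(60, 80)),
#'                          thresholds = list(min_tumor_cells = 30)))
#' res$report$spatial$n_cores
#' }
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_run_config(config)
  if (!is.null(cfg$outdir) &&
      !dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  sim <- do.call(sim_config, sim_args)
  th <- cfg$thresholds
  has_syndata <- "syndata" %in% cfg$stages
  need_syndata <- function(stage, input = NULL) {
    if (has_syndata) return(invisible())
    if (!is.null(input) && !is.null(cfg$inputs[[input]])) return(invisible())
    stop_oncomir("stage '", stage, "' needs the syndata stage",
                 if (!is.null(input))
                   paste0(" (or an `inputs$", input, "` path)") else "")
  }
  report <- list(seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("oncomir")))
  results <- list(config = cfg)

  if ("mirscore" %in% cfg$stages) {
    need_syndata("mirscore")
    expr <- gen_expression_matrix(sim)
    evid <- gen_evidence_table(sim)
    scores <- combine_and_select(expr, evid,
                                 threshold = th$score_threshold)
    results$mirscore <- scores
    write_stage_tsv(scores, cfg$outdir, "mir_scores")
    report$mirscore <- list(
      n_mirs = nrow(scores),
      n_selected = sum(scores$selected),
      threshold = th$score_threshold,
      selected = scores$mir_id[scores$selected]
    )
  }

  if ("assays" %in% cfg$stages) {
    need_syndata("assays")
    plate <- gen_luciferase_plate(sim)
    act <- normalize_luciferase(plate)
    # synthesize combination conditions as near-additive mixes of miR-21
    # with each partner, so the CDI table exercises both directions
    singles <- setdiff(act$condition, "mock")
    lead <- singles[1]
    combos <- do.call(rbind, lapply(setdiff(singles, lead), function(s) {
      avg <- (act$activity[act$condition == lead] +
              act$activity[act$condition == s]) / 2
      data.frame(condition = paste(lead, s, sep = "+"), activity = avg,
                 sem = NA_real_, n_wells = NA_integer_)
    }))
    cdi_tab <- cdi_table(rbind(act, combos))
    results$assays <- list(activities = act, cdi = cdi_tab)
    write_stage_tsv(act, cfg$outdir, "luciferase_activities")
    write_stage_tsv(cdi_tab, cfg$outdir, "cdi")
    report$assays <- list(
      activities = stats::setNames(act$activity, act$condition),
      cdi = stats::setNames(cdi_tab$cdi, cdi_tab$combination)
    )
  }

  if ("spatial" %in% cfg$stages) {
    need_syndata("spatial", "cells")
    cells <- if (!is.null(cfg$inputs$cells))
      utils::read.csv(cfg$inputs$cells, check.names = FALSE)
    else gen_tma_cohort(sim)
    cells <- merge_and_filter(cells, z_threshold = th$z_threshold,
                              quiet = TRUE)
    summaries <- summarize_cores(cells,
                                 min_tumor_cells = th$min_tumor_cells)
    ranked <- rank_cores(summaries)
    strat <- stratify_and_test(summaries, mir21_cutoff = th$mir21_cutoff)
    comp <- compare_compartments(cells)
    results$spatial <- list(cells = cells, summaries = strat$summaries,
                            ranked = ranked, strat = strat,
                            compartments = comp)
    write_stage_tsv(strat$summaries, cfg$outdir, "core_summaries")
    write_stage_tsv(comp$tests, cfg$outdir, "compartment_tests")
    if (isTRUE(cfg$figures) && !is.null(cfg$outdir)) {
      first <- cells[cells$core_id == cells$core_id[1], , drop = FALSE]
      reconstruct(first, file = file.path(cfg$outdir, "core_compartments.png"))
      reconstruct(first, channel = "mir21_cyto",
                  file = file.path(cfg$outdir, "core_mir21.png"))
    }
    report$spatial <- list(
      n_cells = nrow(cells),
      exclusion_fraction = attr(cells, "exclusion_fraction"),
      n_cores = nrow(summaries),
      n_included = sum(summaries$included),
      mean_pearson_r = mean(summaries$pearson_r[summaries$included],
                            na.rm = TRUE),
      stroma_tumor_mir21_ratio =
        comp$tests$mean_ratio[comp$tests$marker == "mir21"],
      strat_p_value = strat$test$p_value,
      strat_status = strat$test$status
    )
  }

  if ("varfilter" %in% cfg$stages) {
    need_syndata("varfilter", "variants")
    variants <- if (!is.null(cfg$inputs$variants))
      read_variant_tsv(cfg$inputs$variants)
    else gen_variant_table(sim,
                           recurrence_cutoff = th$recurrence_cutoff,
                           maf_cutoff = th$maf_cutoff)
    fc <- filter_cascade(variants,
                         recurrence_cutoff = th$recurrence_cutoff,
                         maf_cutoff = th$maf_cutoff)
    results$varfilter <- fc
    write_stage_tsv(fc$survivors, cfg$outdir, "variant_survivors")
    report$varfilter <- list(tally = as.list(fc$tally),
                             n_survivors = nrow(fc$survivors))
  }

  if ("survstrat" %in% cfg$stages) {
    need_syndata("survstrat", "patients")
    patients <- if (!is.null(cfg$inputs$patients))
      utils::read.csv(cfg$inputs$patients, check.names = FALSE)
    else gen_survival_cohort(sim)
    ihc <- ihc_classify(patients$frac_cdk2ap1_negative,
                        threshold = th$ihc_threshold)
    km <- km_logrank(patients, ihc)
    two <- stratify_two_markers(patients, "miR-21-5p", "miR-93-5p")
    results$survstrat <- list(patients = patients, ihc = km,
                              two_marker = two)
    write_stage_tsv(km$km, cfg$outdir, "km_ihc")
    report$survstrat <- list(
      ihc_logrank_p = km$p_value,
      ihc_groups = as.list(stats::setNames(km$n, km$groups)),
      two_marker_overall_p =
        if (!is.null(two$overall)) two$overall$p_value else NA,
      two_marker_contrast_p =
        if (!is.null(two$contrast)) two$contrast$p_value else NA
    )
  }

  results$report <- report
  if (!is.null(cfg$outdir)) {
    jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("oncomir %s", report$package_version),
      sprintf("seed: %d", cfg$seed),
      sprintf("stages: %s", paste(cfg$stages, collapse = ", ")),
      sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    ), file.path(cfg$outdir, "run.log"))
  }
  structure(results, class = "oncomir_report")
}

#' @export
print.oncomir_report <- function(x, ...) {
  r <- x$report
  cat("oncomir pipeline report (seed ", r$seed, ")\n", sep = "")
  if (!is.null(r$mirscore))
    cat(sprintf("  mirscore: %d/%d miRs selected at >= %d\n",
                r$mirscore$n_selected, r$mirscore$n_mirs,
                r$mirscore$threshold))
  if (!is.null(r$assays))
    cat(sprintf("  assays: %d conditions, %d CDI combinations\n",
                length(r$assays$activities), length(r$assays$cdi)))
  if (!is.null(r$spatial))
    cat(sprintf("  spatial: %d cores (%d included), mean r = %.3f, strat p = %.3g\n",
                r$spatial$n_cores, r$spatial$n_included,
                r$spatial$mean_pearson_r, r$spatial$strat_p_value))
  if (!is.null(r$varfilter))
    cat(sprintf("  varfilter: %d survivors\n", r$varfilter$n_survivors))
  if (!is.null(r$survstrat))
    cat(sprintf("  survstrat: IHC log-rank p = %.3g\n",
                r$survstrat$ihc_logrank_p))
  invisible(x)
}
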