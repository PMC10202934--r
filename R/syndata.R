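#' Generate a normalized miRNA expression matrix
#'
#' Emulates a normalized (log-scale) miRNA array profiling of
#' CDK2AP1-deficient versus proficient cell lines. miRs in
#' `cfg$upregulated_set` receive a deficient-group mean elevated by
#' `cfg$effect_size`; all other variation is i.i.d. Gaussian noise on the
#' log-intensity scale.
#'
#' @param cfg A [sim_config()] object. Uses `n_mirs`, `n_samples`,
#'   `upregulated_set`, `effect_size`.
#' @return An object of class `mir_expr`: a list with `values` (numeric
#'   matrix, miRs x samples), `groups` (named character vector of sample
#'   group labels) and the planted truth in attribute-free list element
#'   `truth` (upregulated miR ids).
#' @examples
#' x <- gen_expression_matrix(sim_config(seed = 1, n_mirs = 20))
#' dim(x$values)
#' @export
gen_expression_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ns <- cfg$n_samples
  for (g in c("deficient", "proficient")) {
    if (is.na(ns[g]) || ns[g] < 1L)
      stop_oncomir("expression design has zero samples in the '", g, "' group")
  }
  if (sum(ns) < 2L) stop_oncomir("need at least 2 samples")
  mir_ids <- sim_mir_ids(cfg$n_mirs)
  sample_ids <- c(sprintf("DEF-%02d", seq_len(ns[["deficient"]])),
                  sprintf("PRO-%02d", seq_len(ns[["proficient"]])))
  groups <- stats::setNames(
    rep(c("deficient", "proficient"), times = ns[c("deficient", "proficient")]),
    sample_ids
  )
  withr::with_seed(stage_seed(cfg, "expression"), {
    base <- stats::rnorm(cfg$n_mirs, mean = 8, sd = 1)
    vals <- matrix(stats::rnorm(cfg$n_mirs * length(sample_ids), sd = 1),
                   nrow = cfg$n_mirs, ncol = length(sample_ids),
                   dimnames = list(mir_ids, sample_ids))
    vals <- vals + base
    up <- intersect(cfg$upregulated_set, mir_ids)
    vals[up, groups == "deficient"] <-
      vals[up, groups == "deficient"] + cfg$effect_size
  })
  structure(list(values = vals, groups = groups, truth = up),
            class = "mir_expr")
}

#' @export
print.mir_expr <- function(x, ...) {
  cat(sprintf("<mir_expr> %d miRs x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$groups)[unique(x$groups)],
                            unique(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Generate a miRNA-target interaction-evidence table
#'
#' Draws one evidence record per miR against the CDK2AP1 3'-UTR. Records
#' fall in three classes with proportions `cfg$tier_proportions`:
#' (1) not validated and predicted by fewer than 6 of 12 algorithms,
#' (2) validated XOR predicted by at least 6, (3) validated and predicted
#' by at least 6. The class is recorded in the hidden truth column
#' `.sim_tier_class`.
#'
#' @param cfg A [sim_config()] object.
#' @return Data frame with `mir_id`, `target_gene`, `validated_sources`
#'   (semicolon-separated database names, `""` if none), `validated`,
#'   `n_predicting_algorithms` (0-12) and `.sim_tier_class`.
#' @export
gen_evidence_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$tier_proportions < 0))
    stop_oncomir("`tier_proportions` must be non-negative")
  mir_ids <- sim_mir_ids(cfg$n_mirs)
  n <- length(mir_ids)
  dbs <- c("TarBase", "miRWalk", "miRTarBase", "miRecords")
  withr::with_seed(stage_seed(cfg, "evidence"), {
    cls <- sample(1:3, n, replace = TRUE, prob = cfg$tier_proportions)
    validated <- logical(n)
    n_alg <- integer(n)
    for (i in seq_len(n)) {
      if (cls[i] == 1L) {                 # neither validated nor widely predicted
        validated[i] <- FALSE
        n_alg[i] <- sample(0:5, 1)
      } else if (cls[i] == 2L) {          # exactly one kind of support
        if (stats::runif(1) < 0.5) {
          validated[i] <- TRUE
          n_alg[i] <- sample(0:5, 1)
        } else {
          validated[i] <- FALSE
          n_alg[i] <- sample(6:12, 1)
        }
      } else {                            # both
        validated[i] <- TRUE
        n_alg[i] <- sample(6:12, 1)
      }
    }
    sources <- vapply(seq_len(n), function(i) {
      if (!validated[i]) return("")
      paste(sample(dbs, sample(1:3, 1)), collapse = ";")
    }, character(1))
  })
  data.frame(
    mir_id = mir_ids,
    target_gene = "CDK2AP1",
    validated_sources = sources,
    validated = validated,
    n_predicting_algorithms = n_alg,
    .sim_tier_class = cls,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
}

#' Generate a dual-luciferase reporter plate
#'
#' Simulates firefly/renilla wells for each condition in
#' `cfg$mir_effects`. Renilla counts are log-normal around a common
#' plate baseline; the firefly:renilla ratio of a condition is centered
#' on the mock ratio times the configured expected relative activity,
#' with multiplicative noise of coefficient of variation `cfg$luc_cv`.
#'
#' @param cfg A [sim_config()] object. `cfg$mir_effects` must contain
#'   `mock = 1`; expected activities must be positive.
#' @param plate_id Plate label.
#' @return Data frame with `plate_id`, `condition`, `firefly`, `renilla`
#'   and hidden `.sim_expected_activity`.
#' @export
gen_luciferase_plate <- function(cfg, plate_id = "plate-1") {
  stopifnot(inherits(cfg, "sim_config"))
  eff <- cfg$mir_effects
  if (any(eff <= 0)) stop_oncomir("expected relative activities must be positive")
  conditions <- rep(names(eff), each = cfg$luc_replicates)
  expected <- rep(unname(eff), each = cfg$luc_replicates)
  n <- length(conditions)
  base_ratio <- 2.0       # mock firefly:renilla ratio of the plate
  sdlog <- sqrt(log(1 + cfg$luc_cv^2))
  withr::with_seed(stage_seed(cfg, "luciferase") + nchar(plate_id), {
    renilla <- stats::rlnorm(n, meanlog = log(5e5), sdlog = 0.1)
    ratio <- base_ratio * expected *
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    firefly <- renilla * ratio
  })
  data.frame(
    plate_id = plate_id,
    condition = conditions,
    firefly = firefly,
    renilla = renilla,
    .sim_expected_activity = expected,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
}

# Log-scale correlation that yields Pearson correlation `r` between the
# exponentiated (log-normal) variables with log-sds s1, s2.
lognormal_rho <- function(r, s1, s2) {
  arg <- 1 + r * sqrt(expm1(s1^2) * expm1(s2^2))
  if (arg <= 0)
    stop_oncomir("target Pearson r unattainable at these log-scale dispersions")
  rho <- log(arg) / (s1 * s2)
  if (abs(rho) > 1)
    stop_oncomir("target Pearson r unattainable at these log-scale dispersions")
  rho
}

# Draw n pairs of N(0,1) with correlation rho.
bivariate_z <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

.TMA_CHANNELS <- c("dapi", "mir21", "keratin", "cdk2ap1")
.TMA_REGIONS <- c("nuc", "cyto")

median_channel_names <- function() {
  as.vector(outer(.TMA_CHANNELS, .TMA_REGIONS,
                  function(ch, rg) paste(ch, rg, "median", sep = "_")))
}

#' Generate a cell-level tissue-microarray cohort
#'
#' Produces one row per segmented cell across `n_patients x
#' cores_per_patient` cores. Tumor-cell cytoplasmic miR-21 and nuclear
#' CDK2AP1 medians are drawn from a bivariate log-normal whose log-scale
#' correlation is calibrated so the raw-scale Pearson correlation matches
#' `cfg$target_pearson_r`; core-level means share the same
#' anti-correlation, creating between-core spread. Stromal miR-21 is
#' scaled by `cfg$stroma_mir21_shift`. A fraction
#' `cfg$outlier_fraction` of cells (deterministic count) is displaced by
#' `cfg$outlier_magnitude_sd` channel standard deviations in one median
#' channel and flagged in the hidden column `.sim_outlier`.
#'
#' @param cfg A [sim_config()] object.
#' @return Data frame of cell records: `core_id`, `patient_id`, `x`, `y`
#'   (micrometres; pixel size 0.345 um recorded in attribute
#'   `pixel_size_um`), `compartment` (`tumor`/`stroma`), 24 intensity
#'   columns `{dapi,mir21,keratin,cdk2ap1}_{nuc,cyto}_{mean,median,sd}`,
#'   `excluded` (all `FALSE`; set by [merge_and_filter()]) and the hidden
#'   truth columns `.sim_outlier`, `.sim_outlier_channel`.
#' @export
gen_tma_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$tumor_fraction <= 0 || cfg$tumor_fraction >= 1)
    stop_oncomir("`tumor_fraction` must lie strictly inside (0, 1)")
  n_cores <- cfg$n_patients * cfg$cores_per_patient
  s_core <- cfg$core_log_sd
  s_cell <- cfg$cell_log_sd
  rho_cell <- lognormal_rho(cfg$target_pearson_r, s_cell, s_cell)

  withr::with_seed(stage_seed(cfg, "tma"), {
    core_id <- sprintf("core-%04d", seq_len(n_cores))
    patient_id <- rep(sprintf("pt-%03d", seq_len(cfg$n_patients)),
                      each = cfg$cores_per_patient)
    n_cells <- sample(seq(cfg$cells_per_core_range[1],
                          cfg$cells_per_core_range[2]),
                      n_cores, replace = TRUE)
    # core-level latent log-means, anti-correlated like the cells
    zc <- bivariate_z(n_cores, cfg$target_pearson_r)
    core_mir21 <- log(150) + s_core * zc[, 1]
    core_cdk <- log(120) + s_core * zc[, 2]

    N <- sum(n_cells)
    idx <- rep(seq_len(n_cores), times = n_cells)
    tumor <- stats::runif(N) < cfg$tumor_fraction
    compartment <- ifelse(tumor, "tumor", "stroma")

    # paired channels: bivariate within tumor cells, independent in stroma
    z <- bivariate_z(N, rho_cell)
    z[!tumor, 2] <- stats::rnorm(sum(!tumor))
    mir21_cyto <- exp(core_mir21[idx] + s_cell * z[, 1])
    mir21_cyto[!tumor] <- mir21_cyto[!tumor] * cfg$stroma_mir21_shift
    cdk_nuc <- exp(core_cdk[idx] + s_cell * z[, 2])
    cdk_nuc[!tumor] <- cdk_nuc[!tumor] * 0.8

    lognoise <- function(n, sd) stats::rnorm(n, sd = sd)
    dapi_nuc <- exp(log(200) + lognoise(N, s_cell))
    keratin_cyto <- exp(ifelse(tumor, log(180), log(40)) + lognoise(N, s_cell))
    # companion-region channels track their primary region
    mir21_nuc <- mir21_cyto * exp(log(0.6) + lognoise(N, 0.05))
    cdk_cyto <- cdk_nuc * exp(log(0.5) + lognoise(N, 0.05))
    dapi_cyto <- dapi_nuc * exp(log(0.3) + lognoise(N, 0.05))
    keratin_nuc <- keratin_cyto * exp(log(0.4) + lognoise(N, 0.05))

    med <- list(dapi_nuc_median = dapi_nuc, dapi_cyto_median = dapi_cyto,
                mir21_nuc_median = mir21_nuc, mir21_cyto_median = mir21_cyto,
                keratin_nuc_median = keratin_nuc,
                keratin_cyto_median = keratin_cyto,
                cdk2ap1_nuc_median = cdk_nuc, cdk2ap1_cyto_median = cdk_cyto)

    # planted artifacts: exact count, one median channel per cell,
    # additive displacement of k clean-cohort SDs
    n_out <- round(cfg$outlier_fraction * N)
    out_idx <- sample.int(N, n_out)
    out_channel <- sample(names(med), n_out, replace = TRUE)
    outlier <- logical(N)
    outlier[out_idx] <- TRUE
    channel_lab <- rep(NA_character_, N)
    channel_lab[out_idx] <- out_channel
    for (ch in unique(out_channel)) {
      i <- out_idx[out_channel == ch]
      med[[ch]][i] <- med[[ch]][i] +
        cfg$outlier_magnitude_sd * stats::sd(med[[ch]])
    }

    # coordinates inside a 1-mm core; tumor cells cluster centrally
    radius <- ifelse(tumor, 350, 500) * sqrt(stats::runif(N))
    theta <- stats::runif(N, 0, 2 * pi)

    cells <- data.frame(
      core_id = core_id[idx],
      patient_id = patient_id[idx],
      x = radius * cos(theta) + 500,
      y = radius * sin(theta) + 500,
      compartment = compartment,
      stringsAsFactors = FALSE,
      check.names = FALSE
    )
    for (nm in names(med)) {
      m <- med[[nm]]
      stem <- sub("_median$", "", nm)
      cells[[paste0(stem, "_mean")]] <- m * exp(stats::rnorm(N, 0.01, 0.02))
      cells[[nm]] <- m
      cells[[paste0(stem, "_sd")]] <- m * stats::runif(N, 0.05, 0.15)
    }
    cells$excluded <- FALSE
    cells$.sim_outlier <- outlier
    cells$.sim_outlier_channel <- channel_lab
  })
  attr(cells, "pixel_size_um") <- 0.345
  cells
}

#' Generate a survival cohort with group-dependent hazards
#'
#' Event times are exponential with hazard `h0 * HR(group)` where `h0 =
#' log(2) / baseline_median_dfs`; censoring is independent exponential
#' calibrated to `cfg$censoring_rate` (0 disables censoring). Two designs
#' are available:
#'
#' * `mode = "group"`: patients are assigned uniformly to the groups named
#'   in `cfg$hazard_ratios`. When those names are exactly `positive` and
#'   `low_neg`, the fraction of CDK2AP1-negative tumor cells is planted
#'   below/above 0.45 respectively, so threshold-recovery analyses have a
#'   known answer.
#' * `mode = "two_marker"`: two standard-normal markers (`miR-21-5p`,
#'   `miR-93-5p`) are drawn; patients with both markers above zero form
#'   the elevated-hazard group. `cfg$hazard_ratios` must then be named
#'   `rest` and `high_high`.
#'
#' @param cfg A [sim_config()] object.
#' @param mode `"group"` or `"two_marker"`.
#' @return Data frame of patient records: `patient_id`, `dfs_time`
#'   (months), `dfs_event` (logical), `frac_cdk2ap1_negative`, marker
#'   columns, and hidden `.sim_group`.
#' @export
gen_survival_cohort <- function(cfg, mode = c("group", "two_marker")) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  hr <- cfg$hazard_ratios
  if (any(hr <= 0)) stop_oncomir("`hazard_ratios` must be positive")
  n <- cfg$n_patients
  h0 <- log(2) / cfg$baseline_median_dfs
  withr::with_seed(stage_seed(cfg, "survival") + (mode == "two_marker"), {
    mir21 <- stats::rnorm(n)
    mir93 <- stats::rnorm(n)
    if (mode == "two_marker") {
      if (!setequal(names(hr), c("rest", "high_high")))
        stop_oncomir("two_marker mode requires hazard_ratios named 'rest' and 'high_high'")
      group <- ifelse(mir21 > 0 & mir93 > 0, "high_high", "rest")
    } else {
      group <- sample(names(hr), n, replace = TRUE)
      if (length(unique(group)) < length(hr))
        stop_oncomir("a hazard group received no patients; increase n_patients")
    }
    hazard <- h0 * unname(hr[group])
    t_event <- stats::rexp(n, rate = hazard)
    if (cfg$censoring_rate > 0) {
      # P(censor) = hc / (h + hc) for exponential event and censor times
      hc <- h0 * cfg$censoring_rate / (1 - cfg$censoring_rate)
      t_cens <- stats::rexp(n, rate = hc)
    } else {
      t_cens <- rep(Inf, n)
    }
    frac_neg <- stats::runif(n)
    if (mode == "group" && setequal(names(hr), c("positive", "low_neg"))) {
      frac_neg <- ifelse(group == "low_neg",
                         0.45 + 0.55 * frac_neg,
                         0.45 * frac_neg)
    }
    data.frame(
      patient_id = sprintf("pt-%03d", seq_len(n)),
      dfs_time = pmin(t_event, t_cens),
      dfs_event = t_event <= t_cens,
      frac_cdk2ap1_negative = frac_neg,
      `miR-21-5p` = mir21 + 0.5 * (unname(hr[group]) > min(hr)),
      `miR-93-5p` = mir93,
      `miR-155-5p` = stats::rnorm(n),
      .sim_group = group,
      stringsAsFactors = FALSE,
      check.names = FALSE
    )
  })
}

#' Generate a toy annotated variant table for the filter cascade
#'
#' Plants `n_survivors` variants that pass every rule of
#' [filter_cascade()] plus exactly one violator of each of the four rules
#' (non-exonic/synonymous class, recurrence across samples, population
#' MAF, repeat-region indel). Ground truth lives in the hidden column
#' `.sim_survivor`.
#'
#' @param cfg A [sim_config()] object (only `seed` is used).
#' @param n_survivors Number of planted cascade survivors.
#' @param recurrence_cutoff,maf_cutoff Thresholds the planted violators
#'   are built against; keep in sync with the [filter_cascade()] call.
#' @return Data frame of variant records (see [filter_cascade()] for the
#'   required columns) plus `.sim_survivor` and `.sim_rule`.
#' @export
gen_variant_table <- function(cfg, n_survivors = 2L,
                              recurrence_cutoff = 5L, maf_cutoff = 0.01) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- c("TP53", "CDKN2A", "FAT1", "NOTCH1", "PIK3CA", "CASP8",
             "HRAS", "NSD1", "KMT2D", "EPHA2")
  withr::with_seed(stage_seed(cfg, "variants"), {
    mk <- function(n, class, type, nsamp, maf, repeat_flag, survivor, rule) {
      data.frame(
        sample_id = sample(sprintf("SCC-%d", 1:9), n, replace = TRUE),
        gene = sample(genes, n, replace = TRUE),
        chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
        pos = sample.int(2e8, n),
        ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
        alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
        functional_class = class,
        variant_type = type,
        maf_1000g = maf,
        maf_esp6500 = NA_real_,
        maf_gnomad = maf,
        in_repeat_or_low_complexity = repeat_flag,
        n_samples_with_variant = nsamp,
        .sim_survivor = survivor,
        .sim_rule = rule,
        stringsAsFactors = FALSE,
        check.names = FALSE
      )
    }
    survivors <- mk(n_survivors, "exonic_nonsynonymous", "snv",
                    sample(seq_len(recurrence_cutoff - 1L), n_survivors,
                           replace = TRUE),
                    NA_real_, FALSE, TRUE, "none")
    violators <- rbind(
      mk(1L, "exonic_synonymous", "snv", 1L, NA_real_, FALSE, FALSE,
         "functional_class"),
      mk(1L, "exonic_nonsynonymous", "snv", recurrence_cutoff, NA_real_,
         FALSE, FALSE, "recurrence"),
      mk(1L, "exonic_nonsynonymous", "snv", 1L, 2 * maf_cutoff, FALSE,
         FALSE, "population_maf"),
      mk(1L, "splicing", "indel", 1L, NA_real_, TRUE, FALSE, "repeat_indel")
    )
    out <- rbind(survivors, violators)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}
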