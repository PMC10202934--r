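test_that("every generator is deterministic under a fixed config", {
  cfg <- tiny_cfg(seed = 11)
  expect_identical(gen_expression_matrix(cfg), gen_expression_matrix(cfg))
  expect_identical(gen_evidence_table(cfg), gen_evidence_table(cfg))
  expect_identical(gen_luciferase_plate(cfg), gen_luciferase_plate(cfg))
  expect_identical(gen_tma_cohort(cfg), gen_tma_cohort(cfg))
  expect_identical(gen_survival_cohort(cfg), gen_survival_cohort(cfg))
  expect_identical(gen_variant_table(cfg), gen_variant_table(cfg))
  # a different seed changes the draw
  expect_false(identical(gen_expression_matrix(cfg),
                         gen_expression_matrix(tiny_cfg(seed = 12))))
})

test_that("generators leave the global RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_expression_matrix(tiny_cfg()))
  invisible(gen_tma_cohort(tiny_cfg()))
  expect_identical(.Random.seed, before)
})

test_that("expression generator plants the configured group effect", {
  cfg <- sim_config(seed = 21, n_mirs = 50, effect_size = 2.0,
                    n_samples = c(deficient = 200L, proficient = 200L))
  x <- gen_expression_matrix(cfg)
  def <- rowMeans(x$values[, x$groups == "deficient"])
  pro <- rowMeans(x$values[, x$groups == "proficient"])
  diff_up <- mean((def - pro)[x$truth])
  diff_rest <- mean((def - pro)[setdiff(rownames(x$values), x$truth)])
  expect_lt(abs(diff_up - 2.0), 0.2)
  expect_lt(abs(diff_rest), 0.2)
})

test_that("expression generator handles degenerate and invalid designs", {
  x <- gen_expression_matrix(sim_config(seed = 1, n_mirs = 0))
  expect_identical(dim(x$values), c(0L, 7L))
  expect_identical(colnames(x$values), names(x$groups))
  expect_error(
    gen_expression_matrix(sim_config(seed = 1,
                                     n_samples = c(deficient = 0L,
                                                   proficient = 3L))),
    "deficient")
})

test_that("evidence records respect the 0-12 algorithm range and tier proportions", {
  cfg <- sim_config(seed = 31, n_mirs = 10000,
                    tier_proportions = c(0.5, 0.3, 0.2))
  ev <- gen_evidence_table(cfg)
  expect_true(all(ev$n_predicting_algorithms >= 0 &
                  ev$n_predicting_algorithms <= 12))
  # realized class fractions within the exact binomial 99% CI
  for (k in 1:3) {
    ci <- binom.test(sum(ev$.sim_tier_class == k), nrow(ev),
                     conf.level = 0.99)$conf.int
    expect_true(cfg$tier_proportions[k] >= ci[1] &&
                cfg$tier_proportions[k] <= ci[2])
  }
  # validated records always name a source database
  expect_true(all(nzchar(ev$validated_sources[ev$validated])))
  expect_error(sim_config(tier_proportions = c(0.9, 0.2, -0.1)),
               "non-negative")
})

test_that("luciferase plates are centered on the configured activities", {
  cfg <- sim_config(seed = 41, luc_replicates = 100L, luc_cv = 0.05)
  plate <- gen_luciferase_plate(cfg)
  expect_true(all(plate$firefly > 0 & plate$renilla > 0))
  act <- normalize_luciferase(plate)
  expect_equal(act$activity[act$condition == "mock"], 1.0)
  est <- act$activity[act$condition == "miR-21-5p"]
  expect_true(est > 0.23 && est < 0.27)
  expect_error(sim_config(mir_effects = c(mock = 1, bad = -0.5)), "0, 1")
})

test_that("TMA generator plants cores, compartments and exact outlier counts", {
  cfg <- tiny_cfg(seed = 51)
  cells <- gen_tma_cohort(cfg)
  expect_identical(length(unique(cells$core_id)),
                   cfg$n_patients * cfg$cores_per_patient)
  expect_setequal(unique(cells$compartment), c("tumor", "stroma"))
  expect_identical(sum(cells$.sim_outlier),
                   as.integer(round(cfg$outlier_fraction * nrow(cells))))
  expect_true(all(cells[grep("_median$", names(cells))] >= 0))
  expect_error(sim_config(tumor_fraction = 1), "strictly inside")
})

test_that("survival cohort honors hazard groups and censoring", {
  cfg <- sim_config(seed = 61, n_patients = 200, censoring_rate = 0)
  pts <- gen_survival_cohort(cfg)
  expect_true(all(pts$dfs_event))
  expect_true(all(pts$dfs_time >= 0))
  # planted IHC split: every low_neg patient above 0.45, positive below
  expect_true(all(pts$frac_cdk2ap1_negative[pts$.sim_group == "low_neg"] >= 0.45))
  expect_true(all(pts$frac_cdk2ap1_negative[pts$.sim_group == "positive"] < 0.45))
  cfg2 <- sim_config(seed = 61, n_patients = 200, censoring_rate = 0.4)
  frac_cens <- mean(!gen_survival_cohort(cfg2)$dfs_event)
  expect_lt(abs(frac_cens - 0.4), 0.12)
  expect_error(sim_config(hazard_ratios = c(a = 1, b = -2)), "positive")
})

test_that("variant fixture plants one violator per rule and clean survivors", {
  vt <- gen_variant_table(tiny_cfg(seed = 71), n_survivors = 3L)
  expect_identical(sort(unique(vt$.sim_rule)),
                   sort(c("none", "functional_class", "recurrence",
                          "population_maf", "repeat_indel")))
  expect_identical(sum(vt$.sim_survivor), 3L)
  fc <- filter_cascade(vt)
  expect_setequal(fc$survivors$pos, vt$pos[vt$.sim_survivor])
})

test_that("hidden truth columns are stripped cleanly", {
  vt <- gen_variant_table(tiny_cfg())
  stripped <- strip_truth(vt)
  expect_false(any(startsWith(names(stripped), ".sim_")))
  expect_identical(nrow(stripped), nrow(vt))
})

test_that("sim_config round-trips through YAML with unknown keys rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "n_patients: 10", "effect_size: 1.5"), path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$n_patients, 10L)
  expect_identical(cfg$effect_size, 1.5)
  writeLines(c("seed: 7", "nonsense_key: 1"), path)
  expect_error(read_sim_config(path), "nonsense_key")
})
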