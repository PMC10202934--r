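test_that("a grossly displaced cell is excluded by the z filter", {
  set.seed(7)
  mir <- rnorm(200, 100, 5)
  mir[1] <- mir[1] + 20 * sd(mir)
  cells <- toy_cells(mir, rnorm(200, 120, 5))
  out <- merge_and_filter(cells, quiet = TRUE)
  expect_true(out$excluded[1])
  # brute-force z agrees with the filter decision for every cell
  z <- (out$mir21_cyto_median - mean(out$mir21_cyto_median)) /
    sd(out$mir21_cyto_median)
  z2 <- (out$cdk2ap1_nuc_median - mean(out$cdk2ap1_nuc_median)) /
    sd(out$cdk2ap1_nuc_median)
  expect_identical(out$excluded, abs(z) > 3 | abs(z2) > 3)
})

test_that("zero-variance channels warn and exclude nothing; counts are conserved", {
  cells <- toy_cells(rep(100, 50), rnorm(50, 120, 5))
  expect_warning(out <- merge_and_filter(cells, quiet = TRUE),
                 "zero variance")
  expect_identical(nrow(out), 50L)
  expect_false(any((out$excluded)[abs(scale(out$cdk2ap1_nuc_median)) <= 3]))
  # a list of per-core tables merges; inconsistent headers error
  parts <- split(cells, rep(1:2, each = 25))
  expect_warning(merged <- merge_and_filter(parts, quiet = TRUE), "zero variance")
  expect_identical(nrow(merged), 50L)
  names(parts[[2]])[1] <- "other"
  expect_error(merge_and_filter(parts, quiet = TRUE), "inconsistent headers")
})

test_that("filtering flags but never drops cells on the synthetic cohort", {
  cells <- gen_tma_cohort(tiny_cfg(seed = 13))
  out <- merge_and_filter(cells, quiet = TRUE)
  expect_identical(nrow(out), nrow(cells))
  expect_gt(mean(out$excluded[out$.sim_outlier]), 0.95)
  frac <- attr(out, "exclusion_fraction")
  expect_true(frac >= 0.025 && frac < 0.08)
  # high_only mode is a subset of the two-sided exclusions
  hi <- merge_and_filter(cells, mode = "high_only", quiet = TRUE)
  expect_true(all(out$excluded[hi$excluded]))
})

test_that("core summaries enforce the tumor-cell inclusion cutoff", {
  cells <- rbind(toy_cells(rnorm(499, 100), rnorm(499, 120), core_id = "small"),
                 toy_cells(rnorm(500, 100), rnorm(500, 120), core_id = "big"))
  s <- summarize_cores(cells, min_tumor_cells = 500)
  expect_false(s$included[s$core_id == "small"])
  expect_true(s$included[s$core_id == "big"])
  expect_identical(nrow(s), 2L)  # degenerate cores flagged, not dropped
  # excluded cells do not contribute to counts or means
  cells2 <- toy_cells(c(rep(100, 500), rep(1000, 10)),
                      rnorm(510, 120),
                      excluded = c(rep(FALSE, 500), rep(TRUE, 10)))
  s2 <- summarize_cores(cells2, min_tumor_cells = 500)
  expect_identical(s2$n_tumor_cells, 500L)
  expect_equal(s2$mir21_tumor, 100)
  expect_true(is.na(s2$pearson_r))  # constant miR-21 -> undefined
  expect_error(summarize_cores(cells2[, -8]), "excluded")
})

test_that("per-core Pearson matches closed forms and a two-pass oracle", {
  cells <- toy_cells(c(1, 2, 3), c(3, 2, 1))
  s <- summarize_cores(cells, min_tumor_cells = 3)
  expect_equal(s$pearson_r, -1)
  set.seed(23)
  mir <- rlnorm(1000, 5, 0.3); cdk <- 0.5 * mir + rlnorm(1000, 4, 0.3)
  s2 <- summarize_cores(toy_cells(mir, cdk), min_tumor_cells = 10)
  naive <- sum((mir - mean(mir)) * (cdk - mean(cdk))) /
    sqrt(sum((mir - mean(mir))^2) * sum((cdk - mean(cdk))^2))
  expect_equal(s2$pearson_r, naive, tolerance = 1e-12)
})

test_that("cores rank by inverse correlation with undefined r last", {
  s <- toy_summaries(rep(100, 4), pearson_r = c(0.1, -0.8, NA, -0.2))
  ranked <- rank_cores(s)
  expect_identical(ranked$pearson_r, c(-0.8, -0.2, 0.1, NA))
  single <- rank_cores(toy_summaries(100, pearson_r = 0.3))
  expect_identical(nrow(single), 1L)
  s$included[2] <- FALSE
  expect_false("core-02" %in% rank_cores(s)$core_id)
})

test_that("compartment comparison recovers the planted stromal miR-21 shift", {
  cfg <- tiny_cfg(seed = 29, stroma_mir21_shift = 2.0,
                  cells_per_core_range = c(400L, 500L))
  cells <- merge_and_filter(gen_tma_cohort(cfg), quiet = TRUE)
  cc <- compare_compartments(cells)
  ratio <- cc$tests$mean_ratio[cc$tests$marker == "mir21"]
  expect_lt(abs(ratio - 2.0) / 2.0, 0.1)
  expect_lt(cc$tests$p_value[cc$tests$marker == "mir21"], 0.01)
})

test_that("compartment comparison handles nulls, zeros and missing compartments", {
  set.seed(31)
  v <- rnorm(400, 100, 5)
  cells <- toy_cells(v, rnorm(400, 120, 5),
                     compartment = rep(c("tumor", "stroma"), 200),
                     core_id = rep(c("c1", "c2"), each = 200))
  cc <- compare_compartments(cells)
  expect_gt(cc$tests$p_value[cc$tests$marker == "mir21"], 0.05)
  expect_lt(abs(cc$tests$mean_ratio[cc$tests$marker == "mir21"] - 1), 0.05)
  # a stroma compartment with zero miR-21 gives ratio 0
  cells0 <- toy_cells(c(rep(100, 5), rep(0, 5)), rnorm(10, 120),
                      compartment = rep(c("tumor", "stroma"), each = 5))
  cc0 <- compare_compartments(cells0, test = "welch")
  expect_equal(cc0$tests$mean_ratio[cc0$tests$marker == "mir21"], 0)
  # tumor-only core skipped with a warning
  lone <- toy_cells(rnorm(10, 100), rnorm(10, 120), core_id = "lonely")
  expect_warning(compare_compartments(rbind(cells, lone)), "skipped")
})

test_that("miR-21 stratification uses a strict cutoff with ties to low", {
  s <- toy_summaries(c(151, 150, 149), cdk2ap1_tumor = c(90, 100, 110))
  st <- stratify_and_test(s, mir21_cutoff = 150)
  grp <- setNames(st$summaries$strat_group, st$summaries$mir21_tumor)
  expect_identical(unname(grp[c("151", "150", "149")]),
                   c("high", "low", "low"))
  expect_identical(st$test$n_high, 1L)
  # excluded cores stay out of both groups
  s$included[3] <- FALSE
  expect_identical(
    stratify_and_test(s)$summaries$strat_group[3], "excluded")
  # an empty group is reported, not an error
  st2 <- stratify_and_test(toy_summaries(c(10, 20)))
  expect_match(st2$test$status, "empty high")
  expect_true(is.na(st2$test$p_value))
})

test_that("patient-paired stratification pairs per-patient means", {
  s <- toy_summaries(c(200, 100, 210, 90, 220, 80),
                     cdk2ap1_tumor = c(50, 100, 55, 108, 60, 112),
                     patient_id = rep(c("p1", "p2", "p3"), each = 2))
  st <- stratify_and_test(s, pairing = "patient_paired")
  expect_identical(st$test$n_pairs, 3L)
  expect_lt(st$test$p_value, 0.05)
  expect_lt(st$test$mean_cdk2ap1_high, st$test$mean_cdk2ap1_low)
})

test_that("digital reconstruction renders and validates channels", {
  cells <- gen_tma_cohort(tiny_cfg(seed = 37))
  one <- cells[cells$core_id == cells$core_id[1], ]
  p <- reconstruct(one)
  expect_s3_class(p, "ggplot")
  file <- withr::local_tempfile(fileext = ".png")
  reconstruct(one, channel = "mir21_cyto", file = file)
  expect_true(file.exists(file) && file.size(file) > 0)
  # the color scale spans the log2 range of the channel
  p2 <- ggplot2::ggplot_build(reconstruct(one, channel = "mir21_cyto"))
  rng <- range(log2(one$mir21_cyto_median + 1))
  expect_equal(p2$plot$scales$scales[[1]]$range$range, rng)
  expect_error(reconstruct(one, channel = "nope"), "mir21_cyto")
  # empty input draws an empty canvas without crashing
  expect_s3_class(reconstruct(one[0, ]), "ggplot")
})
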