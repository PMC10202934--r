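test_that("IHC classification applies the inclusive 45% boundary", {
  expect_identical(ihc_classify(c(0.44, 0.45, 0.46)),
                   c("positive", "low_neg", "low_neg"))
  expect_identical(ihc_classify(c(0, 1)), c("positive", "low_neg"))
  expect_identical(ihc_classify(0.45, inclusive = FALSE), "positive")
  expect_identical(ihc_classify(0.30, threshold = 0.25), "low_neg")
  expect_error(ihc_classify(1.2), "\\[0, 1\\]")
})

test_that("log-rank on duplicated groups is null and errors need two groups", {
  d <- data.frame(dfs_time = c(3, 5, 8, 12), dfs_event = c(1, 1, 0, 1))
  both <- rbind(d, d)
  res <- km_logrank(both, rep(c("a", "b"), each = 4))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_error(km_logrank(d, rep("a", 4)), "two groups")
  expect_error(km_logrank(d, c("a", "b")), "one entry per patient")
})

test_that("log-rank matches a hand-computed textbook example", {
  # events at t=1,2 in group A; group B censored at t=3,4
  d <- data.frame(dfs_time = c(1, 2, 3, 4),
                  dfs_event = c(TRUE, TRUE, FALSE, FALSE))
  labels <- c("A", "A", "B", "B")
  # hand calculation: at t=1, 4 at risk (2 A), 1 event -> E_A = 0.5,
  # V = 1*2*2*3/(16*3) = 0.25; at t=2, 3 at risk (1 A), 1 event ->
  # E_A = 1/3, V = 1*1*2*2/(9*2) = 2/9. O_A - E_A = 2 - 5/6 = 7/6,
  # chi^2 = (7/6)^2 / (0.25 + 2/9)
  chisq_hand <- (7 / 6)^2 / (0.25 + 2 / 9)
  res <- km_logrank(d, labels)
  expect_equal(res$statistic, chisq_hand, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(chisq_hand, 1, lower.tail = FALSE))
})

test_that("KM curves are valid survival functions", {
  cfg <- sim_config(seed = 47, n_patients = 120)
  pts <- gen_survival_cohort(cfg)
  res <- km_logrank(pts, ihc_classify(pts$frac_cdk2ap1_negative))
  for (g in unique(res$km$group)) {
    km <- res$km[res$km$group == g, ]
    expect_true(all(km$surv <= 1 & km$surv >= 0))
    expect_true(all(diff(km$surv) <= 1e-12))          # non-increasing
    expect_true(all(diff(km$n_risk) < 0))             # at-risk decreasing
  }
  # all-censored cohort stays flat at 1
  flat <- km_logrank(
    data.frame(dfs_time = 1:6, dfs_event = FALSE),
    rep(c("a", "b"), 3))
  expect_true(all(flat$km$surv == 1))
})

test_that("log-rank p agrees with a permutation test on a small cohort", {
  cfg <- sim_config(seed = 53, n_patients = 50,
                    hazard_ratios = c(a = 1, b = 1.8))
  pts <- gen_survival_cohort(cfg)
  res <- km_logrank(pts, pts$.sim_group)
  set.seed(1)
  perm <- replicate(2000, {
    km_logrank(pts, sample(pts$.sim_group))$statistic
  })
  p_perm <- (1 + sum(perm >= res$statistic)) / 2001
  expect_lt(abs(p_perm - res$p_value), 0.05)
})

test_that("dichotomization rules are deterministic with ties to low", {
  d <- data.frame(m = c(1, 2, 3, 4))
  expect_identical(dichotomize(d, "m"), c("low", "low", "high", "high"))
  expect_identical(dichotomize(d, "m", rule = "quantile", q = 0.5),
                   dichotomize(d, "m"))
  expect_identical(dichotomize(d, "m", rule = "fixed", cutoff = 1),
                   c("low", "high", "high", "high"))
  expect_error(dichotomize(d, "m", rule = "fixed", cutoff = 4),
               "leaves a group empty")
  expect_error(dichotomize(data.frame(m = rep(2, 5)), "m"), "identical")
  expect_error(dichotomize(d, "nope"), "not found")
  # median rule: the median value itself goes low
  expect_identical(dichotomize(data.frame(m = c(1, 2, 3)), "m"),
                   c("low", "low", "high"))
})

test_that("two-marker stratification partitions patients and finds planted risk", {
  cfg <- sim_config(seed = 59, n_patients = 300,
                    hazard_ratios = c(rest = 1, high_high = 2.5))
  pts <- gen_survival_cohort(cfg, mode = "two_marker")
  res <- stratify_two_markers(pts, "miR-21-5p", "miR-93-5p")
  expect_identical(length(res$groups), nrow(pts))      # a partition
  expect_identical(sum(table(res$groups)), nrow(pts))
  expect_identical(res$overall$df, 3L)
  expect_lt(res$contrast$p_value, 0.05)
  # degenerate marker pair: perfectly collinear markers leave two joint
  # groups empty; contrasts still run on the populated ones
  pts2 <- data.frame(dfs_time = rexp(40), dfs_event = TRUE,
                     a = rep(c(1, 2), 20))
  pts2$b <- pts2$a
  res2 <- stratify_two_markers(pts2, "a", "b")
  expect_match(res2$status, "empty group")
  expect_false(is.null(res2$contrast))
})

test_that("threshold scanning recovers a planted IHC split", {
  cfg <- sim_config(seed = 67, n_patients = 200)
  pts <- gen_survival_cohort(cfg)
  res <- suppressMessages(scan_optimal_threshold(pts, n_perm = 50))
  expect_lte(abs(res$threshold - 0.45), 0.05)          # within one grid step
  expect_lt(res$p_permutation, 0.05)
  # flat null: maximum not significant after the permutation check
  null_pts <- gen_survival_cohort(
    sim_config(seed = 68, n_patients = 60, hazard_ratios = c(a = 1, b = 1)))
  null_res <- suppressMessages(scan_optimal_threshold(null_pts, n_perm = 100))
  expect_gt(null_res$p_permutation, 0.05)
  # single-point grid returns that point
  one <- suppressMessages(
    scan_optimal_threshold(pts, grid = 0.4, n_perm = 0))
  expect_equal(one$threshold, 0.4)
  expect_error(suppressMessages(
    scan_optimal_threshold(pts, grid = c(-1, 2))), "empty group")
})
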