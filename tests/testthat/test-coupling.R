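test_that("pearson coupling matches the textbook computation", {
  res <- pearson_coupling(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(res$r, 0.98198, tolerance = 1e-5)
  expect_equal(res$r2, 0.96429, tolerance = 1e-5)
  # from-scratch covariance/sd computation on random inputs
  set.seed(44)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- rnorm(30) + 0.5 * x
    r_manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_coupling(x, y)$r, r_manual, tolerance = 1e-12)
  }
  # r2 is exactly r squared
  expect_equal(res$r2, res$r^2, tolerance = 1e-15)
})

test_that("the coupling call policy follows the p and R2 thresholds", {
  x <- 1:20
  ident <- pearson_coupling(x, x + 0)
  expect_equal(ident$r, 1)
  expect_equal(ident$call, "coupled")
  # large-n independent samples are uncoupled
  set.seed(5)
  nullr <- pearson_coupling(rnorm(1e4), rnorm(1e4))
  expect_equal(nullr$call, "uncoupled")
  # significant but weak: large n, true r with r2 below 0.1
  set.seed(6)
  z <- rnorm(5000)
  weak <- pearson_coupling(z, 0.15 * z + rnorm(5000))
  expect_lt(weak$p, 0.01)
  expect_lt(weak$r2, 0.1)
  expect_equal(weak$call, "weak")
  expect_error(pearson_coupling(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_coupling(1:2, 2:3), "at least 3")
})

test_that("all pairwise couplings cover each unordered pair once", {
  tab <- simulate_phase_durations(profile_rpe(), 125, seed = 3)
  res <- all_pairwise_coupling(tab)
  expect_equal(nrow(res), 3)
  expect_setequal(paste(res$phase_a, res$phase_b),
                  c("G1 S", "G1 G2", "S G2"))
  res4 <- all_pairwise_coupling(tab, phases = PHASE_LEVELS)
  expect_equal(nrow(res4), 6)
  # bonferroni never decreases p
  resb <- all_pairwise_coupling(tab, p_adjust = "bonferroni")
  expect_true(all(resb$p >= res$p))
})

test_that("a dominant shared factor produces a coupled call", {
  p <- factor_model_params(m_coupling = 1)
  # single-factor control produces coupled calls in a sizable share of
  # ensembles (the realized effect coefficient varies between runs)
  hit <- vapply(1:15, function(s) {
    cells <- simulate_factor_cells(p, seed = s)
    any(all_pairwise_coupling(cells$table)$call == "coupled")
  }, logical(1))
  expect_true(any(hit))
})

test_that("part-to-sum correlation matches the closed form and simulation", {
  expect_equal(part_sum_correlation(2, 0), 1)
  expect_equal(part_sum_correlation(1, 1), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(part_sum_correlation(1, 2), 1 / sqrt(5), tolerance = 1e-12)
  expect_error(part_sum_correlation(0, 1), "> 0")
  set.seed(77)
  n <- 1e5
  b <- rnorm(n, 10, 1)
  for (ratio in c(0, 0.5, 1, 2, 5)) {
    cc <- rnorm(n, 5, ratio)
    expect_lt(abs(cor(b, b + cc) - part_sum_correlation(1, ratio)), 0.02)
  }
})

test_that("variance decomposition attributes total-duration variance", {
  # a single variable phase takes the whole decomposition
  df <- data.frame(cell_id = sprintf("c%d", 1:50), condition = "x",
                   d_g1_h = withr::with_seed(1, rgamma(50, 4, 1)),
                   d_s_h = 10, d_g2_h = 3, d_m_h = 0.5)
  vd <- variance_decomposition(as_phase_table(df))
  expect_equal(unname(vd["G1"]), 1, tolerance = 1e-12)
  expect_equal(unname(vd[c("S", "G2", "M")]), rep(0, 3))
  # independent phases with variance ratio 4:1:0:0 split 0.8 / 0.2
  n <- 1e5
  df2 <- data.frame(cell_id = sprintf("c%d", seq_len(n)), condition = "x",
                    d_g1_h = withr::with_seed(2, rnorm(n, 10, 2)),
                    d_s_h = withr::with_seed(3, rnorm(n, 10, 1)),
                    d_g2_h = 3, d_m_h = 0.5)
  vd2 <- variance_decomposition(as_phase_table(df2))
  expect_equal(unname(vd2["G1"]), 0.8, tolerance = 0.02)
  expect_equal(unname(vd2["S"]), 0.2, tolerance = 0.02)
  # fractions of independent phases sum to ~ 1
  tab <- simulate_phase_durations(profile_rpe(), 2e4, seed = 4)
  expect_equal(sum(variance_decomposition(tab)), 1, tolerance = 0.05)
})

test_that("the noise bootstrap is exact at delta = 0 and sized 100 x 100", {
  tab <- simulate_phase_durations(profile_rpe(), 120, seed = 8)
  nb0 <- noise_bootstrap_correlations(tab, delta = 0, n_outer = 7,
                                      n_inner = 5, seed = 9)
  expect_equal(length(nb0$r), 35)
  expect_true(all(nb0$r == nb0$point_estimate))
  nb <- noise_bootstrap_correlations(tab, seed = 10)
  expect_equal(length(nb$r), 10000)
  # independent phases: nearly all replicates below the strength threshold
  expect_gt(nb$frac_uncoupled, 0.9)
  # determinism under the seed
  nb2 <- noise_bootstrap_correlations(tab, seed = 10)
  expect_identical(nb$r, nb2$r)
})

test_that("tiny durations are clamped at one frame with a log message", {
  df <- data.frame(cell_id = sprintf("c%d", 1:30), condition = "x",
                   d_g1_h = withr::with_seed(1, runif(30, 0.01, 0.05)),
                   d_s_h = withr::with_seed(2, rgamma(30, 9, 1)),
                   d_g2_h = 3, d_m_h = 0.5)
  expect_message(
    nb <- noise_bootstrap_correlations(as_phase_table(df),
                                       n_outer = 10, n_inner = 10,
                                       seed = 11),
    "clamped")
  expect_gt(nb$n_clamped, 0)
})

test_that("null p-values of the coupling test are uniform", {
  # 2,000 independent tables at the study sample size
  pv <- vapply(1:2000, function(s) {
    xy <- withr::with_seed(s, matrix(rgamma(250, 8, 1), ncol = 2))
    pearson_coupling(xy[, 1], xy[, 2])$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("Fisher-z sample sizes reproduce the planning numbers", {
  expect_identical(sample_size_for_correlation(0.1, 0.01, 0.8), 112L)
  # perfect-correlation limit: the +3 small-sample floor, rounded up
  expect_identical(sample_size_for_correlation(1 - 1e-12, 0.01, 0.8), 4L)
  expect_identical(sample_size_for_correlation(0.25, 0.05, 0.8), 30L)
  expect_error(sample_size_for_correlation(1.2), "< 1")
  expect_error(sample_size_for_correlation(0.1, alpha = 0), "0, 1")
})
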