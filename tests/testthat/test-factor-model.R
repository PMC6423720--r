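test_that("factor ensembles have the stated structure and moments", {
  p <- factor_model_params(m_coupling = 5,
                           m_specific = c(G1 = 3, S = 2))
  ens <- draw_factor_ensemble(p, seed = 1)
  expect_equal(dim(ens$a), c(4, 10))
  # coupling factors touch both coupled phases; specific factors one
  cp <- ens$type == "coupling"
  expect_true(all(ens$a["G1", cp] != 0) && all(ens$a["S", cp] != 0))
  expect_true(all(ens$a["G2", ] == 0) && all(ens$a["M", ] == 0))
  g1sp <- ens$type == "G1"
  expect_true(all(ens$a["S", g1sp] == 0)) # phase-specific: a_S = 0
  expect_true(all(ens$a["G1", ens$type == "S"] == 0))
  # lognormal abundance prior: mean = median * exp(sd^2/2) ~ 1197
  p2 <- factor_model_params(m_coupling = 10000)
  ens2 <- draw_factor_ensemble(p2, seed = 2)
  mu <- mean(ens2$abundance_mean)
  se <- sd(ens2$abundance_mean) / sqrt(10000)
  expect_lt(abs(mu - 1000 * exp(0.18)), 3 * se)
  # empty ensemble: baseline rates only
  p0 <- factor_model_params(m_coupling = 0,
                            m_specific = c(G1 = 0, S = 0, G2 = 0, M = 0))
  cells0 <- simulate_factor_cells(p0, n_cells = 10, seed = 3)
  expect_true(all(cells0$rates[, "G1"] == p0$lambda0[["G1"]]))
})

test_that("without coupling strength the phases stay uncoupled", {
  # gamma = 0: plain Erlang draws, pairwise R^2 ~ 0
  pz <- factor_model_params(gamma = c(G1 = 0, S = 0, G2 = 0, M = 0),
                            m_coupling = 1)
  cells <- simulate_factor_cells(pz, n_cells = 10000, seed = 4)
  expect_lt(abs(cor(cells$table$d_g1_h, cells$table$d_s_h)), 0.05)
  expect_equal(cells$n_floored, 0)
  # sigma_effect = 0: all effect coefficients are exactly zero
  ps <- factor_model_params(sigma_effect = 0, m_coupling = 5)
  ens <- draw_factor_ensemble(ps, seed = 5)
  expect_true(all(ens$a == 0))
  cells2 <- simulate_factor_cells(ps, ens, n_cells = 5000, seed = 5)
  expect_lt(abs(cor(cells2$table$d_g1_h, cells2$table$d_s_h)), 0.05)
})

test_that("a single calibrated factor couples; many dilute", {
  p <- factor_model_params() # m reference 1, 25% rate-modulation target
  r2_one <- vapply(1:40, function(s) {
    cells <- simulate_factor_cells(p, seed = s)
    cor(cells$table$d_g1_h, cells$table$d_s_h)^2
  }, numeric(1))
  p1000 <- p
  p1000$m_coupling <- 1000L
  r2_many <- vapply(1:20, function(s) {
    cells <- simulate_factor_cells(p1000, seed = s)
    cor(cells$table$d_g1_h, cells$table$d_s_h)^2
  }, numeric(1))
  expect_gt(mean(r2_one), mean(r2_many))
  expect_lt(mean(r2_many), 0.05)
})

test_that("the sweep reports one row per m and dilutes with m", {
  p <- factor_model_params()
  sw <- coupling_sweep(p, m_values = c(1, 10, 100), n_sims = 25, seed = 6)
  expect_equal(sw$m, c(1, 10, 100))
  expect_true(all(diff(sw$mean_r2) < 0))
  expect_true(all(sw$sd_r2 >= 0))
  expect_warning(coupling_sweep(p, m_values = 1, n_sims = 1, seed = 1),
                 "standard deviation")
  # phase-specific factors dilute further at fixed coupling count
  psp <- factor_model_params(m_coupling = 5,
                             m_specific = c(G1 = 50, S = 50))
  pno <- factor_model_params(m_coupling = 5)
  r2sp <- coupling_sweep(psp, m_values = 5, n_sims = 40, seed = 7)$mean_r2
  r2no <- coupling_sweep(pno, m_values = 5, n_sims = 40, seed = 7)$mean_r2
  expect_lt(r2sp, r2no)
})

test_that("perturbation selects the argmax-product factor", {
  p <- factor_model_params(m_coupling = 30)
  ens <- draw_factor_ensemble(p, seed = 8)
  pert <- perturb_single_factor(ens, fold = 10)
  # brute-force oracle over coupling factors
  prods <- ens$a["G1", ] * ens$a["S", ]
  expect_identical(pert$perturbed_factor,
                   which(prods == max(prods[ens$type == "coupling"])))
  expect_equal(pert$abundance_mean[pert$perturbed_factor],
               10 * ens$abundance_mean[pert$perturbed_factor])
  expect_equal(pert$abundance_mean[-pert$perturbed_factor],
               ens$abundance_mean[-pert$perturbed_factor])
  # m = 1: the only factor is selected
  p1 <- factor_model_params(m_coupling = 1)
  e1 <- draw_factor_ensemble(p1, seed = 9)
  expect_identical(perturb_single_factor(e1)$perturbed_factor, 1L)
  p0 <- factor_model_params(m_coupling = 0, m_specific = c(G1 = 2))
  expect_error(perturb_single_factor(draw_factor_ensemble(p0, seed = 1)),
               "no phase-coupling factors")
})

test_that("amplifying the dominant factor restores mean coupling", {
  p <- factor_model_params()
  base <- coupling_sweep(p, m_values = c(10, 100), n_sims = 30, seed = 10)
  pert <- coupling_sweep(p, m_values = c(10, 100), n_sims = 30, seed = 10,
                         perturb = TRUE)
  expect_true(all(pert$mean_r2 > base$mean_r2))
  expect_true(all(pert$perturbed))
})

test_that("the normal copy-number variant reproduces the Poisson regime", {
  p <- factor_model_params(m_coupling = 10)
  r2p <- vapply(1:25, function(s) {
    cells <- simulate_factor_cells(p, seed = s)
    cor(cells$table$d_g1_h, cells$table$d_s_h)^2
  }, numeric(1))
  r2n <- vapply(1:25, function(s) {
    cells <- simulate_factor_cells_normal_abundance(p, seed = 1000 + s)
    cor(cells$table$d_g1_h, cells$table$d_s_h)^2
  }, numeric(1))
  expect_lt(abs(mean(r2p) - mean(r2n)), 0.05)
  # determinism of the variant
  a <- simulate_factor_cells_normal_abundance(p, seed = 3)
  b <- simulate_factor_cells_normal_abundance(p, seed = 3)
  expect_identical(a$table, b$table)
})
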