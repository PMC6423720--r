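test_that("Erlang log-density matches hand evaluations and stays finite", {
  # k = 2, lambda = 1, x = 1: density is x e^{-x} = e^{-1}
  expect_equal(erlang_log_pdf(1, 2, 1, dt = 1), -1)
  # exponential density at the origin tends to lambda = 1 (log -> 0)
  expect_equal(erlang_log_pdf(1e-12, 1, 1, dt = 1), 0, tolerance = 1e-9)
  # dt enters as an additive log constant
  expect_equal(erlang_log_pdf(2, 3, 1.5, dt = 1 / 6),
               erlang_log_pdf(2, 3, 1.5, dt = 1) + log(1 / 6))
  # no factorial overflow at large shape
  expect_true(is.finite(erlang_log_pdf(10, 200, 20, dt = 1)))
  expect_error(erlang_log_pdf(0, 1, 1), "> 0")
  expect_error(erlang_log_pdf(1, 2.5, 1), "integer")
})

test_that("profile rate equals the numeric maximizer of the likelihood", {
  # closed form lambda(k) = k/mean(x) vs the root of the score function
  set.seed(40)
  x <- rgamma(400, shape = 6, rate = 1.7)
  n <- length(x)
  for (k in c(1, 3, 8, 20, 64)) {
    score <- function(lam) n * k / lam - sum(x)
    lam_num <- uniroot(score, c(1e-6, 1e3), tol = 1e-14)$root
    expect_equal(k / mean(x), lam_num, tolerance = 1e-10)
  }
})

test_that("the fit recovers known shapes and is dt-invariant", {
  set.seed(17)
  f1 <- fit_erlang_phase(rexp(2000, 1), dt = 1 / 6)
  expect_identical(f1$k, 1L)
  fits <- lapply(1:20, function(s)
    fit_erlang_phase(withr::with_seed(s, rgamma(1000, 8, rate = 1.2))))
  k_hat <- vapply(fits, `[[`, integer(1), "k")
  expect_gte(mean(abs(k_hat - 8) <= 1), 0.9)
  lam_rel <- vapply(fits, function(f) abs(f$lambda / 1.2 - 1), numeric(1))
  expect_lt(median(lam_rel), 0.1)
  x <- withr::with_seed(3, rgamma(500, 8, rate = 1.2))
  fa <- fit_erlang_phase(x, dt = 1)
  fb <- fit_erlang_phase(x, dt = 0.01)
  expect_identical(fa$k, fb$k)
  expect_equal(fa$lambda, fb$lambda)
  expect_equal(fa$loglik - fb$loglik, 500 * log(1 / 0.01))
})

test_that("zero-variance data drives the shape to the boundary", {
  expect_warning(f <- fit_erlang_phase(rep(5, 100), k_max = 50), "k_max")
  expect_identical(f$k, 50L)
})

test_that("shared-rate fit recovers a common rate and is nested", {
  set.seed(12)
  durs <- list(G1 = rgamma(2000, 4, rate = 2), S = rgamma(2000, 20, rate = 2),
               G2 = rgamma(2000, 8, rate = 2), M = rgamma(2000, 1, rate = 2))
  sh <- fit_shared_rate(durs, seed = 1)
  expect_lt(abs(sh$lambda / 2 - 1), 0.1)
  expect_true(all(abs(sh$k - c(G1 = 4, S = 20, G2 = 8, M = 1)) <= 1))
  # nested-model inequality against the independent fits
  indep <- sum(vapply(names(durs), function(p)
    fit_erlang_phase(durs[[p]])$loglik, numeric(1)))
  shared <- fit_shared_rate(durs, dt = DEFAULT_FRAME_H, seed = 1)
  expect_lte(shared$loglik, indep + 1e-8)
})

test_that("coordinate ascent matches exhaustive search at small k_max", {
  set.seed(23)
  durs <- list(A = rgamma(80, 3, rate = 1.5), B = rgamma(80, 6, rate = 1.5))
  sh <- fit_shared_rate(durs, k_max = 12, n_restarts = 5, seed = 2)
  # brute force over all shape pairs with the closed-form rate
  n_p <- vapply(durs, length, integer(1))
  sx <- vapply(durs, sum, numeric(1))
  slog <- vapply(durs, function(v) sum(log(v)), numeric(1))
  best <- -Inf
  for (ka in 1:12) for (kb in 1:12) {
    kv <- c(ka, kb)
    lam <- sum(n_p * kv) / sum(sx)
    ll <- sum(n_p * kv) * log(lam) + sum((kv - 1) * slog) -
      lam * sum(sx) - sum(n_p * lgamma(kv)) +
      sum(n_p) * log(DEFAULT_FRAME_H)
    if (ll > best) best <- ll
  }
  expect_equal(sh$loglik, best, tolerance = 1e-10)
})

test_that("shared rate cannot absorb strongly heterogeneous rates", {
  # rates spanning 20x: the likelihood-ratio versus independent fits is
  # large, the signature that one rate cannot fit all phases
  set.seed(31)
  durs <- list(G1 = rgamma(300, 8, rate = 1), S = rgamma(300, 8, rate = 20),
               G2 = rgamma(300, 8, rate = 4), M = rgamma(300, 8, rate = 10))
  sh <- fit_shared_rate(durs, seed = 3)
  indep <- sum(vapply(names(durs), function(p)
    fit_erlang_phase(durs[[p]])$loglik, numeric(1)))
  expect_gt(indep - sh$loglik, 50)
})

test_that("bootstrap spreads are positive, finite, and scale with n", {
  x <- withr::with_seed(6, rgamma(500, 8, rate = 1.2))
  bs <- bootstrap_fit_sd(x, n_boot = 1000, seed = 7)
  expect_true(bs$k_sd > 0 && is.finite(bs$k_sd))
  expect_true(bs$lambda_sd > 0 && is.finite(bs$lambda_sd))
  # doubling the data (each point twice) shrinks the sds by ~ 1/sqrt(2)
  bs2 <- bootstrap_fit_sd(c(x, x), n_boot = 1000, seed = 7)
  expect_lt(abs(bs2$lambda_sd / bs$lambda_sd - 1 / sqrt(2)), 0.15)
  expect_warning(bootstrap_fit_sd(x, n_boot = 2, seed = 1), "small")
})

test_that("KS validation is calibrated and detects gross mismatch", {
  fit <- withr::with_seed(3, fit_erlang_phase(rgamma(500, 8, rate = 1.2)))
  # data from the fitted law itself: p-values roughly uniform
  pv <- vapply(1:200, function(s) {
    obs <- withr::with_seed(1000 + s, rgamma(200, fit$k, rate = fit$lambda))
    validate_fit_ks(obs, fit, n_sim = 1000, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(pv < 0.05), 0.01)
  expect_lte(mean(pv < 0.05), 0.10)
  # a +5 h shift is decisively rejected
  obs <- withr::with_seed(9, rgamma(300, fit$k, rate = fit$lambda)) + 5
  expect_lt(validate_fit_ks(obs, fit, n_sim = 5000, seed = 2)$p_value, 1e-6)
  # the statistic agrees with an independent empirical-CDF computation
  obs2 <- withr::with_seed(10, rgamma(300, fit$k, rate = fit$lambda))
  res <- validate_fit_ks(obs2, fit, n_sim = 300, seed = 11)
  sim <- withr::with_seed(11, rgamma(300, fit$k, rate = fit$lambda))
  grid <- sort(c(obs2, sim))
  d_manual <- max(abs(ecdf(obs2)(grid) - ecdf(sim)(grid)))
  expect_equal(res$statistic, d_manual, tolerance = 1e-12)
})

test_that("Welch-Satterthwaite matches hand arithmetic and keeps the mean", {
  # equal scales collapse to the exact sum of shapes
  ws <- welch_satterthwaite(c(2, 3), c(1, 1))
  expect_identical(ws$k_sum, 5L)
  expect_equal(ws$theta_sum, 1)
  expect_equal(ws$k_sum_real, 5)
  # (4,1) + (1,3): k_real = 49/13, rounded to 4, scale preserving mean 7
  ws2 <- welch_satterthwaite(c(4, 1), c(1, 3))
  expect_equal(ws2$k_sum_real, 49 / 13)
  expect_identical(ws2$k_sum, 4L)
  expect_equal(ws2$theta_sum, 1.75)
  # single component is returned unchanged
  ws3 <- welch_satterthwaite(7, 0.5)
  expect_identical(ws3$k_sum, 7L)
  expect_equal(ws3$theta_sum, 0.5)
  # mean exactness before and after integer rounding (random components)
  set.seed(2)
  for (i in 1:20) {
    k <- sample(1:30, 3)
    th <- runif(3, 0.1, 4)
    w <- welch_satterthwaite(k, th)
    expect_equal(w$k_sum_real * w$theta_sum_real, sum(k * th),
                 tolerance = 1e-12)
    expect_equal(w$k_sum * w$theta_sum, sum(k * th), tolerance = 1e-12)
  }
})

test_that("fits serialize to the JSON schema", {
  f <- withr::with_seed(1, fit_erlang_phase(rgamma(100, 4, 2), phase = "G1"))
  js <- jsonlite::fromJSON(fit_to_json(f), simplifyVector = TRUE)
  expect_equal(js$phase, "G1")
  expect_equal(js$k, f$k)
  expect_equal(js$lambda_per_h, f$lambda, tolerance = 1e-12)
  expect_equal(js$n, 100)
})
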