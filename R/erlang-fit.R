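#' Erlang log-density of a phase duration
#'
#' Log of the Erlang probability of observing a duration `x` under shape
#' `k` (integer number of rate-limiting steps) and per-hour rate `lambda`,
#' multiplied by the measurement interval `dt`:
#' \deqn{f(x; k, \lambda) = \frac{\lambda^k x^{k-1} e^{-\lambda x}}{(k-1)!}\,\Delta T.}
#' The `dt` factor converts the density to a per-frame observation
#' probability; it is an additive constant on the log scale and never
#' changes a maximum-likelihood argmax. Computed via `lgamma` so that it
#' stays finite for large `k` (no factorial overflow).
#'
#' @param x duration in hours, strictly positive (vectorized).
#' @param k positive integer shape (number of steps).
#' @param lambda per-hour rate, > 0.
#' @param dt measurement interval in hours, > 0.
#' @return log-density values, same length as `x`.
#' @export
erlang_log_pdf <- function(x, k, lambda, dt = 1) {
  k <- assert_integerish(k, "k")
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  assert_scalar_num(lambda, "lambda", 0, strict = TRUE)
  assert_scalar_num(dt, "dt", 0, strict = TRUE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("durations `x` must be finite and > 0", call. = FALSE)
  k * log(lambda) + (k - 1) * log(x) - lambda * x - lgamma(k) + log(dt)
}

# Erlang log-likelihood profile over k = 1..k_max from sufficient statistics,
# with the closed-form conditional rate lambda(k) = k / mean(x)
erlang_profile_loglik <- function(n, sum_x, sum_log_x, dt, k_max) {
  ks <- seq_len(k_max)
  lam <- ks * n / sum_x
  n * ks * log(lam) + (ks - 1) * sum_log_x - lam * sum_x -
    n * lgamma(ks) + n * log(dt)
}

#' Fit an Erlang distribution to phase durations by exact maximum likelihood
#'
#' Finds the integer shape `k` and rate `lambda` maximizing the Erlang
#' likelihood of a sample of phase durations. For each candidate `k` the
#' conditional maximizer of the rate is available in closed form,
#' `lambda(k) = k / mean(x)` (from dL/dlambda = 0), so the fit is an
#' exhaustive, deterministic scan over `k = 1..k_max` of the profile
#' log-likelihood. Ties on log-likelihood resolve to the smallest `k`
#' (parsimony). The measurement interval `dt` enters the reported
#' log-likelihood but cannot change the argmax.
#'
#' @param x positive phase durations in hours, length >= 2.
#' @param dt measurement interval in hours (default 10 min).
#' @param k_max largest shape considered; hitting it triggers a boundary
#'   warning (zero-variance data drives the optimum to `k = Inf`).
#' @param phase optional phase label carried in the result.
#' @return an `erlang_fit`: list with `phase`, `k`, `lambda`, `loglik`,
#'   `n`, `dt`, and bootstrap slots `k_sd`, `lambda_sd` (NA until
#'   [bootstrap_fit_sd()] fills them).
#' @seealso [bootstrap_fit_sd()], [validate_fit_ks()], [fit_shared_rate()]
#' @export
fit_erlang_phase <- function(x, dt = DEFAULT_FRAME_H, k_max = 500,
                             phase = NA_character_) {
  if (length(x) < 2) stop("need at least 2 durations", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("durations must be finite and > 0", call. = FALSE)
  k_max <- assert_integerish(k_max, "k_max")
  assert_scalar_num(dt, "dt", 0, strict = TRUE)
  n <- length(x)
  ll <- erlang_profile_loglik(n, sum(x), sum(log(x)), dt, k_max)
  k_hat <- which.max(ll) # first max: smallest k wins ties
  if (k_hat == k_max)
    warning("Erlang shape fit hit k_max = ", k_max,
            "; possible boundary solution (data variance too small)",
            call. = FALSE)
  structure(
    list(phase = phase, k = as.integer(k_hat), lambda = k_hat / mean(x),
         loglik = ll[k_hat], n = n, dt = dt,
         k_sd = NA_real_, lambda_sd = NA_real_, k_max = k_max),
    class = "erlang_fit")
}

#' @export
print.erlang_fit <- function(x, ...) {
  cat(sprintf(
    "Erlang fit%s: k = %d, lambda = %.4g /h (mean %.3g h), logLik = %.3f, n = %d\n",
    if (is.na(x$phase)) "" else paste0(" [", x$phase, "]"),
    x$k, x$lambda, x$k / x$lambda, x$loglik, x$n))
  if (!is.na(x$k_sd))
    cat(sprintf("  bootstrap sd: k %.3g, lambda %.3g\n", x$k_sd, x$lambda_sd))
  invisible(x)
}

#' Fit independent Erlang models to every phase of a table
#'
#' @param table a `phase_table` with duration columns.
#' @param phases phases to fit (default all with data).
#' @inheritParams fit_erlang_phase
#' @return named list of `erlang_fit` objects.
#' @export
fit_erlang_table <- function(table, dt = DEFAULT_FRAME_H, k_max = 500,
                             phases = PHASE_LEVELS) {
  table <- as_phase_table(table)
  fits <- list()
  for (p in phases) {
    x <- table[[dur_col(p)]]
    x <- x[!is.na(x)]
    if (length(x) >= 2)
      fits[[p]] <- fit_erlang_phase(x, dt = dt, k_max = k_max, phase = p)
  }
  fits
}

#' Fit the single-shared-rate Markovian model across phases
#'
#' Jointly fits all phases to Erlang distributions constrained to one
#' common rate `lambda`, with per-phase integer shapes: the likelihood is
#' the product of the per-phase Erlang likelihoods. Given a shape vector
#' the conditional rate is closed-form,
#' `lambda = sum_p(n_p k_p) / sum_p(sum x_p)`; the shape vector is found by
#' coordinate ascent (each phase's shape rescanned exhaustively holding the
#' others) from seeded random restarts. As a nested submodel its maximized
#' log-likelihood can never exceed the sum of the independent per-phase
#' fits.
#'
#' @param durations named list of positive duration vectors, one per phase
#'   (all four phases must be nonempty for the canonical model, but any
#'   named set of two or more works).
#' @param dt measurement interval in hours.
#' @param k_max largest per-phase shape considered.
#' @param n_restarts number of random restarts for the shape search.
#' @param seed optional integer seed for the restarts.
#' @return a `shared_rate_fit`: list with `lambda`, named integer vector
#'   `k`, `loglik`, `n` (per-phase counts), `dt`.
#' @export
fit_shared_rate <- function(durations, dt = DEFAULT_FRAME_H, k_max = 500,
                            n_restarts = 10, seed = NULL) {
  if (!is.list(durations) || is.null(names(durations)) ||
      any(!nzchar(names(durations))))
    stop("`durations` must be a named list of duration vectors",
         call. = FALSE)
  phases <- names(durations)
  if (length(phases) < 2) stop("need at least two phases", call. = FALSE)
  for (p in phases)
    if (length(durations[[p]]) < 1 || any(durations[[p]] <= 0))
      stop("phase '", p, "' must have positive, nonempty durations",
           call. = FALSE)
  k_max <- assert_integerish(k_max, "k_max")
  n_p <- vapply(durations, length, integer(1))
  sx_p <- vapply(durations, sum, numeric(1))
  slog_p <- vapply(durations, function(v) sum(log(v)), numeric(1))
  sx_tot <- sum(sx_p)

  joint_ll <- function(kvec) {
    lam <- sum(n_p * kvec) / sx_tot
    sum(n_p * kvec) * log(lam) + sum((kvec - 1) * slog_p) - lam * sx_tot -
      sum(n_p * lgamma(kvec)) + sum(n_p) * log(dt)
  }

  # rescan phase j's shape with the others fixed (conditional lambda closed
  # form per candidate shape)
  scan_phase <- function(kvec, j) {
    ks <- seq_len(k_max)
    K_other <- sum(n_p[-j] * kvec[-j])
    Ktot <- K_other + n_p[j] * ks
    lam <- Ktot / sx_tot
    ll <- Ktot * log(lam) + (ks - 1) * slog_p[j] +
      sum((kvec[-j] - 1) * slog_p[-j]) - lam * sx_tot -
      n_p[j] * lgamma(ks) - sum(n_p[-j] * lgamma(kvec[-j])) +
      sum(n_p) * log(dt)
    which.max(ll)
  }

  inits <- with_seed_opt(seed, {
    # first restart from the moment-based shapes, the rest random
    mom <- pmax(1L, pmin(k_max, vapply(durations, function(v) {
      if (length(v) >= 2 && var(v) > 0) as.integer(round(mean(v)^2 / var(v)))
      else k_max
    }, integer(1))))
    c(list(mom), lapply(seq_len(max(0, n_restarts - 1)), function(i)
      vapply(phases, function(p)
        sample.int(min(k_max, 200L), 1), integer(1))))
  })

  best <- NULL
  for (k0 in inits) {
    kvec <- as.numeric(k0)
    names(kvec) <- phases
    repeat {
      changed <- FALSE
      for (j in seq_along(phases)) {
        knew <- scan_phase(kvec, j)
        if (knew != kvec[j]) {
          kvec[j] <- knew
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    ll <- joint_ll(kvec)
    if (is.null(best) || ll > best$loglik)
      best <- list(k = kvec, loglik = ll)
  }
  if (any(best$k == k_max))
    warning("shared-rate fit hit k_max for phase(s): ",
            paste(phases[best$k == k_max], collapse = ", "), call. = FALSE)
  structure(
    list(lambda = sum(n_p * best$k) / sx_tot,
         k = stats::setNames(as.integer(best$k), phases),
         loglik = best$loglik, n = n_p, dt = dt),
    class = "shared_rate_fit")
}

#' @export
print.shared_rate_fit <- function(x, ...) {
  cat(sprintf("Shared-rate Erlang fit: lambda = %.4g /h, logLik = %.3f\n",
              x$lambda, x$loglik))
  cat("  k:", paste(sprintf("%s=%d", names(x$k), x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap standard deviations of Erlang fit parameters
#'
#' Resamples the durations with replacement `n_boot` times, refits the
#' Erlang model to each resample, and reports the standard deviations of
#' the fitted shape and rate.
#'
#' @inheritParams fit_erlang_phase
#' @param n_boot number of bootstrap resamples (1,000 is the conventional
#'   choice for error bars on `k` and `lambda`).
#' @param seed optional integer seed.
#' @return list with `k_sd`, `lambda_sd` and the full bootstrap draws
#'   `k_boot`, `lambda_boot`.
#' @export
bootstrap_fit_sd <- function(x, dt = DEFAULT_FRAME_H, n_boot = 1000,
                             seed = NULL, k_max = 500) {
  n_boot <- assert_integerish(n_boot, "n_boot")
  if (n_boot < 2) stop("`n_boot` must be >= 2", call. = FALSE)
  if (n_boot < 30)
    warning("n_boot = ", n_boot,
            " is too small for stable standard deviations", call. = FALSE)
  n <- length(x)
  draws <- with_seed_opt(seed, {
    k_b <- integer(n_boot)
    l_b <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      xb <- x[sample.int(n, n, replace = TRUE)]
      ll <- erlang_profile_loglik(n, sum(xb), sum(log(xb)), dt, k_max)
      k_b[b] <- which.max(ll)
      l_b[b] <- k_b[b] / mean(xb)
    }
    list(k = k_b, lambda = l_b)
  })
  list(k_sd = sd(draws$k), lambda_sd = sd(draws$lambda),
       k_boot = draws$k, lambda_boot = draws$lambda)
}

#' Validate an Erlang fit by simulation and a two-sample KS test
#'
#' Simulates `n_sim` durations from the fitted Erlang distribution and
#' compares them to the observed durations with a two-sided two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param observed observed durations (hours).
#' @param fit an `erlang_fit`.
#' @param n_sim number of simulated durations.
#' @param seed optional integer seed.
#' @return list with `statistic` (KS D) and `p_value`.
#' @export
validate_fit_ks <- function(observed, fit, n_sim = 10000, seed = NULL) {
  stopifnot(inherits(fit, "erlang_fit"))
  sim <- with_seed_opt(seed, rgamma(n_sim, shape = fit$k, rate = fit$lambda))
  kt <- suppressWarnings(ks.test(observed, sim))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Welch-Satterthwaite Erlang approximation to a sum of Erlang variables
#'
#' A sequence of phases with different step rates is hypoexponential
#' (generalized Erlang). The Welch-Satterthwaite moment match approximates
#' the sum of Erlang components `(k_i, theta_i)` (shape, scale in hours) by
#' one gamma distribution:
#' \deqn{k_{sum} = \frac{(\sum_i \theta_i k_i)^2}{\sum_i \theta_i^2 k_i},
#'   \qquad \theta_{sum} = \frac{\sum_i \theta_i k_i}{k_{sum}}.}
#' To return an Erlang proper, `k_sum` is then rounded half-up to the
#' nearest integer (floor at 1) and the scale rescaled so that the mean
#' `k * theta` is preserved exactly.
#'
#' @param k positive integer shapes of the components.
#' @param theta positive scales (hours) of the components.
#' @return list with integer `k_sum`, mean-preserving `theta_sum`, and the
#'   unrounded `k_sum_real`, `theta_sum_real`.
#' @export
welch_satterthwaite <- function(k, theta) {
  k <- assert_integerish(k, "k")
  if (length(k) == 0 || length(k) != length(theta))
    stop("`k` and `theta` must be nonempty and the same length",
         call. = FALSE)
  if (any(k < 1) || any(theta <= 0))
    stop("components need k >= 1 and theta > 0", call. = FALSE)
  m1 <- sum(theta * k)            # mean of the sum
  k_real <- m1^2 / sum(theta^2 * k)
  theta_real <- m1 / k_real
  k_int <- max(1L, as.integer(floor(k_real + 0.5))) # round half-up
  list(k_sum = k_int, theta_sum = m1 / k_int,
       k_sum_real = k_real, theta_sum_real = theta_real)
}

#' Serialize Erlang fits to JSON
#'
#' @param fits a single `erlang_fit` or a (named) list of them.
#' @param path optional file; when NULL the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
fit_to_json <- function(fits, path = NULL) {
  if (inherits(fits, "erlang_fit")) fits <- list(fits)
  out <- lapply(fits, function(f)
    list(phase = f$phase, k = f$k, lambda_per_h = f$lambda,
         k_sd = f$k_sd, lambda_sd = f$lambda_sd,
         loglik = f$loglik, n = f$n, dt_h = f$dt))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
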