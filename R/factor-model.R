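#' Parameters of the many-for-all heritable-factor model
#'
#' The many-for-all model posits many types of heritable molecular
#' factors, each exerting a weak effect on the progression rate of one or
#' more cell-cycle phases. Per cell and phase the Erlang step rate is
#' \deqn{\lambda_P = \lambda_{0,P} + \gamma_P \sum_i a_{P,i}\,(n_i - \bar n_i),}
#' with effect coefficients `a ~ N(0, sigma_effect)` per phase a factor
#' touches, per-cell copy numbers `n_i ~ Poisson(lambda_i)` and mean
#' abundances `lambda_i` lognormal (median `abundance_log_median`, log-sd
#' `abundance_log_sd`). The factor term is centered at its ensemble
#' expectation `sum_i a_i lambda_i`: a shift common to all cells of a
#' simulation cannot affect within-population correlations, and without
#' centering the random ensemble-mean offset (sd ~ `sigma_effect *
#' sqrt(sum lambda_i^2)`) dwarfs the baseline rate and drives rates
#' negative. Phase-coupling factors carry coefficients on every phase in
#' `coupled_phases`; phase-specific factors on exactly one phase.
#'
#' When `gamma` is not given it is calibrated so that the expected
#' across-cell standard deviation of the factor term equals
#' `gamma_cv_target` (default 25%) of `lambda0` at the reference factor
#' count `gamma_reference_m` (default 1), then held fixed when the factor
#' count is swept.
#'
#' @param lambda0 named per-phase baseline rates (per hour).
#' @param k named per-phase positive integer shapes.
#' @param coupled_phases phases under shared control of the coupling
#'   factors (default G1 and S, the canonical pair).
#' @param m_coupling number of phase-coupling factor types.
#' @param m_specific named per-phase counts of phase-specific factor
#'   types (default none).
#' @param gamma named per-phase coupling fraction; `NULL` to calibrate.
#' @param gamma_cv_target,gamma_reference_m calibration target and
#'   reference factor count (see Details).
#' @param sigma_effect sd of the effect coefficients (default 0.01).
#' @param abundance_log_median median of the mean-abundance lognormal
#'   (copies; default 1,000).
#' @param abundance_log_sd log-scale sd of the mean-abundance lognormal
#'   (default 0.6).
#' @param perturbation_fold fold-increase applied by
#'   [perturb_single_factor()] (default 10).
#' @param rate_floor_fraction lower bound on rates as a fraction of
#'   `lambda0`, in (0, 1) (default 0.05); floor activations are counted.
#' @param n_cells default cells per simulation (default 200).
#' @param n_sims default simulations per condition (default 200).
#' @return a `factor_model_params` list.
#' @export
factor_model_params <- function(lambda0 = profile_rpe()$lambda,
                                k = profile_rpe()$k,
                                coupled_phases = c("G1", "S"),
                                m_coupling = 1,
                                m_specific = c(G1 = 0, S = 0, G2 = 0, M = 0),
                                gamma = NULL,
                                gamma_cv_target = 0.25,
                                gamma_reference_m = 1,
                                sigma_effect = 0.01,
                                abundance_log_median = 1000,
                                abundance_log_sd = 0.6,
                                perturbation_fold = 10,
                                rate_floor_fraction = 0.05,
                                n_cells = 200, n_sims = 200) {
  lambda0 <- lambda0[PHASE_LEVELS]
  k <- assert_integerish(k[PHASE_LEVELS], "k")
  if (anyNA(lambda0) || any(lambda0 <= 0))
    stop("`lambda0` must be positive and named over all phases",
         call. = FALSE)
  if (anyNA(k) || any(k < 1)) stop("`k` must be >= 1 per phase",
                                   call. = FALSE)
  coupled_phases <- match.arg(coupled_phases, PHASE_LEVELS,
                              several.ok = TRUE)
  if (length(coupled_phases) < 2)
    stop("coupling factors need at least two phases", call. = FALSE)
  m_coupling <- assert_integerish(m_coupling, "m_coupling")
  ms <- stats::setNames(rep(0L, 4), PHASE_LEVELS)
  if (length(m_specific)) {
    m_specific <- assert_integerish(m_specific, "m_specific")
    ms[names(m_specific)] <- m_specific
  }
  assert_scalar_num(sigma_effect, "sigma_effect", 0)
  assert_scalar_num(perturbation_fold, "perturbation_fold", 0,
                    strict = TRUE)
  assert_scalar_num(rate_floor_fraction, "rate_floor_fraction", 0,
                    strict = TRUE)
  if (rate_floor_fraction >= 1)
    stop("`rate_floor_fraction` must be in (0, 1)", call. = FALSE)
  mean_abund <- abundance_log_median * exp(abundance_log_sd^2 / 2)
  if (is.null(gamma)) {
    # expected across-cell sd of sum(a_i * (n_i - lambda_i)) at the
    # reference count: sigma_effect * sqrt(m_ref * E[lambda_i])
    sd_ref <- sigma_effect * sqrt(gamma_reference_m * mean_abund)
    gamma <- if (sd_ref > 0) gamma_cv_target * lambda0 / sd_ref
             else 0 * lambda0
  } else {
    gamma <- gamma[PHASE_LEVELS]
    if (anyNA(gamma) || any(gamma < 0))
      stop("`gamma` must be >= 0 and named over all phases", call. = FALSE)
  }
  structure(list(lambda0 = stats::setNames(as.numeric(lambda0),
                                           PHASE_LEVELS),
                 k = stats::setNames(k, PHASE_LEVELS),
                 coupled_phases = coupled_phases,
                 m_coupling = m_coupling, m_specific = ms,
                 gamma = stats::setNames(as.numeric(gamma), PHASE_LEVELS),
                 gamma_cv_target = gamma_cv_target,
                 gamma_reference_m = gamma_reference_m,
                 sigma_effect = sigma_effect,
                 abundance_log_median = abundance_log_median,
                 abundance_log_sd = abundance_log_sd,
                 perturbation_fold = perturbation_fold,
                 rate_floor_fraction = rate_floor_fraction,
                 n_cells = n_cells, n_sims = n_sims),
            class = "factor_model_params")
}

#' Draw a factor ensemble
#'
#' Realizes one ensemble: effect coefficients `a_{P,i} ~ N(0,
#' sigma_effect)` for each phase a factor touches (zero elsewhere - a
#' G1-specific factor has `a_S = 0` and vice versa), and mean abundances
#' `lambda_i` from the lognormal prior. Per-cell copy numbers are drawn
#' later by [simulate_factor_cells()].
#'
#' @param params a [factor_model_params()].
#' @param seed optional integer seed.
#' @return a `factor_ensemble`: list with coefficient matrix `a`
#'   (phases x factors), `abundance_mean`, and factor `type` labels
#'   (`"coupling"` or the specific phase).
#' @export
draw_factor_ensemble <- function(params, seed = NULL) {
  stopifnot(inherits(params, "factor_model_params"))
  with_seed_opt(seed, {
    m_total <- params$m_coupling + sum(params$m_specific)
    a <- matrix(0, nrow = 4, ncol = m_total,
                dimnames = list(PHASE_LEVELS, NULL))
    type <- character(m_total)
    col <- 0L
    if (params$m_coupling > 0) {
      idx <- col + seq_len(params$m_coupling)
      for (p in params$coupled_phases)
        a[p, idx] <- rnorm(params$m_coupling, 0, params$sigma_effect)
      type[idx] <- "coupling"
      col <- col + params$m_coupling
    }
    for (p in PHASE_LEVELS) {
      mp <- params$m_specific[[p]]
      if (mp > 0) {
        idx <- col + seq_len(mp)
        a[p, idx] <- rnorm(mp, 0, params$sigma_effect)
        type[idx] <- p
        col <- col + mp
      }
    }
    abundance_mean <- if (m_total > 0)
      rlnorm(m_total, meanlog = log(params$abundance_log_median),
             sdlog = params$abundance_log_sd)
    else numeric(0)
    structure(list(a = a, abundance_mean = abundance_mean, type = type),
              class = "factor_ensemble")
  })
}

#' Simulate cells under a factor ensemble
#'
#' Draws per-cell factor copy numbers (`Poisson(lambda_i)` by default, or
#' a truncated-rounded `Normal(lambda_i, lambda_i)` with
#' `abundance_model = "normal"`), modulates each phase's rate by the
#' centered factor term, floors rates at `rate_floor_fraction * lambda0`,
#' and draws each duration from the Erlang with the cell's rate.
#'
#' @param params a [factor_model_params()].
#' @param ensemble a [draw_factor_ensemble()] result (drawn fresh when
#'   `NULL`).
#' @param n_cells number of cells (defaults to `params$n_cells`).
#' @param seed optional integer seed.
#' @param abundance_model `"poisson"` or `"normal"` copy-number model.
#' @param condition condition label for the table.
#' @return list with `table` (a `phase_table`), `rates` (cells x phases
#'   matrix of realized rates) and `n_floored` (count of floored
#'   cell-phase rates).
#' @export
simulate_factor_cells <- function(params, ensemble = NULL,
                                  n_cells = params$n_cells, seed = NULL,
                                  abundance_model = c("poisson", "normal"),
                                  condition = "many_for_all") {
  stopifnot(inherits(params, "factor_model_params"))
  abundance_model <- match.arg(abundance_model)
  with_seed_opt(seed, {
    if (is.null(ensemble)) ensemble <- draw_factor_ensemble(params)
    m <- length(ensemble$abundance_mean)
    lam_i <- ensemble$abundance_mean
    if (m > 0) {
      N <- switch(abundance_model,
        poisson = matrix(rpois(n_cells * m, rep(lam_i, each = n_cells)),
                         n_cells, m),
        normal = matrix(round(pmax(0, rnorm(n_cells * m,
                                            rep(lam_i, each = n_cells),
                                            rep(sqrt(lam_i),
                                                each = n_cells)))),
                        n_cells, m))
      dev <- N - rep(lam_i, each = n_cells)
    }
    rates <- matrix(NA_real_, n_cells, 4,
                    dimnames = list(NULL, PHASE_LEVELS))
    n_floored <- 0L
    for (p in PHASE_LEVELS) {
      base <- params$lambda0[[p]]
      lam_cell <- if (m > 0)
        base + params$gamma[[p]] * as.numeric(dev %*% ensemble$a[p, ])
      else rep(base, n_cells)
      floor_p <- params$rate_floor_fraction * base
      fl <- lam_cell < floor_p
      n_floored <- n_floored + sum(fl)
      rates[, p] <- pmax(lam_cell, floor_p)
    }
    if (n_floored >= n_cells * 4L)
      stop("all rates hit the floor; `gamma` is too large for this ",
           "ensemble", call. = FALSE)
    d <- vapply(PHASE_LEVELS, function(p)
      rgamma(n_cells, shape = params$k[[p]], rate = rates[, p]),
      numeric(n_cells))
    d <- matrix(d, nrow = n_cells, dimnames = list(NULL, PHASE_LEVELS))
    list(table = build_phase_table_from_durations(d, condition,
                                                  DEFAULT_FRAME_H),
         rates = rates, n_floored = n_floored)
  })
}

#' @rdname simulate_factor_cells
#' @export
simulate_factor_cells_normal_abundance <- function(params, ensemble = NULL,
                                                   n_cells = params$n_cells,
                                                   seed = NULL,
                                                   condition =
                                                     "many_for_all") {
  simulate_factor_cells(params, ensemble, n_cells, seed,
                        abundance_model = "normal", condition = condition)
}

#' Amplify the dominant phase-coupling factor
#'
#' Models a targeted perturbation: among the coupling factors, selects the
#' type `i*` maximizing the product of effect coefficients on the first
#' two coupled phases (`a_{P1,i} * a_{P2,i}`, the factor with the largest
#' net coupling effect) and multiplies its mean abundance by `fold`
#' (copy numbers are then redrawn around the amplified mean when cells
#' are simulated; `mode = "copies"` instead records that realized copies
#' be scaled).
#'
#' @param ensemble a `factor_ensemble` with at least one coupling factor.
#' @param fold fold-change (default 10).
#' @param mode `"mean"` (amplify the mean abundance, default) or
#'   `"copies"`.
#' @param phases length-2 phases whose coefficient product is maximized;
#'   default the first two phases with nonzero coupling coefficients.
#' @return the modified `factor_ensemble` (with `perturbed_factor`
#'   attribute).
#' @export
perturb_single_factor <- function(ensemble, fold = 10,
                                  mode = c("mean", "copies"),
                                  phases = NULL) {
  stopifnot(inherits(ensemble, "factor_ensemble"))
  mode <- match.arg(mode)
  assert_scalar_num(fold, "fold", 0, strict = TRUE)
  idx <- which(ensemble$type == "coupling")
  if (!length(idx))
    stop("ensemble has no phase-coupling factors", call. = FALSE)
  if (is.null(phases)) {
    touched <- PHASE_LEVELS[rowSums(ensemble$a[, idx, drop = FALSE] != 0)
                            > 0]
    if (length(touched) < 2)
      stop("cannot identify two coupled phases", call. = FALSE)
    phases <- touched[1:2]
  }
  prod_ab <- ensemble$a[phases[1], idx] * ensemble$a[phases[2], idx]
  i_star <- idx[which.max(prod_ab)]
  if (mode == "mean") {
    ensemble$abundance_mean[i_star] <- fold *
      ensemble$abundance_mean[i_star]
  } else {
    ensemble$copy_scale <- stats::setNames(
      rep(1, length(ensemble$type)), NULL)
    ensemble$copy_scale[i_star] <- fold
  }
  ensemble$perturbed_factor <- i_star
  ensemble
}

#' Sweep coupling strength against the number of factor types
#'
#' For each factor-type count `m`, runs `n_sims` independent simulations
#' (fresh ensemble and cells each time; `n_cells` cells per simulation),
#' computes the squared Pearson correlation of the focal phase pair per
#' simulation, and reports the mean and standard deviation of `R^2`
#' across simulations. With `perturb = TRUE` each ensemble first has its
#' dominant coupling factor amplified by `params$perturbation_fold`.
#' Coupling weakens as `m` grows: no single factor dominates, so the net
#' effect of many independently varying factors dilutes each one's shared
#' control; adding phase-specific factors (via `params$m_specific`)
#' dilutes it further.
#'
#' @param params a [factor_model_params()]; `m_coupling` is overridden by
#'   each `m` in turn.
#' @param m_values factor-type counts to sweep.
#' @param n_sims simulations per `m` (defaults to `params$n_sims`).
#' @param seed optional integer seed.
#' @param perturb amplify the dominant coupling factor per ensemble.
#' @param pair phase pair whose `R^2` is tracked (default the coupled
#'   pair).
#' @return a `sweep_result` data frame: `m`, `mean_r2`, `sd_r2`,
#'   `n_sims`, `perturbed`.
#' @export
coupling_sweep <- function(params, m_values = c(1, 10, 100, 1000),
                           n_sims = params$n_sims, seed = NULL,
                           perturb = FALSE, pair = NULL) {
  stopifnot(inherits(params, "factor_model_params"))
  if (!length(m_values)) stop("`m_values` must be nonempty", call. = FALSE)
  m_values <- assert_integerish(m_values, "m_values")
  if (is.null(pair)) pair <- params$coupled_phases[1:2]
  if (n_sims < 2)
    warning("n_sims < 2: standard deviation of R^2 not estimable",
            call. = FALSE)
  seeds <- derive_seeds(seed, length(m_values))
  rows <- lapply(seq_along(m_values), function(j) {
    m <- m_values[j]
    pj <- params
    pj$m_coupling <- m
    sim_seeds <- derive_seeds(seeds[[j]], n_sims)
    r2 <- vapply(seq_len(n_sims), function(s) {
      with_seed_opt(sim_seeds[[s]], {
        ens <- draw_factor_ensemble(pj)
        if (perturb)
          ens <- perturb_single_factor(ens, fold = pj$perturbation_fold,
                                       phases = pair)
        cells <- simulate_factor_cells(pj, ens)
        cor(cells$table[[dur_col(pair[1])]],
            cells$table[[dur_col(pair[2])]])^2
      })
    }, numeric(1))
    data.frame(m = m, mean_r2 = mean(r2),
               sd_r2 = if (n_sims >= 2) sd(r2) else NA_real_,
               n_sims = n_sims, perturbed = perturb)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}
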