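#' Pearson coupling between two phase-duration vectors
#'
#' Computes the Pearson correlation `r`, its square `R^2`, the two-sided
#' p-value from the t-test for the Pearson coefficient, and applies the
#' coupling call policy: a pair is called `"coupled"` only when the
#' correlation is both significant (`p < p_threshold`, default 0.01) and
#' strong (`R^2 > r2_threshold`, default 0.1); significant-but-weak pairs
#' are `"weak"`; anything else is `"uncoupled"`.
#'
#' @param x,y paired duration vectors, length >= 3.
#' @param pair length-2 character label for the pair.
#' @param p_threshold significance threshold on the two-sided p-value.
#' @param r2_threshold effect-size threshold on `R^2`.
#' @return one-row data frame: `phase_a`, `phase_b`, `r`, `r2`, `p`, `n`,
#'   `call`.
#' @export
pearson_coupling <- function(x, y, pair = c("A", "B"),
                             p_threshold = 0.01, r2_threshold = 0.1) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in one of the inputs",
         call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  data.frame(phase_a = pair[1], phase_b = pair[2],
             r = r, r2 = r^2, p = ct$p.value, n = n,
             call = coupling_call(r^2, ct$p.value, p_threshold, r2_threshold),
             stringsAsFactors = FALSE)
}

coupling_call <- function(r2, p, p_threshold = 0.01, r2_threshold = 0.1) {
  if (p < p_threshold && r2 > r2_threshold) "coupled"
  else if (p < p_threshold) "weak"
  else "uncoupled"
}

#' All pairwise phase-duration couplings in a table
#'
#' One [pearson_coupling()] result per unordered phase pair. By default M
#' is excluded: its ~30 min duration is comparable to the acquisition
#' interval and contributes little variance.
#'
#' @param table a `phase_table` with duration columns.
#' @param phases phases to compare (default G1, S, G2).
#' @param p_adjust `"none"` (the per-pair policy, default) or
#'   `"bonferroni"` across the tested pairs.
#' @inheritParams pearson_coupling
#' @return data frame with one row per pair.
#' @export
all_pairwise_coupling <- function(table, phases = c("G1", "S", "G2"),
                                  p_threshold = 0.01, r2_threshold = 0.1,
                                  p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  table <- as_phase_table(table)
  phases <- match.arg(phases, PHASE_LEVELS, several.ok = TRUE)
  prs <- combn(phases, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    pearson_coupling(table[[dur_col(a)]], table[[dur_col(b)]],
                     pair = c(a, b), p_threshold = p_threshold,
                     r2_threshold = r2_threshold)
  }))
  if (p_adjust == "bonferroni") {
    out$p <- pmin(1, out$p * nrow(out))
    out$call <- mapply(coupling_call, out$r2, out$p,
                       MoreArgs = list(p_threshold = p_threshold,
                                       r2_threshold = r2_threshold))
  }
  out
}

#' Predicted correlation between a part and its sum
#'
#' For independent random variables B and C with A = B + C, the Pearson
#' correlation between the part B and the sum A has the closed form
#' \deqn{\rho_{A,B} = \frac{1}{\sqrt{1 + (\sigma_C/\sigma_B)^2}},}
#' always positive and increasing with B's share of A's variance. This is
#' why each phase correlates with total cycle duration even when phases
#' are mutually independent.
#'
#' @param sigma_b standard deviation of the part (hours), > 0.
#' @param sigma_c standard deviation of the remainder (hours), >= 0.
#' @return the predicted correlation.
#' @export
part_sum_correlation <- function(sigma_b, sigma_c) {
  assert_scalar_num(sigma_b, "sigma_b", 0, strict = TRUE)
  assert_scalar_num(sigma_c, "sigma_c", 0)
  1 / sqrt(1 + (sigma_c / sigma_b)^2)
}

#' Variance decomposition of total cell-cycle duration
#'
#' For each phase, the fraction of the variation in total cycle duration
#' attributed to it: the squared Pearson correlation between the phase
#' duration and the per-cell sum of all four phase durations. For mutually
#' independent phases these fractions equal each phase's variance share
#' and sum to ~1; correlated phases need not sum to 1.
#'
#' @param table a `phase_table` with all four durations per cell.
#' @return named numeric vector of `R^2` fractions, one per phase.
#' @export
variance_decomposition <- function(table) {
  table <- as_phase_table(table)
  d <- as.matrix(table[, DUR_COLS])
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 cells with all four phase durations",
         call. = FALSE)
  total <- rowSums(d)
  out <- apply(d, 2, function(col)
    if (sd(col) == 0) 0 else cor(col, total)^2)
  stats::setNames(out, PHASE_LEVELS)
}

# split a table with sister links into a pairs data frame (one row per
# unordered pair), sister order randomized per pair to avoid labeling bias
sister_pairs_frame <- function(table, seed = NULL) {
  table <- as_phase_table(table)
  has <- !is.na(table$sister_id)
  ids <- table$cell_id[has]
  sis <- table$sister_id[has]
  first <- ids < sis # each unordered pair once
  a <- ids[first]; b <- sis[first]
  if (length(a) < 1) stop("table contains no sister pairs", call. = FALSE)
  flip <- with_seed_opt(seed, runif(length(a)) < 0.5)
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  ia <- match(a, table$cell_id)
  ib <- match(b, table$cell_id)
  out <- data.frame(cell_a = a, cell_b = b, stringsAsFactors = FALSE)
  for (p in PHASE_LEVELS) {
    out[[paste0(tolower(p), "_a")]] <- table[[dur_col(p)]][ia]
    out[[paste0(tolower(p), "_b")]] <- table[[dur_col(p)]][ib]
  }
  out
}

#' Per-phase correlation between sister cells
#'
#' Pearson correlation of each phase's duration between sisters (one value
#' per phase), the classic heritability signature.
#'
#' @param table a `phase_table` with symmetric `sister_id` links.
#' @param phases phases to evaluate.
#' @param seed optional seed for the per-pair sister-order randomization.
#' @return named numeric vector of correlations.
#' @export
sister_phase_correlation <- function(table, phases = c("G1", "S", "G2"),
                                     seed = NULL) {
  pf <- sister_pairs_frame(table, seed = seed)
  vapply(phases, function(p) {
    a <- pf[[paste0(tolower(p), "_a")]]
    b <- pf[[paste0(tolower(p), "_b")]]
    ok <- stats::complete.cases(a, b)
    cor(a[ok], b[ok])
  }, numeric(1))
}

#' Coupling between sister-difference signals across phases
#'
#' For each pair of distinct phases (P, Q), correlates the within-pair
#' difference `dP(sister1) - dP(sister2)` with the corresponding `dQ`
#' difference across sister pairs. If heritable factors assort into
#' daughters independently, these difference signals are uncorrelated even
#' when the phase durations themselves are strongly heritable;
#' interdependent assortment couples them.
#'
#' @inheritParams sister_phase_correlation
#' @inheritParams pearson_coupling
#' @return data frame of [pearson_coupling()] rows, one per phase pair.
#' @export
sibling_difference_coupling <- function(table, phases = c("G1", "S", "G2"),
                                        seed = NULL, p_threshold = 0.01,
                                        r2_threshold = 0.1) {
  pf <- sister_pairs_frame(table, seed = seed)
  if (nrow(pf) < 3) stop("need at least 3 sister pairs", call. = FALSE)
  deltas <- lapply(phases, function(p)
    pf[[paste0(tolower(p), "_a")]] - pf[[paste0(tolower(p), "_b")]])
  names(deltas) <- phases
  prs <- combn(phases, 2)
  do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    res <- pearson_coupling(deltas[[a]], deltas[[b]],
                            pair = c(paste0("d", a), paste0("d", b)),
                            p_threshold = p_threshold,
                            r2_threshold = r2_threshold)
    res
  }))
}

#' Noise-injection bootstrap for a phase-pair correlation
#'
#' Recomputes the Pearson correlation of a phase pair under repeated
#' injection of measurement noise. Every replicate uses all N cells (the
#' "selected without replacement with N = sample size" scheme, in which
#' variability comes only from the injected noise; set
#' `replace = TRUE` for a conventional with-replacement bootstrap). Each
#' cell's phase duration receives an independent noise term per phase and
#' per replicate,
#' \deqn{\epsilon_{total} = \epsilon_{begin} + \epsilon_{end},\qquad
#'   \epsilon \sim \mathrm{Uniform}(-0.5, 0.5)\times T\,\delta,}
#' where `T` is the frame interval and `delta` the frame-error multiplier
#' (default 3, covering +/- 1 frame identification accuracy on top of the
#' within-frame transition-timing uncertainty). The two-level loop of
#' `n_outer` x `n_inner` replicates yields `n_outer * n_inner` R values
#' (10,000 at the defaults), summarized by the fraction with `R^2` below
#' the strength threshold.
#'
#' Durations pushed to zero or below by the noise are clamped at one frame
#' interval and counted.
#'
#' @param table a `phase_table`.
#' @param pair length-2 character vector of phases, e.g. `c("G1","S")`.
#' @param n_outer,n_inner replicate counts (defaults 100 x 100).
#' @param delta frame-error multiplier (>= 0; 0 disables noise, making
#'   every replicate equal to the point estimate).
#' @param t_frame frame interval `T` in hours.
#' @param seed optional integer seed.
#' @param replace resample cells with replacement per replicate.
#' @param r2_threshold threshold defining "no strong correlation".
#' @return list with `r` (all replicate correlations),
#'   `frac_uncoupled` = fraction with `R^2 < r2_threshold`,
#'   `point_estimate`, `n_clamped`, and the configuration.
#' @export
noise_bootstrap_correlations <- function(table, pair = c("G1", "S"),
                                         n_outer = 100, n_inner = 100,
                                         delta = 3,
                                         t_frame = DEFAULT_FRAME_H,
                                         seed = NULL, replace = FALSE,
                                         r2_threshold = 0.1) {
  n_outer <- assert_integerish(n_outer, "n_outer")
  n_inner <- assert_integerish(n_inner, "n_inner")
  if (n_outer < 1 || n_inner < 1)
    stop("replicate counts must be >= 1", call. = FALSE)
  assert_scalar_num(delta, "delta", 0)
  assert_scalar_num(t_frame, "t_frame", 0, strict = TRUE)
  table <- as_phase_table(table)
  pair <- match.arg(pair, PHASE_LEVELS, several.ok = TRUE)
  if (length(pair) != 2) stop("`pair` must name two phases", call. = FALSE)
  x <- table[[dur_col(pair[1])]]
  y <- table[[dur_col(pair[2])]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete cells", call. = FALSE)
  point <- cor(x, y)
  n_rep <- n_outer * n_inner
  amp <- t_frame * delta

  res <- with_seed_opt(seed, {
    n_clamped <- 0L
    r <- numeric(n_rep)
    for (b in seq_len(n_rep)) {
      idx <- if (replace) sample.int(n, n, replace = TRUE) else seq_len(n)
      # begin + end noise, drawn independently per phase and per cell
      ex <- (runif(n, -0.5, 0.5) + runif(n, -0.5, 0.5)) * amp
      ey <- (runif(n, -0.5, 0.5) + runif(n, -0.5, 0.5)) * amp
      xb <- x[idx] + ex
      yb <- y[idx] + ey
      bad <- xb <= 0 | yb <= 0
      if (any(bad)) {
        n_clamped <- n_clamped + sum(xb <= 0) + sum(yb <= 0)
        xb <- pmax(xb, t_frame)
        yb <- pmax(yb, t_frame)
      }
      r[b] <- cor(xb, yb)
    }
    list(r = r, n_clamped = n_clamped)
  })
  if (res$n_clamped > 0)
    message(res$n_clamped, " noised durations clamped at one frame interval")
  list(r = res$r, frac_uncoupled = mean(res$r^2 < r2_threshold),
       point_estimate = point, n_clamped = res$n_clamped,
       config = list(pair = pair, n_outer = n_outer, n_inner = n_inner,
                     delta = delta, t_frame = t_frame, n = n,
                     replace = replace, r2_threshold = r2_threshold,
                     seed = seed))
}

#' Sample size required to detect a correlation (Fisher z method)
#'
#' Number of cells needed so that a true correlation of magnitude
#' `sqrt(r2_threshold)` is detected with the given power at two-sided
#' level `alpha`:
#' \deqn{n = \left\lceil \left(\frac{z_{1-\alpha/2} + z_{power}}
#'   {\mathrm{atanh}(\sqrt{R^2})}\right)^2 + 3 \right\rceil.}
#' At `r2_threshold = 0.1`, `alpha = 0.01`, `power = 0.80` this gives 112
#' cells per condition. The +3 term is the small-sample correction of the
#' Fisher z variance; the result is rounded up.
#'
#' @param r2_threshold smallest `R^2` worth detecting, in (0, 1).
#' @param alpha two-sided type I error rate.
#' @param power target power (1 - type II error rate).
#' @return required sample size (integer).
#' @export
sample_size_for_correlation <- function(r2_threshold, alpha = 0.01,
                                        power = 0.8) {
  assert_scalar_num(r2_threshold, "r2_threshold", 0, strict = TRUE)
  if (r2_threshold >= 1) stop("`r2_threshold` must be < 1", call. = FALSE)
  for (v in c(alpha = alpha, power = power))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("`alpha` and `power` must lie in (0, 1)", call. = FALSE)
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  cstar <- atanh(sqrt(r2_threshold))
  as.integer(ceiling((z / cstar)^2 + 3))
}
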