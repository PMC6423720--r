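#' Synthesize a 1-D reporter trace for one cell
#'
#' Builds an idealized single-cell reporter time series from a cell's
#' phase durations, frame by frame (frame 0 at birth), for testing the
#' event detectors:
#'
#' * `pcna_variance`: the spatial-variance signal of a PCNA reporter -
#'   punctate foci during S phase give a high plateau; G1 and G2 are low
#'   plateaus (levels 1 and 3 in arbitrary units).
#' * `pip_mvenus`: a degron reporter that is high in G1 (level 100),
#'   rapidly degraded at S onset (fast exponential fall to the S plateau,
#'   level 5), and re-accumulates linearly from G2 onset.
#'
#' Additive Gaussian noise with sd `noise_sd` times the dynamic range is
#' applied. True boundary frames (first frame at or after each
#' transition) are recorded as ground truth; a trace whose G1 or S phase
#' is shorter than one frame is flagged unresolvable.
#'
#' @param durations named list or one-row `phase_table` providing
#'   `d_g1_h`, `d_s_h`, `d_g2_h` (hours).
#' @param kind `"pcna_variance"` or `"pip_mvenus"`.
#' @param noise_sd noise sd as a fraction of the dynamic range (>= 0).
#' @param seed optional integer seed.
#' @param frame_interval frame interval in hours.
#' @param cell_id trace label.
#' @return a `trace_series` data frame (`frame` 0-based, `time_h`,
#'   `signal`) with attributes `kind`, `frame_interval`, `truth` (list of
#'   true boundary frames) and `resolvable`.
#' @export
simulate_reporter_trace <- function(durations,
                                    kind = c("pcna_variance",
                                             "pip_mvenus"),
                                    noise_sd = 0.05, seed = NULL,
                                    frame_interval = DEFAULT_FRAME_H,
                                    cell_id = "trace") {
  kind <- match.arg(kind)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(frame_interval, "frame_interval", 0, strict = TRUE)
  if (is.data.frame(durations)) durations <- as.list(durations[1, ])
  d_g1 <- durations$d_g1_h
  d_s <- durations$d_s_h
  d_g2 <- durations$d_g2_h
  if (any(c(d_g1, d_s, d_g2) <= 0))
    stop("durations must be positive", call. = FALSE)
  dt <- frame_interval
  total <- d_g1 + d_s + d_g2
  n_frames <- floor(total / dt) + 1
  t <- (seq_len(n_frames) - 1) * dt
  t_s0 <- d_g1
  t_s1 <- d_g1 + d_s
  resolvable <- d_g1 >= dt && d_s >= 2 * dt && d_g2 >= 2 * dt

  if (kind == "pcna_variance") {
    lo <- 1; hi <- 3
    signal <- ifelse(t >= t_s0 & t < t_s1, hi, lo)
    range_ <- hi - lo
    truth <- list(s_onset_frame = as.integer(ceiling(t_s0 / dt)),
                  s_end_frame = as.integer(ceiling(t_s1 / dt)))
  } else {
    g1_level <- 100; s_level <- 5
    signal <- numeric(n_frames)
    g1_idx <- t < t_s0
    s_idx <- t >= t_s0 & t < t_s1
    g2_idx <- t >= t_s1
    signal[g1_idx] <- g1_level
    # fast degradation: by the first frame inside S the signal is already
    # far below the 50% mark
    signal[s_idx] <- s_level + (g1_level - s_level) *
      exp(-(t[s_idx] - t_s0 + dt) / (0.5 * dt))
    signal[g2_idx] <- pmin(g1_level, s_level +
                             10 * (t[g2_idx] - t_s1 + dt) / dt)
    range_ <- g1_level - s_level
    truth <- list(s_onset_frame = as.integer(ceiling(t_s0 / dt)),
                  g2_onset_frame = as.integer(ceiling(t_s1 / dt)))
  }
  if (noise_sd > 0)
    signal <- signal + with_seed_opt(seed,
                                     rnorm(n_frames, 0,
                                           noise_sd * range_))
  structure(data.frame(frame = seq_len(n_frames) - 1L, time_h = t,
                       signal = signal),
            cell_id = cell_id, kind = kind, frame_interval = dt,
            truth = truth, resolvable = resolvable,
            class = c("trace_series", "data.frame"))
}

#' Synthesize traces for every cell of a phase table
#'
#' @param table a `phase_table` with G1, S, G2 durations.
#' @inheritParams simulate_reporter_trace
#' @return list with `traces` (list of `trace_series`) and `truth`
#'   (data frame of ground-truth boundary frames per cell).
#' @export
simulate_trace_set <- function(table, kind = c("pcna_variance",
                                               "pip_mvenus"),
                               noise_sd = 0.05, seed = NULL,
                               frame_interval = DEFAULT_FRAME_H) {
  kind <- match.arg(kind)
  table <- as_phase_table(table)
  seeds <- derive_seeds(seed, nrow(table))
  traces <- lapply(seq_len(nrow(table)), function(i)
    simulate_reporter_trace(
      list(d_g1_h = table$d_g1_h[i], d_s_h = table$d_s_h[i],
           d_g2_h = table$d_g2_h[i]),
      kind = kind, noise_sd = noise_sd, seed = seeds[[i]],
      frame_interval = frame_interval, cell_id = table$cell_id[i]))
  truth <- do.call(rbind, lapply(traces, function(tr) {
    tt <- attr(tr, "truth")
    data.frame(cell_id = attr(tr, "cell_id"),
               event1_frame = tt[[1]], event2_frame = tt[[2]],
               resolvable = attr(tr, "resolvable"),
               stringsAsFactors = FALSE)
  }))
  list(traces = traces, truth = truth)
}

# centered moving average with edge padding
smooth_ma <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  h <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / window, window),
                           sides = 2))[(h + 1):(h + length(x))]
}

# first run of >=`len` consecutive TRUE starting at/after `from`
first_sustained <- function(flag, from = 1L, len = 2L) {
  n <- length(flag)
  if (from > n - len + 1L) return(NA_integer_)
  for (i in from:(n - len + 1L))
    if (all(flag[i:(i + len - 1L)])) return(i)
  NA_integer_
}

#' Call S-phase boundaries from a PCNA-variance trace
#'
#' Detects S phase as the low-to-high and subsequent high-to-low
#' transitions of the (smoothed) variance signal: plateau levels are
#' estimated from the smoothed signal's lower and upper tails, and a
#' boundary is the first crossing of their midpoint sustained for at
#' least two frames (suppressing single-frame noise spikes). Calls are
#' affine-invariant in the signal and returned as 0-based frame indices,
#' the onset frame being the first frame inside the new phase.
#'
#' @param trace a `trace_series` of kind `pcna_variance` (or any data
#'   frame with `frame` and `signal`).
#' @param smoothing_window moving-average window in frames (odd; default
#'   3).
#' @return list with `cell_id`, `s_onset_frame`, `s_end_frame`,
#'   `no_call` flag and `reason`.
#' @export
call_s_phase_pcna <- function(trace, smoothing_window = 3) {
  sig <- trace$signal
  frames <- trace$frame
  no_call <- function(reason)
    list(cell_id = attr(trace, "cell_id") %||% NA_character_,
         s_onset_frame = NA_integer_, s_end_frame = NA_integer_,
         no_call = TRUE, reason = reason)
  if (length(sig) < 3) return(no_call("trace too short"))
  x <- smooth_ma(sig, smoothing_window)
  lo <- quantile(x, 0.05, names = FALSE)
  hi <- quantile(x, 0.95, names = FALSE)
  noise <- stats::mad(diff(x)) / sqrt(2)
  if (!(hi - lo > 3 * noise) || hi - lo <= 0)
    return(no_call("no distinct low/high plateaus"))
  mid <- (lo + hi) / 2
  above <- x > mid
  on <- first_sustained(above, from = 1L)
  if (is.na(on)) return(no_call("no sustained upward crossing"))
  off <- first_sustained(!above, from = on + 1L)
  if (is.na(off)) return(no_call("no sustained downward crossing"))
  list(cell_id = attr(trace, "cell_id") %||% NA_character_,
       s_onset_frame = frames[on], s_end_frame = frames[off],
       no_call = FALSE, reason = NA_character_)
}

#' Call S and G2 onsets from a PIP-degron trace
#'
#' Applies the degron-reporter rules: S onset is the first frame at which
#' the signal has lost 50% of its G1 level; G2 onset is the first
#' subsequent frame exceeding the S-phase level by 2% of the maximum
#' signal. Plateau levels are estimated in two passes (provisional
#' crossing, refine the plateau medians, final crossing).
#'
#' @param trace a `trace_series` of kind `pip_mvenus`.
#' @param smoothing_window moving-average window in frames (default 3).
#' @return list with `cell_id`, `s_onset_frame`, `g2_onset_frame`,
#'   `no_call`, `reason`.
#' @export
call_phases_pip <- function(trace, smoothing_window = 3) {
  sig <- trace$signal
  frames <- trace$frame
  no_call <- function(reason)
    list(cell_id = attr(trace, "cell_id") %||% NA_character_,
         s_onset_frame = NA_integer_, g2_onset_frame = NA_integer_,
         no_call = TRUE, reason = reason)
  n <- length(sig)
  if (n < 3) return(no_call("trace too short"))
  # plateau levels are estimated on a smoothed copy; the threshold
  # crossings themselves use the raw signal so that step edges are not
  # smeared across frames
  x <- smooth_ma(sig, smoothing_window)
  # pass 1: provisional G1 level from the initial frames
  g1_prov <- median(x[seq_len(min(5L, n))])
  on_prov <- which(sig < 0.5 * g1_prov)[1]
  if (is.na(on_prov) || on_prov < 2)
    return(no_call("signal never drops below 50% of the G1 level"))
  # pass 2: refined G1 level from the pre-onset plateau
  g1_level <- median(x[seq_len(on_prov - 1L)])
  on <- which(sig < 0.5 * g1_level)[1]
  if (is.na(on) || on < 2)
    return(no_call("signal never drops below 50% of the G1 level"))
  if (on + 1L >= n) return(no_call("no frames after S onset"))
  s_prov <- quantile(x[(on + 1L):n], 0.2, names = FALSE)
  thr <- s_prov + 0.02 * max(sig)
  # only look for the G2 rise once the degradation tail has settled
  # below the threshold
  settle <- first_sustained(sig < thr, from = on)
  if (is.na(settle))
    return(no_call("signal never settles onto an S-phase plateau"))
  rise_prov <- first_sustained(sig > thr, from = settle + 1L)
  if (is.na(rise_prov))
    return(no_call("no rise above the S-phase level"))
  # refine the S plateau as the median between settling and the
  # provisional rise
  if (rise_prov - settle >= 2) {
    s_level <- median(sig[settle:(rise_prov - 1L)])
    thr <- s_level + 0.02 * max(sig)
    rise <- first_sustained(sig > thr, from = settle + 1L)
    if (is.na(rise)) rise <- rise_prov
  } else rise <- rise_prov
  list(cell_id = attr(trace, "cell_id") %||% NA_character_,
       s_onset_frame = frames[on], g2_onset_frame = frames[rise],
       no_call = FALSE, reason = NA_character_)
}

#' Call events on a set of traces
#'
#' @param traces list of `trace_series`.
#' @param kind detector to apply; `NULL` reads each trace's `kind`
#'   attribute.
#' @param ... passed to the detector.
#' @return data frame with one row per trace: `cell_id`,
#'   `event1_frame`, `event2_frame`, `no_call`, `reason`.
#' @export
call_trace_events <- function(traces, kind = NULL, ...) {
  do.call(rbind, lapply(traces, function(tr) {
    k <- kind %||% attr(tr, "kind")
    res <- switch(k,
                  pcna_variance = call_s_phase_pcna(tr, ...),
                  pip_mvenus = call_phases_pip(tr, ...),
                  stop("unknown trace kind: ", k, call. = FALSE))
    data.frame(cell_id = res$cell_id,
               event1_frame = res[[2]], event2_frame = res[[3]],
               no_call = res$no_call, reason = res$reason,
               stringsAsFactors = FALSE)
  }))
}

#' Evaluate event calls against ground truth
#'
#' @param calls data frame from [call_trace_events()] (columns `cell_id`,
#'   `event1_frame`, `event2_frame`, `no_call`).
#' @param truth ground-truth data frame (`cell_id`, `event1_frame`,
#'   `event2_frame`).
#' @return list with per-event error vectors, `frac_within_1` (fraction
#'   of called boundaries within +/- 1 frame of truth), `no_call_rate`,
#'   `mean_abs_error`, and the joined `errors` data frame.
#' @export
evaluate_calls <- function(calls, truth) {
  unmatched <- setdiff(calls$cell_id, truth$cell_id)
  if (length(unmatched))
    stop("calls with no matching ground truth: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  idx <- match(calls$cell_id, truth$cell_id)
  e1 <- calls$event1_frame - truth$event1_frame[idx]
  e2 <- calls$event2_frame - truth$event2_frame[idx]
  called <- !calls$no_call
  errs <- c(e1[called], e2[called])
  list(errors = data.frame(cell_id = calls$cell_id,
                           event1_error = e1, event2_error = e2,
                           no_call = calls$no_call,
                           stringsAsFactors = FALSE),
       frac_within_1 = if (length(errs)) mean(abs(errs) <= 1) else NA_real_,
       no_call_rate = mean(calls$no_call),
       mean_abs_error = if (length(errs)) mean(abs(errs)) else NA_real_)
}
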