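# build a one-row event-time data frame from five event times (hours)
event_df <- function(times, cell_id = "c1", frame_interval = 1 / 6) {
  data.frame(cell_id = cell_id, condition = "test",
             frame_interval_h = frame_interval,
             t_birth_h = times[1], t_s_onset_h = times[2],
             t_s_end_h = times[3], t_m_start_h = times[4],
             t_telophase_h = times[5], stringsAsFactors = FALSE)
}

# small valid duration-only table
small_duration_table <- function(n = 3) {
  as_phase_table(data.frame(
    cell_id = sprintf("c%d", seq_len(n)), condition = "test",
    d_g1_h = 7 + seq_len(n) / 10, d_s_h = 10 + seq_len(n) / 10,
    d_g2_h = 3 + seq_len(n) / 10, d_m_h = 0.5,
    stringsAsFactors = FALSE))
}

# noiseless rectangular PCNA-variance trace: low/high plateaus with the
# high phase spanning frames [step_up, step_down)
rect_trace <- function(n_frames = 60, step_up = 10, step_down = 40,
                       lo = 1, hi = 3, frame_interval = 1 / 6,
                       cell_id = "t1") {
  f <- seq_len(n_frames) - 1L
  structure(data.frame(frame = f, time_h = f * frame_interval,
                       signal = ifelse(f >= step_up & f < step_down,
                                       hi, lo)),
            cell_id = cell_id, kind = "pcna_variance",
            frame_interval = frame_interval,
            class = c("trace_series", "data.frame"))
}

# hand-built PIP-degron trace: G1 plateau 100 (frames 0-9), linear fall
# 80/60/40/20 (frames 10-13, first frame below 50 is 12), S plateau 5
# (frames 14-53), rise 6.5 at 54, 7.5 at 55 (first frame above the
# 5 + 0.02*100 = 7 threshold), then continuing up
pip_fixture_trace <- function(frame_interval = 1 / 6) {
  sig <- c(rep(100, 10), 80, 60, 40, 20, rep(5, 40),
           6.5, 7.5, 10, 13, 16, 19, 22, 25, 28, 31, 34, 37, 40, 43, 46)
  f <- seq_along(sig) - 1L
  structure(data.frame(frame = f, time_h = f * frame_interval,
                       signal = sig),
            cell_id = "pip1", kind = "pip_mvenus",
            frame_interval = frame_interval,
            class = c("trace_series", "data.frame"))
}
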