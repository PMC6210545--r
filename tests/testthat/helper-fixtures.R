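# Fixtures are generated in code; nothing is stored on disk.

# Unstructured random trace: components uniform in [-2, 2] G, random labels.
random_trace <- function(n, seed, rate_hz = 31.25, fall_frac = 0.2) {
  set.seed(seed)
  accel_trace(
    t = (seq_len(n) - 1) / rate_hz,
    ax = round(runif(n, -2, 2), 6),
    ay = round(runif(n, -2, 2), 6),
    az = round(runif(n, -2, 2), 6),
    label = ifelse(runif(n) < fall_frac, "Fall", "NotFall"),
    rate_hz = rate_hz
  )
}

# Independent run-length oracle for the consecutive-count rule, built on
# rle() rather than the detector's counter loop.
oracle_run_events <- function(labels, min_count = 3, max_count = 50) {
  r <- rle(labels == "Fall")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_count & r$lengths <= max_count
  data.frame(start_idx = starts[keep] - 1L, end_idx = ends[keep])
}

# Cleanly separable feature rows for classifier tests: fall rows swing
# several G inside the window, ADL rows barely move.
separable_features <- function(n_fall = 60, n_adl = 140, seed = 1) {
  set.seed(seed)
  fall <- data.frame(
    a_res = runif(n_fall, 3, 6), s_min = runif(n_fall, 0.1, 0.4),
    s_max = runif(n_fall, 4, 6.5), label = "Fall"
  )
  fall$delta_s <- fall$s_max - fall$s_min
  adl <- data.frame(
    a_res = runif(n_adl, 0.9, 1.2), s_min = runif(n_adl, 0.8, 1.0),
    s_max = runif(n_adl, 1.0, 1.3), label = "NotFall"
  )
  adl$delta_s <- adl$s_max - adl$s_min
  rbind(fall, adl)[, c("a_res", "s_min", "s_max", "delta_s", "label")]
}

# Tiny quickly-separable labelled traces for GRU tests: quiet ADL baseline
# vs unmistakable high-peak falls.
small_labelled_traces <- function(n_sessions = 2, seed = 1) {
  lapply(seq_len(n_sessions), function(i) {
    simulate_session(sim_session_config(
      falls_per_type = 1, fall_to_adl_ratio = 2, tagged = FALSE,
      adl_mix = c(sitting = 1, walking = 1),
      seed = seed * 100 + i
    ))
  })
}
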