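# Handcrafted features for the traditional classifiers: resultant
# acceleration (Ares) plus min / max / swing of the resultant over a
# 750 ms sliding window with 50% overlap.

#' Sliding-window feature configuration
#'
#' Window length in samples is `floor(window_ms / 1000 * rate_hz)` and the
#' hop between window starts is `floor(window_len * (1 - overlap_frac))`.
#' At the 31.25 Hz smartwatch rate the defaults give a 23-sample window and
#' an 11-sample hop.
#'
#' @param window_ms Window length in milliseconds (default 750).
#' @param overlap_frac Fractional overlap between consecutive windows,
#'   in `[0, 1)` (default 0.5).
#' @param rate_hz Sampling rate in Hz (default 31.25).
#' @return A `feature_config` list with the derived `window_len` and `hop`.
#' @export
feature_config <- function(window_ms = 750, overlap_frac = 0.5, rate_hz = 31.25) {
  assert_scalar_number(window_ms, "window_ms", positive = TRUE)
  assert_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  assert_scalar_number(overlap_frac, "overlap_frac")
  if (overlap_frac < 0 || overlap_frac >= 1) stopf("`overlap_frac` must be in [0, 1)")
  window_len <- floor(window_ms / 1000 * rate_hz)
  if (window_len < 2) stopf("window of %g ms at %g Hz holds fewer than 2 samples", window_ms, rate_hz)
  hop <- max(1L, floor(window_len * (1 - overlap_frac)))
  structure(
    list(window_ms = window_ms, overlap_frac = overlap_frac, rate_hz = rate_hz,
         window_len = as.integer(window_len), hop = as.integer(hop)),
    class = "feature_config"
  )
}

#' Euclidean norm of a 3-vector
#'
#' @param v Numeric vector of length 3 (finite components), in G.
#' @return `sqrt(vx^2 + vy^2 + vz^2)`.
#' @export
euclidean_norm <- function(v) {
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v))) {
    stopf("`v` must be a finite numeric 3-vector")
  }
  # spelt out (not sum()) so scalar and vectorized paths share identical
  # floating-point association
  sqrt(v[[1]]^2 + v[[2]]^2 + v[[3]]^2)
}

#' Resultant acceleration series of a trace
#'
#' Element `i` is the Euclidean norm of sample `i`'s acceleration vector
#' (Ares), so the series preserves the trace length.
#'
#' @param trace An [accel_trace()].
#' @return Numeric vector of per-sample resultants in G.
#' @export
resultant_series <- function(trace) {
  validate_accel_trace(trace)
  sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
}

#' Per-window min/max/swing of a resultant series
#'
#' Tiles the series with windows of the configured length and hop (0-based,
#' half-open index ranges) and reports `s_min`, `s_max` and their difference
#' `delta_s` for each window.
#'
#' @param series Numeric resultant series (e.g. from [resultant_series()]).
#' @param cfg A [feature_config()].
#' @return Data frame with columns `window_start`, `window_end` (0-based,
#'   half-open), `s_min`, `s_max`, `delta_s`.
#' @export
window_features <- function(series, cfg = feature_config()) {
  if (!inherits(cfg, "feature_config")) stopf("`cfg` must be a feature_config")
  n <- length(series)
  w <- cfg$window_len
  if (n < w) stopf("series of length %d is shorter than one %d-sample window", n, w)
  starts <- seq.int(1L, n - w + 1L, by = cfg$hop)
  s_min <- vapply(starts, function(s) min(series[s:(s + w - 1L)]), numeric(1))
  s_max <- vapply(starts, function(s) max(series[s:(s + w - 1L)]), numeric(1))
  data.frame(
    window_start = starts - 1L,
    window_end = starts - 1L + w,
    s_min = s_min, s_max = s_max, delta_s = s_max - s_min
  )
}

#' Per-sample feature rows (batch)
#'
#' Attaches to every sample its own resultant `a_res` together with the
#' `s_min`/`s_max`/`delta_s` of the most recent *completed* window at that
#' sample (causal assignment, so the same rows can be produced one sample at
#' a time in a live stream). Samples before the first complete window — the
#' warm-up prefix of `window_len - 1` samples — are not emitted.
#'
#' @param trace An [accel_trace()], at least one window long.
#' @param cfg A [feature_config()]; its `rate_hz` should match the trace.
#' @return Data frame with columns `idx` (0-based sample index), `a_res`,
#'   `s_min`, `s_max`, `delta_s`, `label`, `activity`.
#' @seealso [feature_stream()] for the streaming equivalent.
#' @export
per_sample_features <- function(trace, cfg = feature_config(rate_hz = trace_rate(trace))) {
  validate_accel_trace(trace)
  series <- resultant_series(trace)
  n <- length(series)
  w <- cfg$window_len
  if (n < w) stopf("trace of %d samples is shorter than one %d-sample window", n, w)
  wf <- window_features(series, cfg)
  # window j completes at 0-based index wf$window_end[j] - 1; it governs
  # samples from there until the next window completes.
  comp <- wf$window_end - 1L
  idx0 <- seq.int(w - 1L, n - 1L)
  assign_w <- findInterval(idx0, comp)
  data.frame(
    idx = idx0,
    a_res = series[idx0 + 1L],
    s_min = wf$s_min[assign_w],
    s_max = wf$s_max[assign_w],
    delta_s = wf$delta_s[assign_w],
    label = trace$label[idx0 + 1L],
    activity = trace$activity[idx0 + 1L],
    stringsAsFactors = FALSE
  )
}

#' Streaming per-sample feature extractor
#'
#' Creates a mutable extractor for live use: feed samples one at a time with
#' [stream_push()]; each call returns the feature row for that sample (or
#' `NULL` during warm-up). The emitted rows are identical to the batch rows
#' of [per_sample_features()].
#'
#' @param cfg A [feature_config()].
#' @return A `feature_stream` object.
#' @export
feature_stream <- function(cfg = feature_config()) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$i <- -1L            # 0-based index of the last pushed sample
  st$buf <- numeric(0)   # trailing resultants, at most window_len long
  st$next_start <- 0L    # 0-based start of the next window to complete
  st$cur <- NULL         # stats of the most recent completed window
  structure(st, class = "feature_stream")
}

#' Push one sample into a streaming feature extractor
#'
#' @param stream A [feature_stream()].
#' @param ax,ay,az Acceleration components of the new sample, in G.
#' @param label,activity Optional per-sample annotations copied to the row.
#' @return The feature row for this sample as a named list (`idx`, `a_res`,
#'   `s_min`, `s_max`, `delta_s`, `label`, `activity`), or `NULL` while the
#'   first window is still filling. A list rather than a data frame keeps
#'   per-sample overhead compatible with live 31.25 Hz streams.
#' @export
stream_push <- function(stream, ax, ay, az, label = NA_character_,
                        activity = NA_character_) {
  cfg <- stream$cfg
  w <- cfg$window_len
  stream$i <- stream$i + 1L
  a_res <- euclidean_norm(c(ax, ay, az))
  stream$buf <- c(stream$buf, a_res)
  if (length(stream$buf) > w) stream$buf <- stream$buf[-1L]
  # does a window complete at this sample? window starting at next_start
  # completes at next_start + w - 1
  if (stream$i == stream$next_start + w - 1L) {
    stream$cur <- list(s_min = min(stream$buf), s_max = max(stream$buf))
    stream$next_start <- stream$next_start + cfg$hop
  }
  if (is.null(stream$cur)) return(NULL)
  list(
    idx = stream$i, a_res = a_res,
    s_min = stream$cur$s_min, s_max = stream$cur$s_max,
    delta_s = stream$cur$s_max - stream$cur$s_min,
    label = label, activity = activity
  )
}
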