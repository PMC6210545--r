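#' Labelled tri-axial accelerometer trace
#'
#' An `accel_trace` is the universal currency of the toolkit: an ordered,
#' uniformly-labelled stream of tri-axial acceleration samples in units of G
#' (1 G = standard gravity, so a resting wrist shows a resultant near 1).
#' It is a data frame with columns `t` (seconds, strictly increasing), `ax`,
#' `ay`, `az` (G), `label` (`"Fall"` or `"NotFall"`) and `activity`
#' (optional ADL tag, `NA` when untagged), plus attributes `rate_hz`
#' (nominal sampling rate), `subject_id` and `source`.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param ax,ay,az Numeric acceleration components in G; finite.
#' @param label Character vector of per-sample labels, `"Fall"`/`"NotFall"`.
#' @param activity Optional character vector of ADL tags (`NA` = untagged).
#' @param rate_hz Nominal sampling rate in Hz (> 0).
#' @param subject_id Opaque subject identifier.
#' @param source One of `"smartwatch"`, `"notch"`, `"farseeing"`, `"synthetic"`.
#'
#' @return An object of class `accel_trace` (a data frame).
#' @examples
#' tr <- accel_trace(
#'   t = (0:4) / 31.25, ax = rep(0, 5), ay = rep(0, 5), az = rep(1, 5),
#'   label = rep("NotFall", 5), rate_hz = 31.25
#' )
#' nrow(tr)
#' @export
accel_trace <- function(t, ax, ay, az,
                        label = rep(LABEL_NOTFALL, length(t)),
                        activity = rep(NA_character_, length(t)),
                        rate_hz, subject_id = "anonymous",
                        source = c("synthetic", "smartwatch", "notch", "farseeing")) {
  source <- match.arg(source)
  assert_scalar_number(rate_hz, "rate_hz", positive = TRUE)
  n <- length(t)
  if (!all(lengths(list(ax, ay, az, label, activity)) == n)) {
    stopf("t, ax, ay, az, label, activity must have equal length")
  }
  df <- data.frame(
    t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
    az = as.numeric(az), label = as.character(label),
    activity = as.character(activity), stringsAsFactors = FALSE
  )
  attr(df, "rate_hz") <- as.numeric(rate_hz)
  attr(df, "subject_id") <- as.character(subject_id)
  attr(df, "source") <- source
  class(df) <- c("accel_trace", "data.frame")
  validate_accel_trace(df)
}

#' Validate an accelerometer trace
#'
#' Checks finite components, the closed two-value label vocabulary and
#' strictly increasing timestamps.
#'
#' @param trace An `accel_trace`.
#' @return The trace, invisibly unchanged, or an error.
#' @export
validate_accel_trace <- function(trace) {
  if (!inherits(trace, "accel_trace")) stopf("not an accel_trace")
  if (nrow(trace) > 0) {
    num <- as.matrix(trace[, c("ax", "ay", "az")])
    if (!all(is.finite(num))) stopf("acceleration components must be finite")
    if (!all(is.finite(trace$t))) stopf("timestamps must be finite")
    if (nrow(trace) > 1 && any(diff(trace$t) <= 0)) {
      stopf("timestamps must be strictly increasing")
    }
    assert_labels(trace$label)
  }
  trace
}

trace_rate <- function(trace) attr(trace, "rate_hz")

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf(
    "<accel_trace> %d samples @ %g Hz, subject %s, source %s\n",
    nrow(x), attr(x, "rate_hz"), attr(x, "subject_id"), attr(x, "source")
  ))
  if (nrow(x) > 0) {
    n_fall <- sum(x$label == LABEL_FALL)
    cat(sprintf("  %.2f s span, %d Fall-labelled samples (%.1f%%)\n",
                x$t[nrow(x)] - x$t[1], n_fall, 100 * n_fall / nrow(x)))
    print(utils::head(as.data.frame(x), 4))
  }
  invisible(x)
}

# Rebuild a trace from a plain data frame, keeping/overriding metadata.
as_trace <- function(df, like = NULL, rate_hz = NULL, subject_id = NULL,
                     source = NULL) {
  accel_trace(
    t = df$t, ax = df$ax, ay = df$ay, az = df$az, label = df$label,
    activity = if ("activity" %in% names(df)) df$activity else rep(NA_character_, nrow(df)),
    rate_hz = rate_hz %||% attr(like, "rate_hz"),
    subject_id = subject_id %||% (attr(like, "subject_id") %||% "anonymous"),
    source = source %||% (attr(like, "source") %||% "synthetic")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
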