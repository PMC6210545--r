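# Trace CSV input/output and stream resampling.
#
# CSV dialect: comma-separated, UTF-8, header `t,ax,ay,az,label[,activity]`,
# numeric fields written with fixed 6-decimal precision, 0-based sample
# indexing everywhere else in the toolkit.

#' Read a labelled accelerometer trace from CSV
#'
#' Parses the toolkit's CSV dialect (`t,ax,ay,az,label[,activity]`). Labels
#' outside the closed vocabulary `"Fall"`/`"NotFall"` and non-monotone
#' timestamps are rejected; a malformed numeric field raises an error naming
#' the offending line.
#'
#' @param path Path to an existing CSV file.
#' @param dialect Dataset layout name; `"standard"` is the dialect above.
#' @param rate_hz Nominal sampling rate recorded on the trace. Defaults to
#'   the median timestamp spacing's reciprocal.
#' @param subject_id,source Metadata stored on the returned trace.
#' @return An [accel_trace()].
#' @seealso [write_trace_csv()]
#' @export
read_trace_csv <- function(path, dialect = "standard", rate_hz = NULL,
                           subject_id = NULL,
                           source = c("smartwatch", "notch", "farseeing", "synthetic")) {
  if (!identical(dialect, "standard")) stopf("unknown CSV dialect: %s", dialect)
  source <- match.arg(source)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("t", "ax", "ay", "az", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stopf("missing column(s): %s", paste(missing, collapse = ", "))
  }
  for (col in c("t", "ax", "ay", "az")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      # +1 for the header line, +bad for the row
      stopf("malformed numeric field `%s` at line %d of %s",
            col, bad[1] + 1L, path)
    }
    df[[col]] <- v
  }
  assert_labels(df$label)
  if (nrow(df) > 1 && any(diff(df$t) <= 0)) {
    stopf("timestamps not strictly increasing in %s", path)
  }
  if (is.null(rate_hz)) {
    rate_hz <- if (nrow(df) > 1) 1 / stats::median(diff(df$t)) else 31.25
  }
  activity <- if ("activity" %in% names(df)) {
    ifelse(df$activity == "" | is.na(df$activity), NA_character_, df$activity)
  } else {
    rep(NA_character_, nrow(df))
  }
  accel_trace(
    t = df$t, ax = df$ax, ay = df$ay, az = df$az, label = df$label,
    activity = activity, rate_hz = rate_hz,
    subject_id = subject_id %||% sub("\\.csv$", "", basename(path)),
    source = source
  )
}

#' Write a labelled accelerometer trace to CSV
#'
#' Inverse of [read_trace_csv()]. Numeric fields are written with fixed
#' 6-decimal precision, so a write/read round trip is the identity on traces
#' whose values carry at most 6 decimals (all traces produced by this
#' package do).
#'
#' @param trace An [accel_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  validate_accel_trace(trace)
  has_activity <- any(!is.na(trace$activity))
  cols <- c("t", "ax", "ay", "az", "label", if (has_activity) "activity")
  out <- data.frame(
    t = sprintf("%.6f", trace$t),
    ax = sprintf("%.6f", trace$ax),
    ay = sprintf("%.6f", trace$ay),
    az = sprintf("%.6f", trace$az),
    label = trace$label,
    stringsAsFactors = FALSE
  )
  if (has_activity) out$activity <- ifelse(is.na(trace$activity), "", trace$activity)
  ok <- tryCatch({
    utils::write.csv(out[, cols], path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write trace to %s", path)
  invisible(path)
}

# Regenerate timestamps on an exact uniform grid at `rate_hz`, anchored at
# the first input timestamp. Downstream windowing assumes uniform spacing.
regrid_time <- function(t0, n, rate_hz) {
  round(t0 + (seq_len(n) - 1) / rate_hz, 6)
}

#' Down-sample a trace by removing random samples
#'
#' Drops uniformly chosen samples (without replacement, under `seed`) until
#' the target rate is reached, the scheme used to bring higher-rate sensor
#' recordings down to the 31.25 Hz smartwatch rate. Surviving samples keep
#' their original values and labels; timestamps are rewritten on a uniform
#' grid at `target_hz` starting at the first input timestamp.
#'
#' Output length is `floor(n * target_hz / rate_hz)`.
#'
#' @param trace An [accel_trace()].
#' @param target_hz Target rate, strictly below the trace's rate.
#' @param seed Integer seed making the removal reproducible.
#' @return A resampled [accel_trace()].
#' @export
downsample_random <- function(trace, target_hz, seed) {
  validate_accel_trace(trace)
  assert_scalar_number(target_hz, "target_hz", positive = TRUE)
  src_hz <- trace_rate(trace)
  if (target_hz >= src_hz) {
    stopf("target_hz (%g) must be below the source rate (%g); use upsample_random() to raise the rate",
          target_hz, src_hz)
  }
  n <- nrow(trace)
  n_out <- floor(n * target_hz / src_hz)
  keep <- with_seed(seed, sort(sample.int(n, n_out)))
  df <- as.data.frame(trace)[keep, , drop = FALSE]
  df$t <- regrid_time(trace$t[1], n_out, target_hz)
  as_trace(df, like = trace, rate_hz = target_hz)
}

#' Up-sample a trace by inserting averaged samples
#'
#' Inserts samples at uniformly chosen gaps (under `seed`); each inserted
#' sample's components are the arithmetic mean of its immediate neighbours
#' at insertion time. An inserted sample inherits the label its neighbours
#' share; if they disagree it takes `"Fall"` (conservative: never destroys
#' fall evidence). Timestamps are rewritten on a uniform grid at
#' `target_hz`.
#'
#' Output length is `round(n * target_hz / rate_hz)` (round-half-even).
#'
#' @inheritParams downsample_random
#' @param target_hz Target rate, strictly above the trace's rate.
#' @return A resampled [accel_trace()]. The returned trace carries an
#'   `inserted` attribute: 1-based indices of the inserted samples.
#' @export
upsample_random <- function(trace, target_hz, seed) {
  validate_accel_trace(trace)
  assert_scalar_number(target_hz, "target_hz", positive = TRUE)
  src_hz <- trace_rate(trace)
  if (target_hz <= src_hz) {
    stopf("target_hz (%g) must be above the source rate (%g); use downsample_random() to lower the rate",
          target_hz, src_hz)
  }
  n <- nrow(trace)
  if (n < 2) stopf("upsampling needs at least 2 samples")
  n_out <- round(n * target_hz / src_hz)
  n_ins <- n_out - n
  gaps <- with_seed(seed, sort(sample.int(n - 1, n_ins, replace = TRUE)))

  df <- as.data.frame(trace)
  rows <- vector("list", n + n_ins)
  inserted <- logical(n + n_ins)
  out_i <- 0L
  for (i in seq_len(n)) {
    out_i <- out_i + 1L
    rows[[out_i]] <- df[i, , drop = FALSE]
    if (i < n) {
      k <- sum(gaps == i)
      if (k > 0) {
        # k samples in one gap are spaced evenly between the neighbours, so
        # every inserted sample equals the arithmetic mean of its immediate
        # neighbours in the final stream (for k = 1 this is exactly the
        # average of the samples directly before and after the insertion)
        a <- df[i, , drop = FALSE]; b <- df[i + 1, , drop = FALSE]
        lab <- if (a$label == b$label) a$label else LABEL_FALL
        act <- if (!is.na(a$activity) && !is.na(b$activity) &&
                   a$activity == b$activity) a$activity else NA_character_
        for (j in seq_len(k)) {
          f <- j / (k + 1)
          out_i <- out_i + 1L
          rows[[out_i]] <- data.frame(
            t = NA_real_, ax = a$ax + f * (b$ax - a$ax),
            ay = a$ay + f * (b$ay - a$ay), az = a$az + f * (b$az - a$az),
            label = lab, activity = act, stringsAsFactors = FALSE
          )
          inserted[out_i] <- TRUE
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$t <- regrid_time(trace$t[1], nrow(out), target_hz)
  res <- as_trace(out, like = trace, rate_hz = target_hz)
  attr(res, "inserted") <- which(inserted)
  res
}

#' Force the acceleration peak of a fall session to carry Fall labels
#'
#' Real-time hand labelling of fall sessions can miss the moment of impact,
#' so the sample of maximum resultant acceleration — and every sample within
#' `margin_s` seconds of it — is relabelled `"Fall"`. All other labels are
#' untouched; the operation never removes a `"Fall"` label and is
#' idempotent. It is only meaningful on fall-session files, so a trace with
#' no `"Fall"` label anywhere is rejected.
#'
#' @param trace A fall-session [accel_trace()].
#' @param margin_s Half-width in seconds of the forced-label window around
#'   the peak (default 0.5 s).
#' @return The relabelled trace.
#' @export
enforce_fall_peak_labels <- function(trace, margin_s = 0.5) {
  validate_accel_trace(trace)
  assert_scalar_number(margin_s, "margin_s")
  if (margin_s < 0) stopf("`margin_s` must be >= 0")
  if (!any(trace$label == LABEL_FALL)) {
    stopf("trace has no \"Fall\" label; enforce_fall_peak_labels() is only for fall-session files")
  }
  res <- resultant_series(trace)
  peak <- which.max(res)
  in_margin <- abs(trace$t - trace$t[peak]) <= margin_s
  trace$label[in_margin] <- LABEL_FALL
  trace
}
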