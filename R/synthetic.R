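# Synthetic wrist-accelerometer generator.
#
# Emulates the statistical structure the detectors assume: resultant
# acceleration resting near 1 G (gravity is kept in the signal), three fall
# morphologies — full critical phase (free-fall dip, impact peak near
# 5.5 G, damped oscillation), missing weightlessness, and low-magnitude
# (peak capped at 3 G) — scripted ADLs (sitting, waving, jogging, walking,
# throwing), and configurable fall:ADL instance imbalance. Wrist
# orientation is modelled as a per-segment random 3-D rotation of the
# signature direction. All randomness flows from one seed via a documented
# splitting scheme.

FALL_VARIANTS <- c("full_critical_phase", "no_weightlessness", "low_magnitude")
ADL_KINDS <- c("sitting", "waving", "jogging", "walking", "throwing")
ADL_MIN_S <- c(sitting = 2, waving = 3, jogging = 10, walking = 10, throwing = 2)
ADL_DEFAULT_S <- c(sitting = 5, waving = 4, jogging = 12, walking = 12, throwing = 3)

#' Fall-signature shape parameters
#'
#' @param variant `"full_critical_phase"` (free-fall dip, high peak,
#'   oscillation), `"no_weightlessness"` (no dip) or `"low_magnitude"`
#'   (whole pattern compressed, peak capped at 3 G — common for sideways
#'   wrist falls).
#' @param freefall_ms Duration of the near-0 G dip (0 for
#'   `no_weightlessness`; variant default otherwise).
#' @param peak_g Impact peak magnitude in G (> 1; `low_magnitude` caps at
#'   3, `full_critical_phase` defaults to 5.5).
#' @param osc_freq_hz,osc_decay_s Damped-oscillation frequency and
#'   exponential decay constant.
#' @return A `fall_shape_params` list.
#' @export
fall_shape_params <- function(variant = c("full_critical_phase",
                                          "no_weightlessness",
                                          "low_magnitude"),
                              freefall_ms = NULL, peak_g = NULL,
                              osc_freq_hz = 3, osc_decay_s = 0.25) {
  variant <- match.arg(variant)
  defaults <- switch(variant,
    full_critical_phase = list(freefall_ms = 300, peak_g = 5.5),
    no_weightlessness = list(freefall_ms = 0, peak_g = 4.5),
    low_magnitude = list(freefall_ms = 150, peak_g = 2.5)
  )
  freefall_ms <- freefall_ms %||% defaults$freefall_ms
  peak_g <- peak_g %||% defaults$peak_g
  if (variant == "no_weightlessness" && freefall_ms != 0) {
    stopf("no_weightlessness variant requires freefall_ms = 0")
  }
  if (peak_g <= 1) stopf("`peak_g` must exceed the 1 G baseline")
  if (variant == "low_magnitude" && peak_g > 3) {
    stopf("low_magnitude variant caps peak_g at 3 G")
  }
  structure(list(variant = variant, freefall_ms = freefall_ms,
                 peak_g = peak_g, osc_freq_hz = osc_freq_hz,
                 osc_decay_s = osc_decay_s),
            class = "fall_shape_params")
}

# Uniform random rotation matrix (via a random unit quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Turn a resultant-magnitude profile into a tri-axial segment: project the
# profile on a randomly rotated signature direction and add axis noise.
profile_to_xyz <- function(profile, noise_sd) {
  u <- as.numeric(random_rotation() %*% c(0, 0, 1))
  xyz <- outer(profile, u)
  xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd), ncol = 3)
}

segment_df <- function(xyz, label, activity, rate_hz) {
  data.frame(
    ax = round(xyz[, 1], 6), ay = round(xyz[, 2], 6), az = round(xyz[, 3], 6),
    label = label, activity = activity, stringsAsFactors = FALSE
  )
}

quiet_profile <- function(n) rep(1, n)

#' Simulate one fall segment
#'
#' Generates a tri-axial segment whose resultant shows (i) a ~1 G baseline,
#' (ii) an optional dip toward 0 G (weightlessness), (iii) a single global
#' maximum at `peak_g`, and (iv) an exponentially decaying oscillation back
#' to rest. `"Fall"` labels cover the critical phase — dip through
#' oscillation, always including at least `label_margin_s` on either side
#' of the peak, so the peak-label post-processing rule leaves the segment
#' unchanged.
#'
#' @param params A [fall_shape_params()].
#' @param rate_hz Sampling rate in Hz.
#' @param seed Integer seed; identical seeds give identical segments.
#' @param noise_sd Per-axis Gaussian noise, G.
#' @param label_margin_s Minimum Fall-label margin around the peak.
#' @return An [accel_trace()] segment (quiet lead-in/out labelled
#'   `"NotFall"`).
#' @export
simulate_fall <- function(params = fall_shape_params(), rate_hz = 31.25,
                          seed = 1L, noise_sd = 0.03, label_margin_s = 0.5) {
  if (!inherits(params, "fall_shape_params")) {
    stopf("`params` must come from fall_shape_params()")
  }
  with_seed(seed, {
    dt <- 1 / rate_hz
    n_pre <- round(0.8 * rate_hz)
    n_dip <- round(params$freefall_ms / 1000 * rate_hz)
    n_imp <- max(5L, round(0.16 * rate_hz))
    n_osc <- round(0.8 * rate_hz)
    n_post <- round(0.8 * rate_hz)

    dip_floor <- stats::runif(1, 0.1, 0.25)
    dip <- if (n_dip > 0) {
      1 - (1 - dip_floor) * (1 - cos(pi * seq_len(n_dip) / n_dip)) / 2
    } else {
      numeric(0)
    }
    base_imp <- if (n_dip > 0) dip_floor else 1
    # half-sine impact whose middle sample lands exactly on peak_g
    imp <- base_imp + (params$peak_g - base_imp) *
      sin(pi * (seq_len(n_imp) - 1) / (n_imp - 1))
    t_osc <- seq_len(n_osc) * dt
    osc <- 1 + (params$peak_g - 1) * 0.3 * exp(-t_osc / params$osc_decay_s) *
      cos(2 * pi * params$osc_freq_hz * t_osc)

    profile <- c(quiet_profile(n_pre), dip, imp, osc, quiet_profile(n_post))
    n <- length(profile)
    label <- rep(LABEL_NOTFALL, n)
    crit_start <- n_pre + 1L
    crit_end <- n_pre + n_dip + n_imp + n_osc
    peak_i <- n_pre + n_dip + which.max(imp)
    margin <- round(label_margin_s * rate_hz)
    label[max(1L, min(crit_start, peak_i - margin)):min(n, max(crit_end, peak_i + margin))] <- LABEL_FALL

    xyz <- profile_to_xyz(profile, noise_sd)
    df <- segment_df(xyz, label, NA_character_, rate_hz)
    accel_trace(
      t = round((seq_len(n) - 1) / rate_hz, 6),
      ax = df$ax, ay = df$ay, az = df$az, label = df$label,
      activity = df$activity, rate_hz = rate_hz, subject_id = "sim",
      source = "synthetic"
    )
  })
}

#' Simulate one activity-of-daily-living segment
#'
#' Kind-specific morphology of the resultant: `sitting` — a single low
#' transient on a quiet baseline; `waving` — 1–3 Hz periodic moderate
#' amplitude; `jogging` — ~2.5 Hz sustained high amplitude; `walking` —
#' ~1.8 Hz low amplitude; `throwing` — one short spike. All samples are
#' labelled `"NotFall"` and tagged with the activity name. Minimum
#' durations are enforced (waving 3 s; jogging and walking 10 s).
#'
#' @param kind One of `"sitting"`, `"waving"`, `"jogging"`, `"walking"`,
#'   `"throwing"`.
#' @param duration_s Segment duration (kind default when `NULL`).
#' @param rate_hz Sampling rate in Hz.
#' @param seed Integer seed.
#' @param noise_sd Per-axis Gaussian noise, G.
#' @return An [accel_trace()] segment.
#' @export
simulate_adl <- function(kind, duration_s = NULL, rate_hz = 31.25,
                         seed = 1L, noise_sd = 0.03) {
  if (!is.character(kind) || length(kind) != 1L || !kind %in% ADL_KINDS) {
    stopf("unknown ADL kind: %s", paste(kind, collapse = ", "))
  }
  duration_s <- duration_s %||% ADL_DEFAULT_S[[kind]]
  if (duration_s < ADL_MIN_S[[kind]]) {
    stopf("%s segments must last at least %g s", kind, ADL_MIN_S[[kind]])
  }
  with_seed(seed, {
    n <- round(duration_s * rate_hz)
    tt <- (seq_len(n) - 1) / rate_hz
    ramp <- pmin(1, pmin(tt, rev(tt)) / 0.3)  # soft 0.3 s on/off envelope
    profile <- switch(kind,
      sitting = {
        centre <- stats::runif(1, 0.25, 0.75) * duration_s
        1 + stats::runif(1, 0.3, 0.55) * exp(-((tt - centre) / 0.15)^2)
      },
      waving = {
        f <- stats::runif(1, 1, 3); amp <- stats::runif(1, 0.4, 0.7)
        1 + amp * ramp * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      },
      jogging = {
        f <- stats::runif(1, 2.3, 2.7); amp <- stats::runif(1, 1.0, 1.5)
        ph <- stats::runif(1, 0, 2 * pi)
        1 + amp * ramp * (0.5 + 0.5 * sin(2 * pi * f * tt + ph)) +
          0.15 * amp * ramp * sin(4 * pi * f * tt + ph)
      },
      walking = {
        f <- stats::runif(1, 1.65, 1.95); amp <- stats::runif(1, 0.2, 0.35)
        1 + amp * ramp * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      },
      throwing = {
        centre <- stats::runif(1, 0.3, 0.7) * duration_s
        peak <- stats::runif(1, 2.0, 2.8)
        1 + (peak - 1) * exp(-((tt - centre) / 0.08)^2)
      }
    )
    xyz <- profile_to_xyz(profile, noise_sd)
    df <- segment_df(xyz, rep(LABEL_NOTFALL, n), rep(kind, n), rate_hz)
    accel_trace(
      t = round(tt, 6), ax = df$ax, ay = df$ay, az = df$az,
      label = df$label, activity = df$activity, rate_hz = rate_hz,
      subject_id = "sim", source = "synthetic"
    )
  })
}

#' Session simulation configuration
#'
#' @param rate_hz Sampling rate in Hz (default 31.25).
#' @param noise_sd Additive per-axis Gaussian noise in G.
#' @param adl_mix Named non-negative weights over the five ADL kinds.
#' @param falls_per_type Fall count for each of front, back, left, right —
#'   a single count or a length-4 vector in that order.
#' @param fall_to_adl_ratio Target ADL instances per fall: tagged sessions
#'   place that many scripted ADL segments per fall; untagged sessions pad
#'   NotFall time so the 1-second tiling yields that many tiles per fall.
#' @param tagged Whether ADL segments carry activity tags (smartwatch-style
#'   labelling) or not (continuous-stream labelling).
#' @param seed Master seed; every segment derives its own child seed.
#' @param subject_id Identifier stored on the trace.
#' @return A `sim_session_config` list.
#' @export
sim_session_config <- function(rate_hz = 31.25, noise_sd = 0.03,
                               adl_mix = c(sitting = 1, waving = 1, jogging = 1,
                                           walking = 1, throwing = 1),
                               falls_per_type = 1L, fall_to_adl_ratio = 2,
                               tagged = TRUE, seed = 1L, subject_id = "sim") {
  if (is.null(names(adl_mix)) || !all(names(adl_mix) %in% ADL_KINDS)) {
    stopf("`adl_mix` must be named with ADL kinds (%s)", paste(ADL_KINDS, collapse = ", "))
  }
  if (any(adl_mix < 0)) stopf("`adl_mix` weights must be non-negative")
  if (length(falls_per_type) == 1L) falls_per_type <- rep(as.integer(falls_per_type), 4L)
  if (length(falls_per_type) != 4L || any(falls_per_type < 0)) {
    stopf("`falls_per_type` must be one count or four (front, back, left, right)")
  }
  structure(list(rate_hz = rate_hz, noise_sd = noise_sd, adl_mix = adl_mix,
                 falls_per_type = as.integer(falls_per_type),
                 fall_to_adl_ratio = fall_to_adl_ratio, tagged = tagged,
                 seed = as.integer(seed), subject_id = subject_id),
            class = "sim_session_config")
}

# Variant mix by fall direction: forward/backward falls show the textbook
# critical phase; sideways (left/right) falls are dominated by the
# truncated morphologies.
variant_for_type <- function(type) {
  if (type %in% c("front", "back")) {
    sample(FALL_VARIANTS, 1, prob = c(0.8, 0.2, 0))
  } else {
    sample(FALL_VARIANTS, 1, prob = c(0.2, 0.4, 0.4))
  }
}

random_fall_params <- function(type) {
  variant <- variant_for_type(type)
  peak <- switch(variant,
    full_critical_phase = stats::runif(1, 5.0, 6.0),
    no_weightlessness = stats::runif(1, 3.8, 5.2),
    low_magnitude = stats::runif(1, 2.0, 2.9)
  )
  fall_shape_params(variant, peak_g = peak,
                    osc_freq_hz = stats::runif(1, 2.5, 4),
                    osc_decay_s = stats::runif(1, 0.2, 0.3))
}

#' Simulate a full labelled recording session
#'
#' Concatenates fall and ADL segments in shuffled order, separated by quiet
#' gaps, on a uniform time grid; fully reproducible under the master seed.
#' In tagged mode the session contains exactly
#' `round(sum(falls) * fall_to_adl_ratio)` ADL segments; in untagged mode
#' ADL segments are added until the NotFall time yields approximately
#' `fall_to_adl_ratio` 1-second tiles per fall.
#'
#' @param cfg A [sim_session_config()].
#' @return An [accel_trace()].
#' @export
simulate_session <- function(cfg = sim_session_config()) {
  if (!inherits(cfg, "sim_session_config")) stopf("`cfg` must come from sim_session_config()")
  n_falls <- sum(cfg$falls_per_type)
  if (n_falls + sum(cfg$adl_mix > 0) == 0L) stopf("session must contain at least one activity")
  rate <- cfg$rate_hz
  tile <- round(rate)

  fall_types <- rep(c("front", "back", "left", "right"), cfg$falls_per_type)
  plan_seed <- child_seed(cfg$seed, 0L)
  kinds <- names(cfg$adl_mix)[cfg$adl_mix > 0]

  segs <- with_seed(plan_seed, {
    falls <- lapply(seq_along(fall_types), function(i) {
      list(what = "fall", type = fall_types[i],
           params = random_fall_params(fall_types[i]))
    })
    adls <- list()
    if (length(kinds) > 0) {
      if (cfg$tagged) {
        n_adls <- round(n_falls * cfg$fall_to_adl_ratio)
        if (n_falls == 0L) n_adls <- max(1L, round(cfg$fall_to_adl_ratio))
        adls <- lapply(seq_len(n_adls), function(i) {
          kind <- sample(kinds, 1, prob = cfg$adl_mix[kinds])
          list(what = "adl", kind = kind,
               duration = ADL_DEFAULT_S[[kind]] * stats::runif(1, 0.9, 1.3))
        })
      } else {
        # pad NotFall time until the 1 s tiling will produce about
        # ratio-per-fall tiles; accounts for the quiet flanks inside fall
        # segments, inter-segment gaps, and the half-tile lost on average
        # at the end of each maximal NotFall stretch
        target <- cfg$fall_to_adl_ratio * max(1L, n_falls) * tile +
          (n_falls + 1L) * tile / 2
        cum <- n_falls * round(1.6 * rate)
        repeat {
          kind <- sample(kinds, 1, prob = cfg$adl_mix[kinds])
          duration <- ADL_DEFAULT_S[[kind]] * stats::runif(1, 0.9, 1.3)
          adls <- c(adls, list(list(what = "adl", kind = kind, duration = duration)))
          cum <- cum + round(duration * rate) + tile  # + ~1 s gap
          if (cum >= target) break
        }
      }
    }
    items <- c(falls, adls)
    items[sample.int(length(items))]
  })

  pieces <- vector("list", 2L * length(segs) - 1L)
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    seg_seed <- child_seed(cfg$seed, i)
    tr <- if (seg$what == "fall") {
      simulate_fall(seg$params, rate_hz = rate, seed = seg_seed,
                    noise_sd = cfg$noise_sd)
    } else {
      simulate_adl(seg$kind, duration_s = seg$duration, rate_hz = rate,
                   seed = seg_seed, noise_sd = cfg$noise_sd)
    }
    pieces[[2L * i - 1L]] <- as.data.frame(tr)[, c("ax", "ay", "az", "label", "activity")]
    if (i < length(segs)) {
      gap <- with_seed(child_seed(cfg$seed, 10000L + i), {
        n_gap <- round(stats::runif(1, 0.5, 1.5) * rate)
        profile_to_xyz(quiet_profile(n_gap), cfg$noise_sd)
      })
      pieces[[2L * i]] <- segment_df(gap, LABEL_NOTFALL, NA_character_, rate)
    }
  }
  df <- do.call(rbind, pieces)
  # untagged sessions mimic continuous-stream labelling: only Fall/NotFall,
  # no ADL interval annotations
  if (!cfg$tagged) df$activity <- NA_character_
  accel_trace(
    t = round((seq_len(nrow(df)) - 1) / rate, 6),
    ax = df$ax, ay = df$ay, az = df$az, label = df$label,
    activity = df$activity, rate_hz = rate,
    subject_id = cfg$subject_id, source = "synthetic"
  )
}

#' Simulate a multi-file benchmark dataset
#'
#' Emits a set of session files whose fall:ADL instance ratios mirror the
#' three published dataset profiles: `smartwatch_like` (91 falls : 90
#' tagged ADL segments), `notch_like` (107 falls : 2456 untagged 1-second
#' ADL tiles) and `farseeing_like` (the 23 : 27,412 profile scaled down by
#' a factor of 11.5 — to 2 falls : 2384 tiles — so generation stays
#' desk-scale while preserving the ratio). Preset parameters ship in
#' `inst/extdata/benchmark_presets.json`.
#'
#' @param preset `"smartwatch_like"`, `"notch_like"` or `"farseeing_like"`.
#' @param seed Master seed; the file manifest is deterministic under it.
#' @param out_dir Optional directory; when given, each file is also written
#'   as CSV in the package dialect.
#' @return Named list of [accel_trace()] files; when `out_dir` is given the
#'   written paths are attached as attribute `paths`.
#' @export
simulate_benchmark <- function(preset = c("smartwatch_like", "notch_like",
                                          "farseeing_like"),
                               seed = 1L, out_dir = NULL) {
  preset <- match.arg(preset)
  presets <- jsonlite::read_json(
    system.file("extdata", "benchmark_presets.json", package = "wristfall"),
    simplifyVector = TRUE
  )
  p <- presets[[preset]]
  n_files <- p$files
  # largest-remainder apportionment of falls and ADL instances over files
  apportion <- function(total, k) {
    base <- rep(total %/% k, k)
    extra <- total %% k
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  falls_by_file <- apportion(p$falls_total, n_files)
  adls_by_file <- apportion(p$adls_total, n_files)

  traces <- vector("list", n_files)
  names(traces) <- sprintf("%s_file%02d", preset, seq_len(n_files))
  for (i in seq_len(n_files)) {
    nf <- falls_by_file[i]
    per_type <- apportion(nf, 4L)
    cfg <- sim_session_config(
      noise_sd = p$noise_sd,
      falls_per_type = per_type,
      fall_to_adl_ratio = if (nf > 0) adls_by_file[i] / nf else adls_by_file[i],
      tagged = p$tagged,
      seed = child_seed(seed, 500L + i),
      subject_id = sprintf("%s_s%02d", preset, i)
    )
    traces[[i]] <- simulate_session(cfg)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- file.path(out_dir, paste0(names(traces), ".csv"))
    for (i in seq_len(n_files)) write_trace_csv(traces[[i]], paths[i])
    attr(traces, "paths") <- paths
  }
  traces
}
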