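mk_trace <- function(labels, rate_hz = 31.25, activity = NULL) {
  n <- length(labels)
  accel_trace(
    t = (seq_len(n) - 1) / rate_hz, ax = rep(0, n), ay = rep(0, n),
    az = rep(1, n), label = labels,
    activity = activity %||% rep(NA_character_, n), rate_hz = rate_hz
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("instance segmentation tiles untagged NotFall stretches", {
  tr <- mk_trace(c(rep("NotFall", 40), rep("Fall", 20), rep("NotFall", 40)))
  inst <- segment_instances(tr)
  expect_equal(nrow(inst$falls), 1L)
  expect_equal(inst$falls$start_idx, 40L)
  expect_equal(inst$falls$end_idx, 60L)
  # tile = round(31.25) = 31; each 40-sample stretch yields one tile
  expect_equal(nrow(inst$adls), 2L)
  expect_equal(inst$adls$end_idx - inst$adls$start_idx, c(31L, 31L))

  inst93 <- segment_instances(mk_trace(rep("NotFall", 93)))
  expect_equal(nrow(inst93$falls), 0L)
  expect_equal(nrow(inst93$adls), 3L)  # floor(93 / 31)

  empty <- accel_trace(numeric(0), numeric(0), numeric(0), numeric(0),
                       label = character(0), activity = character(0),
                       rate_hz = 31.25)
  inst0 <- segment_instances(empty)
  expect_equal(nrow(inst0$falls), 0L)
  expect_equal(nrow(inst0$adls), 0L)
})

test_that("tagged traces use one instance per tagged segment", {
  labels <- c(rep("NotFall", 50), rep("Fall", 10), rep("NotFall", 80))
  activity <- c(rep("waving", 50), rep(NA, 10), rep("jogging", 80))
  tr <- mk_trace(labels, activity = activity)
  inst <- segment_instances(tr)
  expect_equal(nrow(inst$adls), 2L)
  expect_equal(inst$adls$activity, c("waving", "jogging"))
  # forcing tiling ignores the tags
  inst_tiles <- segment_instances(tr, use_tags = FALSE)
  expect_equal(nrow(inst_tiles$adls), floor(50 / 31) + floor(80 / 31))
})

test_that("event matching follows the per-instance crediting rules", {
  tr <- mk_trace(c(rep("NotFall", 40), rep("Fall", 20), rep("NotFall", 40)))
  inst <- segment_instances(tr)

  # one event fully inside the fall run
  ev <- detection_events(45L, 55L, "nb", 10)
  cnt <- match_events(ev, inst, tr)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn, cnt$tn), c(1L, 0L, 0L, 2L))

  # one event entirely inside an ADL tile: a FP, and that tile is not a TN
  ev <- detection_events(5L, 12L, "nb", 7)
  cnt <- match_events(ev, inst, tr)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn, cnt$tn), c(0L, 1L, 1L, 1L))

  # no events: the fall is missed, both tiles are quiet
  cnt <- match_events(detection_events(), inst, tr)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn, cnt$tn), c(0L, 0L, 1L, 2L))

  # two events on one fall instance credit a single TP (extra one ignored)
  ev <- detection_events(c(41L, 50L), c(45L, 58L), "nb")
  cnt <- match_events(ev, inst, tr)
  expect_equal(c(cnt$tp, cnt$fp), c(1L, 0L))

  # count conservation on a random mix of events
  set.seed(8)
  for (i in 1:10) {
    starts <- sort(sample(0:95, 4))
    ev <- detection_events(starts, starts + sample(3:5, 4, replace = TRUE), "nb")
    cnt <- match_events(ev, inst, tr)
    expect_equal(cnt$fn + cnt$tp, nrow(inst$falls))
    expect_lte(cnt$tn, nrow(inst$adls))
  }

  expect_error(match_events(detection_events(90L, 120L, "nb"), inst, tr), "outside")
})

test_that("metric formulas are applied with NA for undefined ratios", {
  r <- compute_metrics(list(tp = 1, fp = 0, fn = 0, tn = 0))
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)

  r <- compute_metrics(list(tp = 0, fp = 0, fn = 5, tn = 0))
  expect_equal(r$recall, 0)
  expect_true(is.na(r$precision))  # undefined, not 0

  r <- compute_metrics(list(tp = 43, fp = 25, fn = 7, tn = 100))
  expect_equal(r$recall, 0.86)
  expect_equal(r$precision, 43 / 68)
  expect_equal(r$overall_accuracy, 143 / 175)

  expect_error(compute_metrics(list(tp = -1, fp = 0, fn = 0, tn = 0)), "non-negative")
})

test_that("file splits aggregate counts across folds deterministically", {
  traces <- lapply(1:3, function(i) {
    simulate_session(sim_session_config(
      falls_per_type = 1, fall_to_adl_ratio = 2,
      adl_mix = c(sitting = 1, walking = 1), seed = 60 + i
    ))
  })
  det <- detector_spec("nb", seed = 1)
  rep_loo <- evaluate_split(traces, det, split = "leave_one_file_out")
  folds <- attr(rep_loo, "folds")
  expect_length(folds, 3L)
  # running totals: the last fold's totals are the report's counts
  expect_equal(folds[[3]]$tp, rep_loo$tp)
  expect_equal(rep_loo$tp + rep_loo$fn, folds[[3]]$n_falls)

  rep2 <- evaluate_split(traces, det, split = "leave_one_file_out")
  expect_equal(unclass(rep_loo)[1:9], unclass(rep2)[1:9])

  rep_ho <- evaluate_split(traces, det, split = "two_thirds_holdout")
  expect_s3_class(rep_ho, "eval_report")
  expect_error(evaluate_split(traces[1], det, split = "leave_one_file_out"), "at least 2")
})

test_that("sample-by-sample replay reproduces the batch classic pipeline", {
  train <- simulate_session(sim_session_config(
    falls_per_type = 1, fall_to_adl_ratio = 2, seed = 71
  ))
  test_tr <- simulate_session(sim_session_config(
    falls_per_type = 1, fall_to_adl_ratio = 2, seed = 72
  ))
  model <- train_classic(per_sample_features(train), kind = "nb", seed = 1)
  batch_events <- detect_classic(model, test_tr)

  # online replay: stream features one sample at a time, classify each row
  # as it appears, then apply the same run-length rule
  st <- feature_stream(feature_config(rate_hz = 31.25))
  preds <- character(0)
  first_idx <- NA_integer_
  for (i in seq_len(nrow(test_tr))) {
    row <- stream_push(st, test_tr$ax[i], test_tr$ay[i], test_tr$az[i])
    if (!is.null(row)) {
      if (is.na(first_idx)) first_idx <- row$idx
      x <- matrix(c(row$a_res, row$s_min, row$s_max, row$delta_s), 1, 4)
      preds <- c(preds, classify_samples(model, x))
    }
  }
  replay_events <- consecutive_count_decision(preds, consecutive_rule(),
                                              model = "nb", offset = first_idx)
  expect_equal(as.data.frame(replay_events), as.data.frame(batch_events))

  # and the resulting reports agree
  inst <- segment_instances(test_tr)
  expect_equal(
    unclass(compute_metrics(match_events(replay_events, inst, test_tr)))[1:9],
    unclass(compute_metrics(match_events(batch_events, inst, test_tr)))[1:9]
  )
})
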