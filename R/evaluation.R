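# Event-based evaluation: ground-truth instances, event matching,
# per-instance precision/recall/accuracy, and file-level splits.

#' Segment a labelled trace into fall and ADL instances
#'
#' A fall instance is a maximal run of consecutive `"Fall"`-labelled
#' samples. ADL instances are taken from explicit activity tags when any
#' are present (each tagged NotFall segment is one instance); otherwise
#' every maximal NotFall stretch is tiled into non-overlapping
#' `round(rate_hz * adl_tile_s)`-sample instances, discarding the final
#' partial tile.
#'
#' @param trace A labelled [accel_trace()].
#' @param adl_tile_s Tile length in seconds for untagged traces (default 1).
#' @param use_tags Use activity tags when present (default); set `FALSE` to
#'   force 1-second tiling.
#' @return An `instance_set`: list with data frames `falls` and `adls`
#'   (columns `start_idx`, `end_idx`, 0-based half-open; `adls` also has
#'   `activity`), plus `n_samples`.
#' @export
segment_instances <- function(trace, adl_tile_s = 1, use_tags = TRUE) {
  validate_accel_trace(trace)
  n <- nrow(trace)
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0))
  if (n == 0L) {
    return(structure(list(falls = empty,
                          adls = cbind(empty, activity = character(0)),
                          n_samples = 0L),
                     class = "instance_set"))
  }
  is_fall <- trace$label == LABEL_FALL
  r <- rle(is_fall)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  falls <- data.frame(start_idx = run_start[r$values] - 1L,
                      end_idx = run_end[r$values])

  tagged <- use_tags && any(!is.na(trace$activity) & !is_fall)
  if (tagged) {
    key <- ifelse(is_fall, "<fall>", ifelse(is.na(trace$activity), "<gap>", trace$activity))
    rk <- rle(key)
    ke <- cumsum(rk$lengths); ks <- ke - rk$lengths + 1L
    sel <- !(rk$values %in% c("<fall>", "<gap>"))
    adls <- data.frame(start_idx = ks[sel] - 1L, end_idx = ke[sel],
                       activity = rk$values[sel], stringsAsFactors = FALSE)
  } else {
    tile <- as.integer(round(trace_rate(trace) * adl_tile_s))
    s_list <- run_start[!r$values]; e_list <- run_end[!r$values]
    adls <- do.call(rbind, lapply(seq_along(s_list), function(i) {
      len <- e_list[i] - s_list[i] + 1L
      k <- len %/% tile
      if (k == 0L) return(NULL)
      st <- s_list[i] + (seq_len(k) - 1L) * tile
      data.frame(start_idx = st - 1L, end_idx = st - 1L + tile,
                 activity = NA_character_, stringsAsFactors = FALSE)
    }))
    if (is.null(adls)) adls <- cbind(empty, data.frame(activity = character(0)))
  }
  structure(list(falls = falls, adls = adls, n_samples = n),
            class = "instance_set")
}

#' Match detector events against ground-truth instances
#'
#' An event is a true positive iff any sample index it covers carries the
#' `"Fall"` label; for the deep detector those covered indices are exactly
#' the final-row indices of the `heuristic_k` averaged windows, so the same
#' test applies in both modes. Each fall instance credits at most one TP —
#' additional events overlapping an already-credited instance are ignored.
#' Events matching no fall sample are false positives; fall instances
#' touched by no matching event are false negatives; ADL instances
#' containing no event at all are true negatives.
#'
#' @param events A [detection_events()] data frame (sorted by start).
#' @param instances An `instance_set` from [segment_instances()] on the
#'   same trace.
#' @param trace The labelled trace the events refer to.
#' @param mode `"classic"` or `"deep"` (recorded; the matching test is the
#'   label test above in both).
#' @return A `match_counts` list: `tp`, `fp`, `fn`, `tn`, `n_falls`,
#'   `n_adls`, and `adl_table` (per-activity totals/hits for tagged
#'   traces).
#' @export
match_events <- function(events, instances, trace, mode = c("classic", "deep")) {
  mode <- match.arg(mode)
  n <- nrow(trace)
  if (nrow(events) > 0) {
    if (any(events$start_idx < 0L) || any(events$end_idx > n)) {
      stopf("events fall outside the trace (n = %d samples)", n)
    }
    events <- events[order(events$start_idx), , drop = FALSE]
  }
  is_fall <- trace$label == LABEL_FALL

  ev_hit <- logical(nrow(events))   # event covers >= 1 Fall-labelled sample
  if (nrow(events) > 0) {
    ev_hit <- vapply(seq_len(nrow(events)), function(i) {
      any(is_fall[(events$start_idx[i] + 1L):events$end_idx[i]])
    }, logical(1))
  }
  fp <- sum(!ev_hit)

  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1  # half-open ranges
  falls <- instances$falls
  credited <- logical(nrow(falls))
  if (nrow(falls) > 0 && any(ev_hit)) {
    hits <- events[ev_hit, , drop = FALSE]
    credited <- vapply(seq_len(nrow(falls)), function(i) {
      any(overlaps(hits$start_idx, hits$end_idx, falls$start_idx[i], falls$end_idx[i]))
    }, logical(1))
  }
  tp <- sum(credited)
  fn <- nrow(falls) - tp

  adls <- instances$adls
  adl_has_event <- logical(nrow(adls))
  if (nrow(adls) > 0 && nrow(events) > 0) {
    adl_has_event <- vapply(seq_len(nrow(adls)), function(i) {
      any(overlaps(events$start_idx, events$end_idx, adls$start_idx[i], adls$end_idx[i]))
    }, logical(1))
  }
  tn <- sum(!adl_has_event)

  adl_table <- NULL
  tag_idx <- which(!is.na(adls$activity))
  if (length(tag_idx) > 0) {
    act <- adls$activity[tag_idx]
    quiet <- as.integer(!adl_has_event[tag_idx])
    lev <- sort(unique(act))
    adl_table <- data.frame(
      activity = lev,
      instances = as.integer(table(factor(act, lev))),
      quiet = as.integer(tapply(quiet, factor(act, lev), sum)),
      stringsAsFactors = FALSE
    )
    adl_table$accuracy <- adl_table$quiet / adl_table$instances
  }

  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 n_falls = nrow(falls), n_adls = nrow(adls),
                 mode = mode, adl_table = adl_table),
            class = "match_counts")
}

#' Precision, recall and accuracies from outcome counts
#'
#' Applies the per-instance formulas `recall = TP/(TP+FN)`,
#' `precision = TP/(TP+FP)`, `accuracy = (TP+TN)/(TP+TN+FP+FN)`. A ratio
#' with a zero denominator is reported as `NA`, never 0. ADL accuracy is
#' the fraction of ADL instances containing no event; fall accuracy is the
#' fraction of fall instances detected.
#'
#' @param counts A `match_counts` from [match_events()], or any list with
#'   non-negative `tp`, `fp`, `fn`, `tn` (and optionally `n_falls`,
#'   `n_adls`, `adl_table`).
#' @return An `eval_report` list with the counts and all metric fields.
#' @export
compute_metrics <- function(counts) {
  for (f in c("tp", "fp", "fn", "tn")) {
    v <- counts[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stopf("`counts$%s` must be a non-negative number", f)
    }
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  n_falls <- counts$n_falls %||% (tp + fn)
  n_adls <- counts$n_adls %||% (tn + fp)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    overall_accuracy = ratio(tp + tn, tp + tn + fp + fn),
    fall_accuracy = ratio(tp, n_falls),
    adl_accuracy = ratio(tn, n_adls),
    adl_table = counts$adl_table
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("  Precision    %s\n", fmt(x$precision)))
  cat(sprintf("  Recall       %s\n", fmt(x$recall)))
  cat(sprintf("  ADL Acc.     %s\n", fmt(x$adl_accuracy)))
  cat(sprintf("  Overall Acc. %s\n", fmt(x$overall_accuracy)))
  if (!is.null(x$adl_table)) {
    cat("  Per-activity ADL accuracy:\n")
    print(x$adl_table, row.names = FALSE)
  }
  invisible(x)
}

#' Detector specification for split evaluation
#'
#' @param kind `"nb"`, `"svm"` or `"gru"`.
#' @param rule [consecutive_rule()] for the classic detectors.
#' @param feature_cfg [feature_config()] for the classic detectors.
#' @param gru_cfg [gru_config()] for the deep detector.
#' @param train_spec [gru_train_spec()] for the deep detector.
#' @param seed Training seed.
#' @return A `detector_spec` list.
#' @export
detector_spec <- function(kind = c("nb", "svm", "gru"),
                          rule = consecutive_rule(),
                          feature_cfg = feature_config(),
                          gru_cfg = gru_config(),
                          train_spec = gru_train_spec(),
                          seed = 1L) {
  structure(list(kind = match.arg(kind), rule = rule,
                 feature_cfg = feature_cfg, gru_cfg = gru_cfg,
                 train_spec = train_spec, seed = as.integer(seed)),
            class = "detector_spec")
}

train_detector <- function(spec, traces) {
  if (spec$kind == "gru") {
    cfg <- spec$gru_cfg; cfg$seed <- spec$seed
    train_gru(build_gru_model(cfg), traces, spec$train_spec)
  } else {
    rows <- do.call(rbind, lapply(traces, per_sample_features, cfg = spec$feature_cfg))
    train_classic(rows, kind = spec$kind, seed = spec$seed)
  }
}

detect_with <- function(spec, model, trace) {
  if (spec$kind == "gru") {
    detect_gru(model, trace)
  } else {
    detect_classic(model, trace, cfg = spec$feature_cfg, rule = spec$rule)
  }
}

#' Train and evaluate a detector across file-level splits
#'
#' `"two_thirds_holdout"` trains on the first `round(2/3 * n)` files (by
#' list order — contiguous recordings, avoiding sample-level leakage) and
#' tests on the rest. `"leave_one_file_out"` runs one fold per file,
#' training on all other files; outcome counts are summed across folds
#' before the metrics are computed. Test traces are replayed as an online
#' stream would be — sample by sample through the same causal feature /
#' sliding-window path used at training time, which the batch
#' implementation reproduces exactly.
#'
#' @param traces List of labelled [accel_trace()] files.
#' @param detector A [detector_spec()].
#' @param split `"two_thirds_holdout"` or `"leave_one_file_out"`.
#' @param adl_tile_s,use_tags Passed to [segment_instances()].
#' @return An `eval_report` (aggregated counts and metrics); the per-fold
#'   counts are attached as attribute `folds`.
#' @export
evaluate_split <- function(traces, detector,
                           split = c("two_thirds_holdout", "leave_one_file_out"),
                           adl_tile_s = 1, use_tags = TRUE) {
  split <- match.arg(split)
  if (inherits(traces, "accel_trace")) traces <- list(traces)
  n <- length(traces)
  folds <- if (split == "two_thirds_holdout") {
    if (n < 2L) stopf("holdout needs at least 2 files")
    n_train <- max(1L, min(n - 1L, round(2 / 3 * n)))
    list(list(train = seq_len(n_train), test = seq.int(n_train + 1L, n)))
  } else {
    if (n < 2L) stopf("leave-one-file-out needs at least 2 files")
    lapply(seq_len(n), function(i) list(train = setdiff(seq_len(n), i), test = i))
  }
  total <- list(tp = 0L, fp = 0L, fn = 0L, tn = 0L, n_falls = 0L, n_adls = 0L)
  fold_counts <- vector("list", length(folds))
  mode <- if (detector$kind == "gru") "deep" else "classic"
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    model <- train_detector(detector, traces[fold$train])
    for (ti in fold$test) {
      tr <- traces[[ti]]
      events <- detect_with(detector, model, tr)
      inst <- segment_instances(tr, adl_tile_s = adl_tile_s, use_tags = use_tags)
      cnt <- match_events(events, inst, tr, mode = mode)
      for (f in names(total)) total[[f]] <- total[[f]] + cnt[[f]]
    }
    fold_counts[[fi]] <- total
  }
  rep <- compute_metrics(total)
  attr(rep, "folds") <- fold_counts
  rep
}
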