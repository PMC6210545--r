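# Traditional per-sample classifiers over the four handcrafted features
# (a_res, s_min, s_max, delta_s) plus the consecutive-count event rule.
#
# No SVM implementation ships with this R installation, so the SVM here is
# self-contained: an RBF kernel approximated by random Fourier features
# (Rahimi & Recht) with a linear maximum-margin classifier fitted by
# full-batch subgradient descent on the L2-regularized hinge loss.
# Features are standardized by training-set mean/variance. Gaussian class-
# conditional densities are used for naive Bayes (the features are
# continuous). Both fits are deterministic given the seed.

FEATURE_COLS <- c("a_res", "s_min", "s_max", "delta_s")

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    missing <- setdiff(FEATURE_COLS, names(features))
    if (length(missing) > 0) stopf("feature columns missing: %s", paste(missing, collapse = ", "))
    x <- as.matrix(features[, FEATURE_COLS])
  } else {
    x <- as.matrix(features)
  }
  if (ncol(x) != 4L) stopf("expected 4 feature columns, got %d", ncol(x))
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stopf("features must be finite")
  x
}

#' Train a traditional per-sample fall classifier
#'
#' Fits either a Gaussian naive Bayes model (`kind = "nb"`) or a support-
#' vector classifier with an RBF kernel (`kind = "svm"`, approximated with
#' random Fourier features) on per-sample feature rows. Both classes must
#' be present. Training is deterministic given `seed`.
#'
#' @param features Data frame of feature rows (from [per_sample_features()])
#'   or a numeric matrix with columns `a_res`, `s_min`, `s_max`, `delta_s`.
#' @param labels Per-sample labels, `"Fall"`/`"NotFall"`. Defaults to the
#'   `label` column of `features` when present.
#' @param kind `"nb"` or `"svm"`.
#' @param seed Integer seed (drives the random Fourier draw and the
#'   epoch shuffling; naive Bayes is closed form).
#' @param svm_lambda L2 regularization strength of the hinge objective.
#' @param svm_dim Number of random Fourier features.
#' @param svm_epochs Subgradient-descent epochs.
#' @return A `classic_model` usable with [classify_samples()].
#' @export
train_classic <- function(features, labels = NULL, kind = c("nb", "svm"),
                          seed = 1L, svm_lambda = 1e-4, svm_dim = 200L,
                          svm_epochs = 60L) {
  kind <- match.arg(kind)
  if (is.null(labels)) {
    if (!is.data.frame(features) || !"label" %in% names(features)) {
      stopf("`labels` must be supplied when `features` has no label column")
    }
    labels <- features$label
  }
  x <- feature_matrix(features)
  labels <- as.character(labels)
  if (nrow(x) == 0L) stopf("empty training set")
  if (length(labels) != nrow(x)) stopf("labels length must match feature rows")
  assert_labels(labels)
  if (length(unique(labels)) < 2L) {
    stopf("training data must contain both \"Fall\" and \"NotFall\" examples")
  }
  y <- ifelse(labels == LABEL_FALL, 1, -1)

  model <- if (kind == "nb") {
    fit <- lapply(c(fall = LABEL_FALL, notfall = LABEL_NOTFALL), function(cl) {
      xs <- x[labels == cl, , drop = FALSE]
      list(mu = colMeans(xs),
           sd = pmax(apply(xs, 2, stats::sd), 1e-4),
           log_prior = log(nrow(xs) / nrow(x)))
    })
    list(kind = "nb", fit = fit)
  } else {
    mu <- colMeans(x)
    sd <- pmax(apply(x, 2, stats::sd), 1e-8)
    z <- sweep(sweep(x, 2, mu), 2, sd, "/")
    # gamma analogous to the common 1 / (n_features * var) heuristic on
    # standardized inputs
    gamma <- 1 / ncol(z)
    with_seed(seed, {
      omega <- matrix(stats::rnorm(ncol(z) * svm_dim, sd = sqrt(2 * gamma)),
                      ncol(z), svm_dim)
      phase <- stats::runif(svm_dim, 0, 2 * pi)
    })
    phi <- sqrt(2 / svm_dim) * cos(z %*% omega + matrix(phase, nrow(z), svm_dim, byrow = TRUE))
    wts <- svm_fit_hinge(phi, y, lambda = svm_lambda, epochs = svm_epochs)
    list(kind = "svm", mu = mu, sd = sd, omega = omega, phase = phase,
         svm_dim = svm_dim, w = wts$w, b = wts$b)
  }
  structure(c(model, list(seed = seed)), class = "classic_model")
}

# Full-batch subgradient descent on lambda/2 ||w||^2 + mean(hinge), with a
# decaying step size. Deterministic (no sampling).
svm_fit_hinge <- function(phi, y, lambda, epochs) {
  n <- nrow(phi); d <- ncol(phi)
  w <- numeric(d); b <- 0
  for (ep in seq_len(epochs)) {
    eta <- 1 / (lambda * (ep + 10))
    m <- as.numeric(phi %*% w + b) * y
    viol <- m < 1
    if (any(viol)) {
      gw <- lambda * w - crossprod(phi[viol, , drop = FALSE], y[viol])[, 1] / n
      gb <- -sum(y[viol]) / n
    } else {
      gw <- lambda * w
      gb <- 0
    }
    w <- w - eta * gw
    b <- b - eta * gb
  }
  list(w = w, b = b)
}

#' Classify feature rows with a trained traditional model
#'
#' @param model A `classic_model` from [train_classic()].
#' @param features Feature rows as in [train_classic()] (arity 4).
#' @return Character vector of `"Fall"`/`"NotFall"`, one per row.
#' @export
classify_samples <- function(model, features) {
  if (!inherits(model, "classic_model")) stopf("`model` must be a classic_model")
  x <- feature_matrix(features)
  if (nrow(x) == 0L) return(character(0))
  if (model$kind == "nb") {
    loglik <- function(f) {
      ll <- rep(f$log_prior, nrow(x))
      for (j in seq_len(4)) ll <- ll + stats::dnorm(x[, j], f$mu[j], f$sd[j], log = TRUE)
      ll
    }
    ifelse(loglik(model$fit$fall) > loglik(model$fit$notfall),
           LABEL_FALL, LABEL_NOTFALL)
  } else {
    z <- sweep(sweep(x, 2, model$mu), 2, model$sd, "/")
    phi <- sqrt(2 / model$svm_dim) *
      cos(z %*% model$omega + matrix(model$phase, nrow(z), model$svm_dim, byrow = TRUE))
    score <- as.numeric(phi %*% model$w + model$b)
    ifelse(score > 0, LABEL_FALL, LABEL_NOTFALL)
  }
}

#' Consecutive-count decision rule
#'
#' @param min_count,max_count A run of consecutive per-sample `"Fall"`
#'   predictions raises a fall event iff its length lies in
#'   `[min_count, max_count]` (defaults 3 and 50, the band found ideal at
#'   31.25 Hz: runs shorter than 3 are isolated blips, runs longer than 50
#'   — 1.6 s — look like sustained exertion such as jogging, not a fall).
#' @return A `consecutive_rule` list.
#' @export
consecutive_rule <- function(min_count = 3L, max_count = 50L) {
  min_count <- as.integer(min_count); max_count <- as.integer(max_count)
  if (is.na(min_count) || is.na(max_count) || min_count < 1L || min_count > max_count) {
    stopf("need 1 <= min_count <= max_count")
  }
  structure(list(min_count = min_count, max_count = max_count),
            class = "consecutive_rule")
}

#' Turn per-sample labels into fall events by run length
#'
#' Implements the classifier post-processing rule: a counter increments on
#' each `"Fall"` prediction; at the first `"NotFall"` after a run (or at
#' end of stream) an event covering the run is emitted iff the run length
#' lies within the rule's band, then the counter resets. A run longer than
#' `max_count` emits nothing.
#'
#' @param labels Character vector of per-sample predictions
#'   (`"Fall"`/`"NotFall"`).
#' @param rule A [consecutive_rule()].
#' @param model Model tag recorded on the events (`"nb"`, `"svm"`, ...).
#' @param offset Integer added to event indices, for mapping positions in a
#'   feature-row sequence back to trace sample indices.
#' @return A `detection_events` data frame: `start_idx`, `end_idx` (0-based,
#'   half-open), `model`, `score` (run length for classic models).
#' @export
consecutive_count_decision <- function(labels, rule = consecutive_rule(),
                                       model = "nb", offset = 0L) {
  labels <- as.character(labels)
  assert_labels(labels)
  n <- length(labels)
  starts <- integer(0); ends <- integer(0)
  run_start <- NA_integer_; count <- 0L
  for (i in seq_len(n + 1L)) {
    is_fall <- i <= n && labels[i] == LABEL_FALL
    if (is_fall) {
      if (count == 0L) run_start <- i
      count <- count + 1L
    } else if (count > 0L) {
      if (count >= rule$min_count && count <= rule$max_count) {
        starts <- c(starts, run_start)
        ends <- c(ends, run_start + count)
      }
      count <- 0L
    }
  }
  detection_events(
    start_idx = starts - 1L + offset,
    end_idx = ends - 1L + offset,
    model = model,
    score = ends - starts
  )
}

#' Construct a detection-event table
#'
#' @param start_idx,end_idx 0-based half-open sample index ranges with
#'   `start_idx < end_idx`.
#' @param model Source model tag (`"nb"`, `"svm"`, `"gru"`).
#' @param score Optional per-event confidence.
#' @return A `detection_events` data frame.
#' @export
detection_events <- function(start_idx = integer(0), end_idx = integer(0),
                             model = character(0), score = NA_real_) {
  n <- length(start_idx)
  if (length(end_idx) != n) stopf("start_idx and end_idx lengths differ")
  if (n > 0 && any(end_idx <= start_idx)) stopf("events need start_idx < end_idx")
  df <- data.frame(
    start_idx = as.integer(start_idx), end_idx = as.integer(end_idx),
    model = if (n) rep_len(as.character(model), n) else character(0),
    score = if (n) rep_len(as.numeric(score), n) else numeric(0),
    stringsAsFactors = FALSE
  )
  class(df) <- c("detection_events", "data.frame")
  df
}

#' Run a classic model over a whole trace
#'
#' Convenience pipeline: per-sample features, per-sample classification,
#' consecutive-count rule; event indices refer to trace samples.
#'
#' @param model A `classic_model`.
#' @param trace An [accel_trace()].
#' @param cfg A [feature_config()] (defaults to the trace's rate).
#' @param rule A [consecutive_rule()].
#' @return A `detection_events` data frame.
#' @export
detect_classic <- function(model, trace,
                           cfg = feature_config(rate_hz = trace_rate(trace)),
                           rule = consecutive_rule()) {
  rows <- per_sample_features(trace, cfg)
  preds <- classify_samples(model, rows)
  consecutive_count_decision(preds, rule, model = model$kind,
                             offset = rows$idx[1])
}

#' Save / load a trained detector
#'
#' One portable file per model (RDS); works for `classic_model` and
#' `gru_model` objects.
#' @param model The model object.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  readRDS(path)
}
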