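test_that("network construction is deterministic with a softmax head", {
  cfg <- gru_config(steps_n = 8, gru_units = 6, fc_units = 5, seed = 11)
  m1 <- build_gru_model(cfg)
  m2 <- build_gru_model(cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(dim(m1$params$Wz), c(3L, 6L))   # input arity 3
  expect_equal(dim(m1$params$Wo), c(5L, 2L))   # 2-way output

  set.seed(1)
  X <- lapply(1:8, function(t) matrix(rnorm(9), 3, 3))
  p <- wristfall:::gru_forward(m1$params, X)$p
  expect_equal(rowSums(p), rep(1, 3))
  expect_true(all(p >= 0 & p <= 1))

  # all-zero parameters are symmetric between the classes
  zero <- lapply(m1$params, function(q) q * 0)
  p0 <- wristfall:::gru_forward(zero, X)$p
  expect_equal(as.numeric(p0), rep(0.5, 6))

  expect_error(gru_config(steps_n = 0), "steps_n")
  expect_error(gru_config(threshold = 1), "threshold")
})

test_that("analytic BPTT gradients match finite differences", {
  cfg <- gru_config(steps_n = 5, gru_units = 4, fc_units = 3, seed = 21)
  model <- build_gru_model(cfg)
  params <- model$params
  set.seed(2)
  X <- lapply(1:5, function(t) matrix(rnorm(9, sd = 0.8), 3, 3))
  y <- c(1L, 0L, 1L)
  w <- c(1, 2, 1)
  got <- wristfall:::gru_loss_grads(params, X, y, w)
  eps <- 1e-6
  for (nm in names(params)) {
    g_num <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      g_num[i] <- (wristfall:::gru_loss_grads(up, X, y, w)$loss -
                   wristfall:::gru_loss_grads(dn, X, y, w)$loss) / (2 * eps)
    }
    denom <- pmax(abs(g_num), abs(got$grads[[nm]]), 1e-4)
    expect_lt(max(abs(g_num - got$grads[[nm]]) / denom), 1e-4)
  }
})

test_that("training reduces the loss, reproducibly, and rejects one-class data", {
  traces <- small_labelled_traces(2, seed = 1)
  cfg <- gru_config(steps_n = 20, gru_units = 8, fc_units = 8, seed = 1)
  spec <- gru_train_spec(epochs = 5, max_windows = 1500)
  m <- train_gru(build_gru_model(cfg), traces, spec)
  expect_true(m$trained)
  expect_equal(nrow(m$history), 5L)
  expect_lt(m$history$loss[5], m$history$loss[1])

  m2 <- train_gru(build_gru_model(cfg), traces, spec)
  expect_identical(m$params, m2$params)
  expect_identical(m$history$loss, m2$history$loss)

  quiet <- simulate_adl("walking", seed = 5)
  expect_error(train_gru(build_gru_model(cfg), list(quiet), spec), "both")
})

test_that("sliding probabilities equal independent per-window recomputation", {
  cfg <- gru_config(steps_n = 15, gru_units = 6, fc_units = 5, seed = 3)
  model <- build_gru_model(cfg)
  tr <- random_trace(200, seed = 31)
  probs <- predict_probabilities(model, tr, chunk = 37)  # odd chunking on purpose
  expect_equal(nrow(probs), 200 - 15 + 1)
  expect_equal(probs$idx[1], 14L)
  expect_true(all(probs$p_fall >= 0 & probs$p_fall <= 1))

  M <- as.matrix(as.data.frame(tr)[, c("ax", "ay", "az")])
  oracle <- vapply(15:200, function(e) {
    X <- lapply(1:15, function(t) M[e - 15 + t, , drop = FALSE])
    wristfall:::gru_forward(model$params, X)$p[1, 2]
  }, numeric(1))
  expect_equal(probs$p_fall, oracle, tolerance = 1e-12)

  expect_error(predict_probabilities(model, random_trace(10, 1)), "shorter")
})

test_that("average-of-k heuristic triggers, merges and respects ties", {
  cfg <- gru_config(heuristic_k = 10, threshold = 0.5)
  mk <- function(p) data.frame(idx = seq_along(p) + 39L, p_fall = p)

  ev <- heuristic_decision(mk(rep(1, 10)), cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$end_idx - ev$start_idx, 10L)  # covers the k final indices

  expect_equal(nrow(heuristic_decision(mk(rep(0, 50)), cfg)), 0L)

  # mean exactly at the threshold triggers (>= convention); dyadic values
  # keep the comparison exact in floating point
  tie <- mk(c(rep(0.75, 5), rep(0.25, 5)))
  expect_equal(nrow(heuristic_decision(tie, cfg)), 1L)

  # a sustained high block yields one merged event, not one per trigger
  ev <- heuristic_decision(mk(c(rep(0, 5), rep(1, 20), rep(0, 10))), cfg)
  expect_equal(nrow(ev), 1L)

  expect_error(heuristic_decision(mk(rep(0.4, 5)), cfg), "heuristic_k")
  expect_error(heuristic_decision(mk(rep(2, 12)), cfg), "0, 1")
})

test_that("isolated spikes cannot trigger and bumping one probability never untriggers", {
  cfg <- gru_config(heuristic_k = 10, threshold = 0.5)
  set.seed(6)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    p <- rep(0, n)
    p[sample(n, 1)] <- 1
    probs <- data.frame(idx = seq_len(n) + 39L, p_fall = p)
    expect_equal(nrow(heuristic_decision(probs, cfg)), 0L)
  }
  for (i in 1:20) {
    n <- sample(30:120, 1)
    p <- runif(n)
    probs <- data.frame(idx = seq_len(n) + 39L, p_fall = p)
    before <- nrow(heuristic_decision(probs, cfg)) > 0
    j <- sample(n, 1)
    probs$p_fall[j] <- min(1, probs$p_fall[j] + runif(1, 0, 1 - probs$p_fall[j]))
    after <- nrow(heuristic_decision(probs, cfg)) > 0
    if (before) expect_true(after)
  }
})

test_that("one prediction window spans 1.28 s at the defaults", {
  expect_equal(gru_window_duration(gru_config()), 1.28)
})
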