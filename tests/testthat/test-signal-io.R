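test_that("CSV round trip is the identity on valid traces", {
  tr <- random_trace(50, seed = 7)
  tr$activity[10:20] <- "waving"
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path, source = "synthetic")
  expect_equal(as.data.frame(back), as.data.frame(tr),
               ignore_attr = TRUE, tolerance = 0)
  expect_equal(back$activity, tr$activity)

  # 3-row well-formed file parses to a 3-row trace
  writeLines(c("t,ax,ay,az,label",
               "0.000000,0.1,0.2,1.0,NotFall",
               "0.032000,0.1,0.2,1.0,Fall",
               "0.064000,0.1,0.2,1.0,NotFall"), path)
  expect_equal(nrow(read_trace_csv(path)), 3L)
})

test_that("empty trace writes a header-only file that reads back empty", {
  tr <- accel_trace(numeric(0), numeric(0), numeric(0), numeric(0),
                    label = character(0), activity = character(0),
                    rate_hz = 31.25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_trace_csv(path)), 0L)
})

test_that("malformed input is rejected with location information", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay,az,label",
               "0.0,0.1,0.2,1.0,NotFall",
               "0.032,oops,0.2,1.0,NotFall"), path)
  expect_error(read_trace_csv(path), "line 3")

  writeLines(c("t,ax,ay,az,label",
               "0.0,0.1,0.2,1.0,Maybe"), path)
  expect_error(read_trace_csv(path), "label")

  writeLines(c("t,ax,ay,az,label",
               "0.5,0.1,0.2,1.0,NotFall",
               "0.2,0.1,0.2,1.0,NotFall"), path)
  expect_error(read_trace_csv(path), "increasing")

  expect_error(read_trace_csv(file.path(tempdir(), "no-such-file.csv")), "not found")
})

test_that("downsampling hits the exact floor count and preserves survivors", {
  tr <- random_trace(320, seed = 11, rate_hz = 100)
  down <- downsample_random(tr, 31.25, seed = 5)
  expect_equal(nrow(down), 100L)  # floor(320 * 0.3125)
  expect_equal(attr(down, "rate_hz"), 31.25)

  # determinism
  down2 <- downsample_random(tr, 31.25, seed = 5)
  expect_identical(as.data.frame(down), as.data.frame(down2))

  # every surviving sample exists verbatim (values + label) in the source,
  # in order: brute-force subsequence check on value tuples
  key <- function(x) paste(x$ax, x$ay, x$az, x$label)
  expect_true(all(key(down) %in% key(tr)))
  pos <- match(key(down), key(tr))
  expect_true(all(diff(pos) > 0))

  # uniform output grid at the target rate
  expect_equal(diff(down$t), rep(1 / 31.25, 99), tolerance = 1e-9)
  expect_error(downsample_random(tr, 200, seed = 1), "upsample_random")
})

test_that("upsampling hits the exact rounded count and inserts neighbour means", {
  tr <- random_trace(64, seed = 3, rate_hz = 20)
  up <- upsample_random(tr, 31.25, seed = 9)
  expect_equal(nrow(up), 100L)  # round(64 * 1.5625)
  ins <- attr(up, "inserted")
  expect_length(ins, 36L)
  # every inserted component equals the mean of its immediate neighbours
  for (j in ins) {
    expect_equal(up$ax[j], (up$ax[j - 1] + up$ax[j + 1]) / 2)
    expect_equal(up$ay[j], (up$ay[j - 1] + up$ay[j + 1]) / 2)
    expect_equal(up$az[j], (up$az[j - 1] + up$az[j + 1]) / 2)
  }
  # non-inserted samples are the source, verbatim and in order
  expect_equal(up$ax[-ins], tr$ax)
  expect_equal(up$label[-ins], tr$label)

  # constant trace stays constant
  const <- accel_trace(t = (0:9) / 20, ax = rep(0.5, 10), ay = rep(0, 10),
                       az = rep(1, 10), rate_hz = 20)
  upc <- upsample_random(const, 31.25, seed = 1)
  expect_true(all(upc$ax == 0.5) && all(upc$az == 1))

  expect_error(upsample_random(tr, 10, seed = 1), "downsample_random")
  short <- accel_trace(t = 0, ax = 0, ay = 0, az = 1, rate_hz = 20)
  expect_error(upsample_random(short, 31.25, seed = 1), "at least 2")
})

test_that("inserted labels follow the shared-label rule with Fall on ties", {
  tr <- accel_trace(
    t = (0:5) / 10, ax = 1:6, ay = rep(0, 6), az = rep(0, 6),
    label = c("NotFall", "NotFall", "Fall", "Fall", "NotFall", "NotFall"),
    rate_hz = 10
  )
  # force many insertions so every gap (including the disagreeing ones at
  # the run boundaries) receives at least one
  up <- upsample_random(tr, 40, seed = 2)
  ins <- attr(up, "inserted")
  orig_pos <- setdiff(seq_len(nrow(up)), ins)
  for (j in ins) {
    left <- max(orig_pos[orig_pos < j])
    right <- min(orig_pos[orig_pos > j])
    li <- which(orig_pos == left); ri <- which(orig_pos == right)
    expected <- if (tr$label[li] == tr$label[ri]) tr$label[li] else "Fall"
    expect_identical(up$label[j], expected)
  }
})

test_that("resampled output rate matches the target over any 10 s span", {
  tr <- random_trace(2000, seed = 21, rate_hz = 100)
  down <- downsample_random(tr, 31.25, seed = 4)
  up <- upsample_random(random_trace(400, seed = 22, rate_hz = 20), 31.25, seed = 4)
  for (res in list(down, up)) {
    span <- res$t[nrow(res)] - res$t[1]
    windows <- seq(res$t[1], max(res$t[1], res$t[nrow(res)] - 10), by = 5)
    for (w0 in windows) {
      n_in <- sum(res$t >= w0 & res$t < w0 + 10)
      expect_lte(abs(n_in - 31.25 * min(10, span)), 1)
    }
  }
})

test_that("fall-peak label enforcement relabels the peak and is idempotent", {
  f <- simulate_fall(fall_shape_params(), seed = 13)
  res <- resultant_series(f)
  peak <- which.max(res)
  # mislabel the peak region deliberately
  broken <- f
  broken$label[] <- "NotFall"
  broken$label[5] <- "Fall"   # keep it a fall-session file
  fixed <- enforce_fall_peak_labels(broken, margin_s = 0.5)
  expect_identical(fixed$label[peak], "Fall")
  in_margin <- abs(broken$t - broken$t[peak]) <= 0.5
  expect_true(all(fixed$label[in_margin] == "Fall"))
  expect_identical(fixed$label[!in_margin], broken$label[!in_margin])

  # idempotent; never removes a Fall label
  again <- enforce_fall_peak_labels(fixed, margin_s = 0.5)
  expect_identical(again$label, fixed$label)
  expect_true(all(which(broken$label == "Fall") %in% which(fixed$label == "Fall")))

  # pure-ADL file is a contract error
  adl <- simulate_adl("walking", seed = 2)
  expect_error(enforce_fall_peak_labels(adl), "fall-session")
})
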