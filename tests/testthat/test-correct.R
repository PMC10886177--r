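# misidentification correction and Kalman smoothing

test_that("kalman_smooth handles constant input and the R -> 0 limit", {
  expect_equal(kalman_smooth(rep(3, 50)), rep(3, 50))   # zero innovation
  set.seed(1)
  y <- cumsum(rnorm(100))
  # R -> 0: gain -> 1, output tracks the measurements
  out <- kalman_smooth(y, kalman_params(R = 1e-12))
  expect_equal(out, y, tolerance = 1e-6)
  expect_error(kalman_params(R = 0), "positive")
  expect_error(kalman_params(Q = -1), "non-negative")
  expect_error(kalman_smooth(numeric(0)), "nonempty")
})

test_that("kalman_smooth matches an independently coded recursion", {
  # second implementation, written directly from the predict/update
  # equations, scalar state
  oracle <- function(y, A, B, C, Q, R, x0, P0, u = 0) {
    x <- x0; P <- P0
    out <- numeric(length(y))
    for (k in seq_along(y)) {
      x_prior <- A * x + B * u
      P_prior <- A * P * A + Q
      K <- (P_prior * C) / (C * P_prior * C + R)
      x <- x_prior + K * (y[k] - C * x_prior)
      P <- (1 - K * C) * P_prior
      out[k] <- x
    }
    out
  }
  set.seed(42)
  y <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, 0, 0.3)
  for (p in list(kalman_params(), kalman_params(A = 0.95, Q = 0.05, R = 0.4),
                 kalman_params(B = 0.1, x0 = 2, P0 = 10))) {
    got <- kalman_smooth(y, p, u = 1)
    want <- oracle(y, p$A, p$B, p$C, p$Q, p$R,
                   if (is.null(p$x0)) y[1] else p$x0, p$P0, u = 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("kalman_smooth with A=C=1, B=0 is shift-equivariant", {
  set.seed(7)
  y <- rnorm(120, 5, 2)
  base <- kalman_smooth(y, kalman_params(x0 = y[1]))
  shifted <- kalman_smooth(y + 100, kalman_params(x0 = y[1] + 100))
  expect_equal(shifted, base + 100, tolerance = 1e-9)
})

test_that("correct_frame replaces implicated keypoints by interpolation", {
  g <- generate_sequence(data.frame(label = "lift", frames = 60L),
                         noise_px = 0, seed = 2)
  mis <- inject_misidentification(g$seq, 0.02, magnitude = 0.5,
                                  duration = 1L, seed = 6)
  t0 <- unique(mis$log$records$frame)[1L]
  w <- mock_classify(g$labels)
  rep0 <- classify_sequence(mis$seq, w, persistence = 1L)
  expect_identical(rep0$status[t0], "misidentified")
  res <- correct_frame(mis$seq, t0, rep0, w)
  expect_true(res$corrected)
  expect_identical(res$label, "lift")
  # implicated keypoints land at the neighbor midpoint (n = 1 interpolation)
  for (k in res$keypoints) {
    mid <- (mis$seq$arr[t0 - 1L, k + 1L, 1:2] +
              mis$seq$arr[t0 + 1L, k + 1L, 1:2]) / 2
    expect_equal(unclass(res$frame)[k + 1L, 1:2], mid, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # corrected bone length is within 5% of truth
  topo <- body25_topology()
  link <- mis$log$records$link[1L]
  pr <- topo$links[link, 1L] + 1L; ch <- topo$links[link, 2L] + 1L
  blen <- function(kp) sqrt(sum((kp[ch, 1:2] - kp[pr, 1:2])^2))
  truth_len <- blen(g$seq$arr[t0, , ])
  expect_lt(abs(blen(unclass(res$frame)) - truth_len) / truth_len, 0.05)
})

test_that("frames without a dominant action stay uncorrected", {
  g <- generate_sequence(data.frame(label = c("bend", "lift"),
                                    frames = c(11L, 10L)),
                         noise_px = 0, seed = 3)
  w <- mock_classify(g$labels, labels = c("bend", "lift"))
  rep0 <- classify_sequence(g$seq, w)
  # window at the boundary splits 11/10: no >60% dominant
  res <- correct_frame(g$seq, 11L, rep0, w)
  expect_false(res$corrected)
  expect_true(is.na(res$label))
})

test_that("correct_sequence lowers the misidentification rate", {
  g <- generate_sequence(data.frame(label = c("bend", "lift"),
                                    frames = c(200L, 200L)),
                         noise_px = 1, seed = 4)
  mis <- inject_misidentification(g$seq, 0.2, magnitude = 0.5,
                                  duration = 4L, seed = 5)
  w <- mock_classify(g$labels)
  rep0 <- classify_sequence(mis$seq, w)
  out <- correct_sequence(mis$seq, rep0, w)
  expect_lt(out$misid_rate_after, out$misid_rate_before)

  # zero misidentification: output differs only by smoothing
  rep1 <- classify_sequence(g$seq, w)
  out1 <- correct_sequence(g$seq, rep1, w)
  expect_identical(out1$misid_rate_before, 0)
  sm <- smooth_sequence(g$seq)
  expect_identical(out1$seq$arr, sm$arr)

  # smoothing disabled: correction-only passthrough on clean input
  out2 <- correct_sequence(g$seq, rep1, w, smooth = FALSE)
  expect_identical(out2$seq$arr, g$seq$arr)
})
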