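# frame-integrity discrimination: presence, bone anomalies, heterogeneity

test_that("detect_missing applies the absence convention", {
  fr <- neutral_frame()
  expect_identical(detect_missing(fr), integer(0))

  kp <- unclass(fr)
  kp[4L, ] <- c(0, 0, 0)                     # id 3: zero coords + zero conf
  kp[8L, 3L] <- 0.05                         # id 7: low confidence
  fr2 <- skeleton_frame(kp)
  expect_identical(detect_missing(fr2), c(3L, 7L))

  empty <- skeleton_frame(matrix(0, 25L, 3L))
  expect_identical(detect_missing(empty), 0:24)
})

test_that("phi_anomaly measures relative squared-bone-length change", {
  g <- generate_sequence(data.frame(label = "stand", frames = 20L),
                         noise_px = 0, seed = 1)
  # static zero-noise skeleton: no anomaly at any interval
  r <- phi_anomaly(g$seq, 3L, i = 10L)
  expect_true(r$evaluable)
  expect_false(r$flag)
  expect_lt(r$magnitude, 1e-9)

  # stretch the left forearm (link 12, LElbow->LWrist) by x1.5 at t+i
  topo <- body25_topology()
  seq2 <- g$seq
  elbow <- seq2$arr[10L, 7L, 1:2]
  wrist <- seq2$arr[10L, 8L, 1:2]
  seq2$arr[10L, 8L, 1:2] <- elbow + 1.5 * (wrist - elbow)
  r2 <- phi_anomaly(seq2, 5L, i = 5L, tau = 0.2)
  expect_true(r2$flag)
  expect_equal(r2$magnitude, 1.5^2 - 1, tolerance = 1e-9)   # 1.25
  expect_identical(r2$links, 12L)

  # rigid whole-body motion between frames: invariant, no flag
  seq3 <- g$seq
  fr <- rigid_transform(get_frame(seq3, 15L), 0.7, 40, -25)
  seq3$arr[15L, , ] <- unclass(fr)
  r3 <- phi_anomaly(seq3, 10L, i = 5L)
  expect_false(r3$flag)
  expect_lt(r3$magnitude, 1e-9)

  # absent keypoint in either frame: not evaluable
  seq4 <- g$seq
  seq4$arr[6L, 12L, ] <- 0
  expect_false(phi_anomaly(seq4, 6L, i = 1L)$evaluable)
  expect_false(phi_anomaly(seq4, 5L, i = 1L)$evaluable)
})

test_that("action_heterogeneity applies the strict 60% dominance rule", {
  w_window <- function(counts) {            # build one-hot windows
    labs <- rep(names(counts), counts)
    w <- matrix(0, length(labs), length(counts),
                dimnames = list(NULL, names(counts)))
    w[cbind(seq_along(labs), match(labs, names(counts)))] <- 1
    w
  }
  # 15 of 21 argmax A, center labelled B -> heterogeneous, dominant A
  r <- action_heterogeneity(w_window(c(A = 15L, B = 6L)), "B")
  expect_true(r$heterogeneous)
  expect_identical(r$dominant, "A")
  expect_equal(r$proportion, 15 / 21)

  # 12 of 21 (~0.571): below threshold, no dominant
  r2 <- action_heterogeneity(w_window(c(A = 12L, B = 9L)), "B")
  expect_false(r2$heterogeneous)
  expect_true(is.na(r2$dominant))

  # exactly 60% (12 of 20): strict reading, no dominant
  r3 <- action_heterogeneity(w_window(c(A = 12L, B = 8L)), "B")
  expect_true(is.na(r3$dominant))

  expect_error(action_heterogeneity(matrix(numeric(), 0L, 2L), "A"),
               "nonempty")
})

test_that("classify_sequence: clean sequences are 100% complete", {
  g <- generate_sequence(data.frame(label = c("bend", "lift"),
                                    frames = c(60L, 60L)),
                         noise_px = 0, seed = 5)
  rep0 <- classify_sequence(g$seq, mock_classify(g$labels))
  expect_true(all(rep0$status == "complete"))
  # determinism
  rep1 <- classify_sequence(g$seq, mock_classify(g$labels))
  expect_identical(rep0, rep1)
})

test_that("classify_sequence flags injected corruption with evidence", {
  g <- generate_sequence(data.frame(label = "bend", frames = 120L),
                         noise_px = 0.5, seed = 11)
  mis <- inject_misidentification(g$seq, 0.1, magnitude = 0.6,
                                  duration = 4L, seed = 3)
  w <- mock_classify(g$labels)
  rep0 <- classify_sequence(mis$seq, w)
  hit <- unique(mis$log$records$frame)
  expect_true(all(rep0$status[hit] == "misidentified"))
  expect_true(all(rep0$status[-hit] == "complete"))
  expect_true(all(nzchar(rep0$implicated_links[hit])))
  # invariant: missing status iff missing ids recorded
  msg <- inject_missing(g$seq, 0.1, seed = 4)
  rep1 <- classify_sequence(msg$seq, w)
  expect_identical(rep1$status == "missing", nzchar(rep1$missing_ids))

  # missing takes precedence over everything
  both <- inject_missing(mis$seq, 0.2, seed = 5)
  rep2 <- classify_sequence(both$seq, w)
  expect_true(all(rep2$status[rep2$n_missing > 0L] == "missing"))
})

test_that("label flips inside a homogeneous window are heterogeneous", {
  g <- generate_sequence(data.frame(label = "lift", frames = 80L),
                         noise_px = 0, seed = 2)
  labs <- g$labels
  labs[40L] <- "bend"                       # single flipped frame
  w <- mock_classify(labs, labels = c("bend", "lift"))
  rep0 <- classify_sequence(g$seq, w)
  expect_identical(rep0$status[40L], "misidentified")
  expect_true(rep0$heterogeneous[40L])
  expect_identical(rep0$dominant[40L], "lift")
  # policy "both" requires the bone channel too: geometry is clean here
  rep2 <- classify_sequence(g$seq, w, policy = "both")
  expect_identical(rep2$status[40L], "complete")
})

test_that("single-frame bone jitter is suppressed by persistence", {
  g <- generate_sequence(data.frame(label = "stand", frames = 60L),
                         noise_px = 0, seed = 8)
  seq2 <- g$seq
  seq2$arr[30L, 8L, 1:2] <- seq2$arr[30L, 8L, 1:2] + c(80, 0)  # 1-frame jump
  rep0 <- classify_sequence(seq2, NULL, persistence = 2L)
  expect_identical(rep0$status[30L], "complete")
  rep1 <- classify_sequence(seq2, NULL, persistence = 1L)
  expect_identical(rep1$status[30L], "misidentified")
})

test_that("classify_frame returns the matching report row", {
  g <- generate_sequence(data.frame(label = "stand", frames = 30L),
                         noise_px = 0, seed = 9)
  row <- classify_frame(g$seq, 12L)
  expect_identical(row$status, "complete")
  expect_identical(row$frame, g$seq$frame_index[12L])
})
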