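# synthetic motion generator and corruption injection

test_that("generated motion keeps bone lengths constant", {
  g <- generate_sequence(data.frame(label = c("bend", "lift", "reach"),
                                    frames = c(40L, 40L, 40L)),
                         noise_px = 0, seed = 1)
  topo <- body25_topology()
  K1 <- build_link_matrix(get_frame(g$seq, 1L), topo)
  base <- diag(gram(K1))
  for (t in seq(5L, 120L, by = 5L)) {
    Kt <- build_link_matrix(get_frame(g$seq, t), topo)
    phi <- temporal_chain(K1, Kt, interval = t - 1L)
    expect_lt(max(abs(diag(phi)) / base), 1e-9)
  }
  # and the discriminator sees 100% complete frames at zero noise
  rep0 <- classify_sequence(g$seq)
  expect_true(all(rep0$status == "complete"))
})

test_that("generator is deterministic and static scripts are static", {
  sc <- data.frame(label = "bend", frames = 30L)
  a <- generate_sequence(sc, noise_px = 2, seed = 5)
  b <- generate_sequence(sc, noise_px = 2, seed = 5)
  expect_identical(a$seq$arr, b$seq$arr)

  st <- generate_sequence(data.frame(label = "stand", frames = 20L),
                          noise_px = 0, seed = 1)
  for (t in 2:20)
    expect_identical(st$seq$arr[t, , ], st$seq$arr[1L, , ])

  expect_error(generate_sequence(data.frame(label = "fly", frames = 10L)),
               "unknown action")
  expect_error(generate_sequence(data.frame(label = "bend", frames = 0L)),
               "positive")
})

test_that("inject_missing hits the target rate and logs the truth", {
  g <- generate_sequence(data.frame(label = "bend", frames = 2000L),
                         noise_px = 1, seed = 2)
  out0 <- inject_missing(g$seq, 0)
  expect_identical(out0$seq$arr, g$seq$arr)
  expect_equal(nrow(out0$log$records), 0L)

  out <- inject_missing(g$seq, 0.1, burst_len = 5L, seed = 3)
  rep0 <- classify_sequence(out$seq)
  rates <- corruption_rates(rep0)$missing / 100
  # groups sharing keypoints (Trunk/Neck, arms) exceed their own target;
  # every group's realized rate is within 10% relative of target or above
  expect_true(all(rates >= 0.09))
  expect_true(all(rates <= 0.25))
  # exact per-group placement: legs share no keypoints with other groups
  expect_true(abs(rates[["Leg-L"]] - 0.1) <= 0.01)
  expect_true(abs(rates[["Leg-R"]] - 0.1) <= 0.01)

  expect_error(inject_missing(g$seq, 0.1, burst_len = 3000L), "exceeds")

  restored <- restore_truth(out$seq, out$log)
  expect_identical(restored$arr, g$seq$arr)
})

test_that("inject_misidentification changes bone lengths as requested", {
  g <- generate_sequence(data.frame(label = "lift", frames = 400L),
                         noise_px = 0, seed = 6)
  out0 <- inject_misidentification(g$seq, 0)
  expect_identical(out0$seq$arr, g$seq$arr)

  out <- inject_misidentification(g$seq, 0.05, magnitude = 0.5,
                                  duration = 4L, seed = 7)
  out2 <- inject_misidentification(g$seq, 0.05, magnitude = 0.5,
                                   duration = 4L, seed = 7)
  expect_identical(out$seq$arr, out2$seq$arr)     # same seed, same events

  # relative squared-length change of the implicated link is 1.5^2 - 1
  topo <- body25_topology()
  r <- out$log$records
  # pick an event frame whose predecessor is clean
  cand <- which(r$frame > 1L & !(r$frame - 1L) %in% r$frame)
  f <- r$frame[cand[1L]]; link <- r$link[cand[1L]]
  pr <- topo$links[link, 1L] + 1L; ch <- topo$links[link, 2L] + 1L
  l2 <- function(arr) sum((arr[f, ch, 1:2] - arr[f, pr, 1:2])^2)
  expect_equal(l2(out$seq$arr) / l2(g$seq$arr) - 1, 1.25, tolerance = 1e-9)
  # and phi_anomaly agrees
  expect_equal(phi_anomaly(out$seq, f - 1L, i = 1L)$magnitude, 1.25,
               tolerance = 0.05)

  restored <- restore_truth(out$seq, out$log)
  expect_identical(restored$arr, g$seq$arr)
})

test_that("stacked corruption round-trips through both logs", {
  g <- generate_sequence(data.frame(label = "bend", frames = 300L),
                         noise_px = 1, seed = 8)
  mis <- inject_misidentification(g$seq, 0.05, seed = 9)
  msg <- inject_missing(mis$seq, 0.1, seed = 10)
  # restore in reverse order of application
  restored <- restore_truth(msg$seq, list(msg$log, mis$log))
  expect_identical(restored$arr, g$seq$arr)
})
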