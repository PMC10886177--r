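# joint angles and the REBA scoring engine

test_that("joint angles honor the reference conventions", {
  # build a frame with known geometry: vertical trunk & neck, straight
  # right leg, right forearm perpendicular to a vertical right upper arm
  kp <- cbind(matrix(0, 25L, 2L), 0.9)
  set <- function(m, id, x, y) { m[id + 1L, 1:2] <- c(x, y); m }
  kp <- set(kp, 8L, 100, 300)   # MidHip
  kp <- set(kp, 1L, 100, 150)   # Neck: trunk exactly vertical
  kp <- set(kp, 0L, 100, 105)   # Nose: neck vertical
  kp <- set(kp, 9L, 125, 300)   # RHip
  kp <- set(kp, 10L, 125, 410)  # RKnee
  kp <- set(kp, 11L, 125, 515)  # RAnkle: hip-knee-ankle collinear
  kp <- set(kp, 2L, 140, 150)   # RShoulder
  kp <- set(kp, 3L, 140, 230)   # RElbow: upper arm vertical down
  kp <- set(kp, 4L, 210, 230)   # RWrist: forearm perpendicular
  kp <- set(kp, 12L, 75, 300)   # left leg bent 90 deg at the knee
  kp <- set(kp, 13L, 75, 410)
  kp <- set(kp, 14L, 180, 410)
  kp <- set(kp, 5L, 60, 150)    # left arm straight down
  kp <- set(kp, 6L, 60, 230)
  kp <- set(kp, 7L, 60, 310)
  fr <- skeleton_frame(kp)
  a <- joint_angles(fr)
  expect_equal(a[["trunk"]], 0)
  expect_equal(a[["neck"]], 0)
  expect_equal(a[["leg_r"]], 0)            # collinear: zero flexion
  expect_equal(a[["leg_l"]], 90)
  expect_equal(a[["upper_arm_r"]], 0)
  expect_equal(a[["lower_arm_r"]], 90)     # perpendicular forearm
  expect_equal(a[["lower_arm_l"]], 0)      # straight arm
  expect_true(all(a >= 0 & a <= 180, na.rm = TRUE))

  # absent keypoints mark the affected angles unavailable
  kp2 <- kp; kp2[5L, ] <- 0                # RWrist (id 4) absent
  a2 <- joint_angles(skeleton_frame(kp2))
  expect_true(is.na(a2[["lower_arm_r"]]))
  expect_false(is.na(a2[["upper_arm_r"]]))
})

test_that("angles are invariant to translation/scale; rotation shifts the
           vertical-referenced angles by theta", {
  fr <- neutral_frame()
  a0 <- joint_angles(fr)
  moved <- rigid_transform(fr, 0, 321, -77)
  expect_equal(joint_angles(moved), a0, tolerance = 1e-9)
  kp <- unclass(fr); kp[, 1:2] <- kp[, 1:2] * 2.5
  expect_equal(joint_angles(skeleton_frame(kp)), a0, tolerance = 1e-9)

  # theta below the smallest neutral deviation: unsigned angles then shift
  # by exactly theta regardless of rotation sense
  theta <- 3
  rot <- rigid_transform(fr, theta * pi / 180)
  a1 <- joint_angles(rot)
  # vertical-referenced angles move by exactly theta (forward-leaning pose)
  for (nm in c("trunk", "neck", "upper_arm_l", "upper_arm_r"))
    expect_equal(abs(a1[[nm]] - a0[[nm]]), theta, tolerance = 1e-6)
  # interior-angle flexions are rotation invariant
  for (nm in c("leg_l", "leg_r", "lower_arm_l", "lower_arm_r"))
    expect_equal(a1[[nm]], a0[[nm]], tolerance = 1e-9)
})

test_that("neutral posture scores final 1, Negligible", {
  angles <- c(trunk = 0, neck = 0, leg_l = 0, leg_r = 0,
              upper_arm_l = 0, upper_arm_r = 0,
              lower_arm_l = 80, lower_arm_r = 80)
  r <- reba_score(angles, reba_config())
  expect_identical(r$final_score, 1L)
  expect_identical(r$risk_level, "Negligible")
  expect_identical(r$suggestion, "None necessary")

  # unavailable required angles raise an error listing them
  angles2 <- angles; angles2[["trunk"]] <- NA
  expect_error(reba_score(angles2), "trunk")
})

test_that("risk_level reproduces the published bins", {
  expect_identical(risk_level(1L)$risk, "Negligible")
  expect_identical(risk_level(1L)$suggestion, "None necessary")
  expect_identical(risk_level(2L)$risk, "Low")
  expect_identical(risk_level(3L)$risk, "Low")
  expect_identical(risk_level(3L)$suggestion, "Maybe necessary")
  expect_identical(risk_level(4L)$risk, "Medium")
  expect_identical(risk_level(7L)$risk, "Medium")
  expect_identical(risk_level(8L)$risk, "High")
  expect_identical(risk_level(10L)$suggestion, "Necessary soon")
  expect_identical(risk_level(11L)$risk, "Very high")
  expect_identical(risk_level(12L)$risk, "Very high")
  expect_identical(risk_level(12L)$suggestion, "Necessary now")
  expect_identical(risk_level(15L)$risk, "Very high")
  expect_error(risk_level(0L), "1, 15")
  expect_error(risk_level(16L), "1, 15")
})

# full enumeration grid over every scoring-table input
reba_grid <- function() {
  expand.grid(trunk = 1:5, neck = 1:3, legs = 1:4, ua = 1:6, la = 1:2,
              wrist = 1:3, load = 0:3, coupling = 0:3, activity = 0:3)
}

test_that("exhaustive enumeration: extremes match an independent oracle", {
  g <- reba_grid()
  got <- reba_from_scores(g$trunk, g$neck, g$legs, g$ua, g$la, g$wrist,
                          g$load, g$coupling, g$activity)
  # independent oracle: the published tables typed directly here
  A <- array(0L, c(5, 3, 4))
  A[, 1, ] <- rbind(c(1,2,3,4), c(2,3,4,5), c(2,4,5,6), c(3,5,6,7), c(4,6,7,8))
  A[, 2, ] <- rbind(c(1,2,3,4), c(3,4,5,6), c(4,5,6,7), c(5,6,7,8), c(6,7,8,9))
  A[, 3, ] <- rbind(c(3,3,5,6), c(4,5,6,7), c(5,6,7,8), c(6,7,8,9), c(7,8,9,9))
  B <- array(0L, c(6, 2, 3))
  B[, 1, ] <- rbind(c(1,2,2), c(1,2,3), c(3,4,5), c(4,5,5), c(6,7,8), c(7,8,8))
  B[, 2, ] <- rbind(c(1,2,3), c(2,3,4), c(4,5,5), c(5,6,7), c(7,8,8), c(8,9,9))
  Cm <- rbind(c(1,1,1,2,3,3,4,5,6,7,7,7),   c(1,2,2,3,4,4,5,6,6,7,7,8),
              c(2,3,3,3,4,5,6,7,7,8,8,8),   c(3,4,4,4,5,6,7,8,8,9,9,9),
              c(4,4,4,5,6,7,8,8,9,9,9,9),   c(6,6,6,7,8,8,9,9,10,10,10,10),
              c(7,7,7,8,9,9,9,10,10,11,11,11),
              c(8,8,8,9,10,10,10,10,10,11,11,11),
              c(9,9,9,10,10,10,11,11,11,12,12,12),
              c(10,10,10,11,11,11,11,12,12,12,12,12),
              c(11,11,11,11,12,12,12,12,12,12,12,12),
              c(12,12,12,12,12,12,12,12,12,12,12,12))
  sa <- pmin(A[cbind(g$trunk, g$neck, g$legs)] + g$load, 12L)
  sb <- pmin(B[cbind(g$ua, g$la, g$wrist)] + g$coupling, 12L)
  want <- Cm[cbind(sa, sb)] + g$activity
  expect_identical(got$final, as.integer(want))
  expect_identical(min(got$final), 1L)
  expect_identical(max(got$final), 15L)
  expect_true(all(got$final >= 1L & got$final <= 15L))
  # composition with risk_level always lands in the published bins
  expect_true(all(risk_level(got$final)$risk %in%
    c("Negligible", "Low", "Medium", "High", "Very high")))
})

test_that("final score is monotone in every scoring input", {
  g <- reba_grid()
  fin <- reba_from_scores(g$trunk, g$neck, g$legs, g$ua, g$la, g$wrist,
                          g$load, g$coupling, g$activity)$final
  dims <- c(trunk = 5L, neck = 3L, legs = 4L, ua = 6L, la = 2L, wrist = 3L,
            load = 4L, coupling = 4L, activity = 4L)
  arr <- array(fin, dim = unname(dims))
  for (d in seq_along(dims)) {
    a <- aperm(arr, c(d, seq_along(dims)[-d]))
    m <- matrix(a, nrow = dims[d])
    expect_true(all(apply(m, 2L, function(col) all(diff(col) >= 0))),
                label = paste("monotone in", names(dims)[d]))
  }
})

test_that("reba_score_sequence scores frames and marks unavailable ones", {
  g <- generate_sequence(data.frame(label = "bend", frames = 50L),
                         noise_px = 0, seed = 3)
  sc <- reba_score_sequence(g$seq)
  expect_identical(nrow(sc), 50L)
  expect_true(all(sc$final >= 1L & sc$final <= 15L))
  # mid-bend: trunk sweeps towards 55 degrees, scores rise
  expect_gt(sc$final[25L], sc$final[1L])
  # blank the trunk keypoints of one frame: that row becomes NA
  seq2 <- g$seq; seq2$arr[10L, 9L, ] <- 0
  sc2 <- reba_score_sequence(seq2)
  expect_true(is.na(sc2$final[10L]))
  expect_false(anyNA(sc2$final[-10L]))
})
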