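# Synthetic articulated 2D motion with ground truth, plus corruption
# injection (missing-keypoint bursts, misidentification events). Poses are
# produced by forward kinematics over fixed bone lengths, so the
# constant-bone-length premise behind the temporal kinematic chain holds by
# construction; pixel noise is added afterwards in image space.

# evaluate code under a seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# bone lengths (pixels) of the canonical synthetic figure
synthetic_bones <- function() {
  c(trunk = 150, neck = 45, eye = 18, ear = 18, shoulder = 40,
    upper_arm = 80, lower_arm = 70, hip = 25, thigh = 110, shank = 105,
    toe = 45, small_toe = 12, heel = 18)
}

# neutral standing pose parameters (degrees)
synthetic_neutral <- function() {
  c(trunk = 5, neck = 5, ua_r = 10, ua_l = 10, elbow_r = 15, elbow_l = 15,
    hip_r = 2, hip_l = -2, knee_r = 5, knee_l = 5)
}

# forward kinematics: pose parameters (degrees) -> 25 x 2 keypoint matrix.
# Image coordinates, y down; the figure faces +x (sagittal view).
synthetic_pose <- function(params, root = c(640, 400),
                           bones = synthetic_bones()) {
  d <- pi / 180
  up <- function(a) c(sin(a), -cos(a))     # a = 0 is vertical up
  down <- function(a) c(sin(a), cos(a))    # a = 0 is vertical down
  p <- matrix(NA_real_, 25L, 2L)
  a_tr <- params[["trunk"]] * d
  a_h <- a_tr + params[["neck"]] * d
  p[9, ] <- root                                       # MidHip (id 8)
  p[2, ] <- p[9, ] + bones[["trunk"]] * up(a_tr)       # Neck (id 1)
  p[1, ] <- p[2, ] + bones[["neck"]] * up(a_h)         # Nose (id 0)
  p[16, ] <- p[1, ] + bones[["eye"]] * up(a_h + 40 * d)   # REye
  p[17, ] <- p[1, ] + bones[["eye"]] * up(a_h - 40 * d)   # LEye
  p[18, ] <- p[16, ] + bones[["ear"]] * up(a_h + 100 * d) # REar
  p[19, ] <- p[17, ] + bones[["ear"]] * up(a_h - 100 * d) # LEar
  perp <- c(cos(a_tr), sin(a_tr))                      # trunk-perpendicular
  p[3, ] <- p[2, ] + bones[["shoulder"]] * perp        # RShoulder
  p[6, ] <- p[2, ] - bones[["shoulder"]] * perp        # LShoulder
  a_uar <- a_tr + params[["ua_r"]] * d
  a_ual <- a_tr + params[["ua_l"]] * d
  p[4, ] <- p[3, ] + bones[["upper_arm"]] * down(a_uar)              # RElbow
  p[5, ] <- p[4, ] + bones[["lower_arm"]] * down(a_uar + params[["elbow_r"]] * d)
  p[7, ] <- p[6, ] + bones[["upper_arm"]] * down(a_ual)              # LElbow
  p[8, ] <- p[7, ] + bones[["lower_arm"]] * down(a_ual + params[["elbow_l"]] * d)
  p[10, ] <- p[9, ] + bones[["hip"]] * c(1, 0)         # RHip
  p[13, ] <- p[9, ] - bones[["hip"]] * c(1, 0)         # LHip
  a_shr <- params[["hip_r"]] * d - params[["knee_r"]] * d
  a_shl <- params[["hip_l"]] * d - params[["knee_l"]] * d
  p[11, ] <- p[10, ] + bones[["thigh"]] * down(params[["hip_r"]] * d)  # RKnee
  p[12, ] <- p[11, ] + bones[["shank"]] * down(a_shr)                  # RAnkle
  p[14, ] <- p[13, ] + bones[["thigh"]] * down(params[["hip_l"]] * d)  # LKnee
  p[15, ] <- p[14, ] + bones[["shank"]] * down(a_shl)                  # LAnkle
  p[23, ] <- p[12, ] + bones[["toe"]] * down(a_shr + 90 * d)       # RBigToe
  p[24, ] <- p[23, ] + bones[["small_toe"]] * down(a_shr + 90 * d) # RSmallToe
  p[25, ] <- p[12, ] + bones[["heel"]] * down(a_shr - 90 * d)      # RHeel
  p[20, ] <- p[15, ] + bones[["toe"]] * down(a_shl + 90 * d)       # LBigToe
  p[21, ] <- p[20, ] + bones[["small_toe"]] * down(a_shl + 90 * d) # LSmallToe
  p[22, ] <- p[15, ] + bones[["heel"]] * down(a_shl - 90 * d)      # LHeel
  p
}

# per-label target poses; each action sweeps smoothly from neutral toward
# the target and back within its script segment
synthetic_actions <- function() {
  n <- synthetic_neutral()
  list(
    stand = n,
    bend  = replace(n, c("trunk", "neck", "knee_r", "knee_l", "ua_r", "ua_l"),
                    c(55, 20, 25, 25, 25, 25)),
    lift  = replace(n, c("ua_r", "ua_l", "elbow_r", "elbow_l", "trunk"),
                    c(85, 85, 70, 70, 20)),
    reach = replace(n, c("ua_r", "elbow_r", "trunk"), c(70, 25, 12)))
}

#' Generate a synthetic skeleton sequence
#'
#' Animates a fixed-bone-length 25-keypoint figure through an action script
#' by forward kinematics. Each script segment sweeps the pose parameters
#' smoothly from the neutral stance toward the action's target posture and
#' back (a raised-cosine profile), so segments join continuously. Gaussian
#' pixel noise is added to every coordinate afterwards. Confidence of every
#' keypoint is 0.9.
#'
#' @param action_script Data frame with columns `label` (one of `"stand"`,
#'   `"bend"`, `"lift"`, `"reach"`) and `frames` (positive segment length).
#' @param fps Frames per second (default 50).
#' @param noise_px Standard deviation of additive coordinate noise in
#'   pixels (default 1.5, a typical detector jitter).
#' @param seed Integer seed; output is bit-identical for equal seeds.
#' @return List with `seq` (a [skeleton_sequence]), `labels` (character
#'   vector of per-frame true action labels) and `truth` (the noise-free
#'   sequence -- what an occlusion-proof reference measurement would see).
#' @export
generate_sequence <- function(action_script, fps = 50, noise_px = 1.5,
                              seed = 1L) {
  stopifnot(is.data.frame(action_script),
            all(c("label", "frames") %in% names(action_script)))
  if (any(action_script$frames <= 0)) stop("segment durations must be positive")
  acts <- synthetic_actions()
  unknown <- setdiff(action_script$label, names(acts))
  if (length(unknown))
    stop("unknown action label(s): ", paste(unknown, collapse = ", "))
  neutral <- synthetic_neutral()
  total <- sum(action_script$frames)
  arr <- array(NA_real_, dim = c(total, 25L, 3L))
  labels <- character(total)
  t0 <- 0L
  for (s in seq_len(nrow(action_script))) {
    lab <- action_script$label[s]
    dur <- action_script$frames[s]
    target <- acts[[lab]]
    for (k in seq_len(dur)) {
      u <- if (dur == 1L) 0.5 else (k - 1) / (dur - 1)
      w <- sin(pi * u)^2                       # 0 at segment ends, 1 mid-way
      params <- neutral + w * (target - neutral)
      arr[t0 + k, , 1:2] <- synthetic_pose(params)
      labels[t0 + k] <- lab
    }
    t0 <- t0 + dur
  }
  arr[, , 3L] <- 0.9
  clean <- arr
  if (noise_px > 0) {
    noise <- local_seed(seed, stats::rnorm(total * 25L * 2L, 0, noise_px))
    arr[, , 1:2] <- arr[, , 1:2] + noise
  }
  list(seq = skeleton_sequence(arr, fps = fps), labels = labels,
       truth = skeleton_sequence(clean, fps = fps))
}

empty_corruption_log <- function() {
  list(records = data.frame(frame = integer(), keypoint = integer(),
                            x_true = numeric(), y_true = numeric(),
                            conf_true = numeric(), kind = character(),
                            link = integer()))
}

#' Inject bursts of missing keypoints
#'
#' Blanks whole joint groups (coordinates (0, 0), confidence 0) in bursts
#' of `burst_len` consecutive frames, independently per group, until the
#' per-group missing-frame rate reaches `target_rate`. Burst placement is
#' drawn from disjoint blocks so the realized rate matches the target to
#' within block-count rounding. Ground truth is retained in the log.
#'
#' @param seq A [skeleton_sequence].
#' @param target_rate Fraction of frames per joint group to blank, in
#'   `[0, 1)`.
#' @param burst_len Burst length in frames (default 5).
#' @param seed Integer seed.
#' @param groups Joint groups to corrupt (default [body25_joint_groups()]).
#' @return List with `seq` (corrupted sequence) and `log` (corruption log;
#'   see [restore_truth()]).
#' @export
inject_missing <- function(seq, target_rate, burst_len = 5L, seed = 1L,
                           groups = body25_joint_groups()) {
  stopifnot(target_rate >= 0, target_rate < 1)
  total <- n_frames(seq)
  if (burst_len > total) stop("burst_len exceeds sequence length")
  log <- empty_corruption_log()
  if (target_rate == 0) return(list(seq = seq, log = log))
  arr <- seq$arr
  recs <- list()
  local_seed(seed, {
    nblocks <- total %/% burst_len
    starts_all <- (seq_len(nblocks) - 1L) * burst_len + 1L
    for (g in seq_along(groups)) {
      npick <- round(target_rate * nblocks)
      if (npick == 0L) next
      starts <- sample(starts_all, npick)
      ids <- groups[[g]]
      for (s in starts) {
        frames <- s:(s + burst_len - 1L)
        for (f in frames) {
          recs[[length(recs) + 1L]] <- data.frame(
            frame = f, keypoint = ids,
            x_true = arr[f, ids + 1L, 1L], y_true = arr[f, ids + 1L, 2L],
            conf_true = arr[f, ids + 1L, 3L],
            kind = "missing", link = NA_integer_)
        }
        arr[frames, ids + 1L, ] <- 0
      }
    }
  })
  if (length(recs)) {
    log$records <- do.call(rbind, recs)
    # a frame may be hit by overlapping group picks; keep first truth record
    log$records <- log$records[!duplicated(log$records[, c("frame", "keypoint")]), ]
  }
  out <- seq
  out$arr <- arr
  list(seq = out, log = log)
}

# limbs eligible for misidentification events: link index into
# body25_topology() order and the keypoints displaced with it
misid_limbs <- function() {
  list(upper_arm_r = list(link = 8L,  moved = c(3L, 4L)),
       lower_arm_r = list(link = 9L,  moved = 4L),
       upper_arm_l = list(link = 11L, moved = c(6L, 7L)),
       lower_arm_l = list(link = 12L, moved = 7L),
       thigh_r     = list(link = 14L, moved = c(10L, 11L, 22L, 23L, 24L)),
       thigh_l     = list(link = 20L, moved = c(13L, 14L, 19L, 20L, 21L)))
}

#' Inject misidentification events
#'
#' Displaces a limb's distal keypoints for `duration` consecutive frames so
#' the implicated bone's length changes by a factor `1 + magnitude`
#' (emulating a keypoint grabbed from an overlapping second person). Both
#' modes also rotate the bone off its true direction -- a pure radial
#' stretch would leave every joint angle untouched, which is not how a
#' wrong-person keypoint behaves: `limb_displace` rotates by 25 degrees,
#' `second_figure_swap` by 60 degrees (a swapped second-figure limb).
#' Rotation preserves the length change, so the temporal-chain diagonal
#' signal stays exactly `(1 + magnitude)^2 - 1` relative. Ground truth is
#' retained in the log.
#'
#' @param seq A [skeleton_sequence].
#' @param event_rate Target fraction of frames affected, in `[0, 1)`.
#' @param mode `"limb_displace"` or `"second_figure_swap"`.
#' @param magnitude Relative bone-length change (> 0, e.g. 0.5 for a 50%
#'   stretch).
#' @param duration Event duration in frames (default 4).
#' @param seed Integer seed.
#' @return List with `seq`, `log`. The log's records carry the implicated
#'   link index (topology order) in column `link`.
#' @export
inject_misidentification <- function(seq, event_rate,
                                     mode = c("limb_displace",
                                              "second_figure_swap"),
                                     magnitude = 0.5, duration = 4L,
                                     seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(event_rate >= 0, event_rate < 1, magnitude > 0, duration >= 1)
  total <- n_frames(seq)
  log <- empty_corruption_log()
  if (event_rate == 0) return(list(seq = seq, log = log))
  topo <- body25_topology()
  limbs <- misid_limbs()
  arr <- seq$arr
  recs <- list()
  local_seed(seed, {
    nblocks <- total %/% duration
    n_events <- round(event_rate * total / duration)
    starts <- (sample(nblocks, min(n_events, nblocks)) - 1L) * duration + 1L
    for (s in starts) {
      limb <- limbs[[sample(length(limbs), 1L)]]
      parent <- topo$links[limb$link, 1L]
      child <- topo$links[limb$link, 2L]
      frames <- s:(s + duration - 1L)
      for (f in frames) {
        moved <- limb$moved
        recs[[length(recs) + 1L]] <- data.frame(
          frame = f, keypoint = moved,
          x_true = arr[f, moved + 1L, 1L], y_true = arr[f, moved + 1L, 2L],
          conf_true = arr[f, moved + 1L, 3L],
          kind = "misid", link = limb$link)
        bone <- arr[f, child + 1L, 1:2] - arr[f, parent + 1L, 1:2]
        th <- (if (mode == "second_figure_swap") 60 else 25) * pi / 180
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
        newbone <- (1 + magnitude) * as.numeric(R %*% bone)
        delta <- newbone - bone
        arr[f, moved + 1L, 1L] <- arr[f, moved + 1L, 1L] + delta[1L]
        arr[f, moved + 1L, 2L] <- arr[f, moved + 1L, 2L] + delta[2L]
      }
    }
  })
  if (length(recs)) {
    log$records <- do.call(rbind, recs)
    log$records <- log$records[!duplicated(log$records[, c("frame", "keypoint")]), ]
  }
  out <- seq
  out$arr <- arr
  list(seq = out, log = log)
}

#' Undo logged corruption
#'
#' Restores the true coordinates recorded in a corruption log, inverting
#' [inject_missing()] / [inject_misidentification()] exactly.
#'
#' @param seq Corrupted [skeleton_sequence].
#' @param log Corruption log (or list of logs, applied in order).
#' @return The restored [skeleton_sequence].
#' @export
restore_truth <- function(seq, log) {
  if (!is.null(log$records)) log <- list(log)
  arr <- seq$arr
  for (lg in log) {
    r <- lg$records
    if (!nrow(r)) next
    idx_x <- cbind(r$frame, r$keypoint + 1L, 1L)
    arr[idx_x] <- r$x_true
    arr[cbind(r$frame, r$keypoint + 1L, 2L)] <- r$y_true
    arr[cbind(r$frame, r$keypoint + 1L, 3L)] <- r$conf_true
  }
  out <- seq
  out$arr <- arr
  out
}
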