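# REBA (Rapid Entire Body Assessment) joint angles and scoring.
#
# Eight joint angles are computed from BODY_25 keypoints. Trunk, neck and
# upper-arm angles are measured against synthetic vertical reference points
# anchored at the proximal joint (trunk/neck against vertical up, upper arm
# against vertical down -- the arm-hanging neutral), so they are flexion
# magnitudes from the neutral stance. Leg and lower-arm angles are flexion
# = 180 degrees minus the interior angle at the middle joint (straight limb
# = 0 flexion). The wrist is scored as a constant (default 1) because it is
# held nearly fixed in the target tasks.

reba_env <- new.env(parent = emptyenv())

# scoring tables are shipped as CSV data files; sums guard against edits
reba_tables <- function() {
  if (!is.null(reba_env$tables)) return(reba_env$tables)
  dir <- system.file("extdata", "reba", package = "skelrepair")
  ga <- utils::read.csv(file.path(dir, "table_a.csv"))
  gb <- utils::read.csv(file.path(dir, "table_b.csv"))
  gc_ <- utils::read.csv(file.path(dir, "table_c.csv"))
  A <- array(0L, c(5L, 3L, 4L))
  A[cbind(ga$trunk, ga$neck, ga$legs)] <- ga$score
  B <- array(0L, c(6L, 2L, 3L))
  B[cbind(gb$upper_arm, gb$lower_arm, gb$wrist)] <- gb$score
  C <- matrix(0L, 12L, 12L)
  C[cbind(gc_$score_a, gc_$score_b)] <- gc_$score
  if (sum(A) != 321L || sum(B) != 177L || sum(C) != 1192L)
    stop("REBA table checksum mismatch; data files corrupted")
  reba_env$tables <- list(A = A, B = B, C = C)
  reba_env$tables
}

# unsigned angle (degrees) between 2D vectors; NA on degenerate input
angle_between <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (!is.finite(n1) || !is.finite(n2) || n1 < 1e-9 || n2 < 1e-9)
    return(NA_real_)
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Eight REBA joint angles from a skeleton frame
#'
#' Trunk (angle of MidHip-to-Neck from vertical up), neck (Neck-to-Nose
#' from trunk-independent vertical up), left/right leg flexion (knee
#' interior-angle complement), left/right upper-arm flexion (shoulder-to-
#' elbow from vertical down) and left/right lower-arm flexion (elbow
#' interior-angle complement). Angles whose keypoints are absent or
#' degenerate are `NA` (the "unavailable" marker).
#'
#' @param frame A [skeleton_frame].
#' @param conf_min Keypoint absence threshold.
#' @return Named numeric vector of 8 angles in degrees, each in `[0, 180]`:
#'   `trunk`, `neck`, `leg_l`, `leg_r`, `upper_arm_l`, `upper_arm_r`,
#'   `lower_arm_l`, `lower_arm_r`.
#' @export
joint_angles <- function(frame, conf_min = 0.1) {
  absent <- absent_keypoints(frame, conf_min)
  xy <- unclass(frame)[, 1:2, drop = FALSE]
  pt <- function(id) xy[id + 1L, ]
  ok <- function(...) !any(absent[c(...) + 1L])
  up <- c(0, -1); down <- c(0, 1)   # image coordinates, y grows downward
  flex <- function(a, b, c) {       # 180 - interior angle at b
    ang <- angle_between(pt(a) - pt(b), pt(c) - pt(b))
    if (is.na(ang)) NA_real_ else 180 - ang
  }
  c(trunk = if (ok(1, 8)) angle_between(pt(1) - pt(8), up) else NA_real_,
    neck = if (ok(0, 1)) angle_between(pt(0) - pt(1), up) else NA_real_,
    leg_l = if (ok(12, 13, 14)) flex(12, 13, 14) else NA_real_,
    leg_r = if (ok(9, 10, 11)) flex(9, 10, 11) else NA_real_,
    upper_arm_l = if (ok(5, 6)) angle_between(pt(6) - pt(5), down) else NA_real_,
    upper_arm_r = if (ok(2, 3)) angle_between(pt(3) - pt(2), down) else NA_real_,
    lower_arm_l = if (ok(5, 6, 7)) flex(5, 6, 7) else NA_real_,
    lower_arm_r = if (ok(2, 3, 4)) flex(2, 3, 4) else NA_real_)
}

#' Joint angles for every frame of a sequence
#' @param seq A [skeleton_sequence].
#' @param conf_min Keypoint absence threshold.
#' @return Numeric T x 8 matrix (degrees, `NA` = unavailable).
#' @export
joint_angles_sequence <- function(seq, conf_min = 0.1) {
  T_ <- n_frames(seq)
  out <- matrix(NA_real_, T_, 8L)
  for (t in seq_len(T_)) out[t, ] <- joint_angles(get_frame(seq, t), conf_min)
  colnames(out) <- c("trunk", "neck", "leg_l", "leg_r", "upper_arm_l",
                     "upper_arm_r", "lower_arm_l", "lower_arm_r")
  out
}

#' REBA modifier configuration
#'
#' Defaults are the neutral assessment: no load, good coupling, all
#' rotation/adjustment and activity flags off, wrist score 1 (wrist held
#' constant). Rotation and extra-point interventions are manual inputs, not
#' inferred from 2D keypoints.
#'
#' @param load_kg External load in kilograms (binned at 5 and 10 kg).
#' @param shock TRUE if there is shock or rapid build-up of force (+1 load).
#' @param coupling Hand coupling: `"good"`, `"fair"`, `"poor"`,
#'   `"unacceptable"`.
#' @param static,repeated,rapid_change Activity flags (+1 each).
#' @param trunk_twist,neck_twist Twist or side-bend flags (+1 each).
#' @param shoulder_raised,arm_abducted,arm_supported Upper-arm adjustments
#'   (+1, +1, -1).
#' @param leg_raised TRUE for unilateral/unstable weight bearing (base leg
#'   score 2).
#' @param wrist_score Constant wrist score in 1..3.
#' @return A `reba_config` list.
#' @export
reba_config <- function(load_kg = 0, shock = FALSE,
                        coupling = c("good", "fair", "poor", "unacceptable"),
                        static = FALSE, repeated = FALSE,
                        rapid_change = FALSE, trunk_twist = FALSE,
                        neck_twist = FALSE, shoulder_raised = FALSE,
                        arm_abducted = FALSE, arm_supported = FALSE,
                        leg_raised = FALSE, wrist_score = 1L) {
  coupling <- match.arg(coupling)
  if (!wrist_score %in% 1:3) stop("wrist_score must be in 1..3")
  structure(list(load_kg = load_kg, shock = isTRUE(shock),
                 coupling = coupling, static = isTRUE(static),
                 repeated = isTRUE(repeated),
                 rapid_change = isTRUE(rapid_change),
                 trunk_twist = isTRUE(trunk_twist),
                 neck_twist = isTRUE(neck_twist),
                 shoulder_raised = isTRUE(shoulder_raised),
                 arm_abducted = isTRUE(arm_abducted),
                 arm_supported = isTRUE(arm_supported),
                 leg_raised = isTRUE(leg_raised),
                 wrist_score = as.integer(wrist_score)),
            class = "reba_config")
}

# angle-bin functions (flexion magnitudes; 2D gives no extension sign)
trunk_bin <- function(a) if (a <= 5) 1L else if (a <= 20) 2L else if (a <= 60) 3L else 4L
neck_bin <- function(a) if (a <= 20) 1L else 2L
upper_arm_bin <- function(a) if (a <= 20) 1L else if (a <= 45) 2L else if (a <= 90) 3L else 4L
lower_arm_bin <- function(a) if (a >= 60 && a <= 100) 1L else 2L
knee_increment <- function(a) if (a < 30) 0L else if (a <= 60) 1L else 2L

#' Combine REBA per-joint scores through the scoring tables
#'
#' The table walk shared by [reba_score()] and exhaustive enumeration:
#' Score A = Table A(trunk, neck, legs) + load score, Score B =
#' Table B(upper arm, lower arm, wrist) + coupling score, Score C =
#' Table C(A, B), final = C + activity score. All arguments are vectorized.
#'
#' @param trunk,neck,legs,upper_arm,lower_arm,wrist Per-joint scores
#'   (trunk 1-5, neck 1-3, legs 1-4, upper arm 1-6, lower arm 1-2,
#'   wrist 1-3).
#' @param load_score Load/force score 0-3.
#' @param coupling_score Coupling score 0-3.
#' @param activity_score Activity score 0-3.
#' @return Data frame with columns `score_a`, `score_b`, `score_c`,
#'   `final`.
#' @export
reba_from_scores <- function(trunk, neck, legs, upper_arm, lower_arm,
                             wrist, load_score = 0L, coupling_score = 0L,
                             activity_score = 0L) {
  tb <- reba_tables()
  n <- max(lengths(list(trunk, neck, legs, upper_arm, lower_arm, wrist,
                        load_score, coupling_score, activity_score)))
  r <- function(x) rep_len(as.integer(x), n)
  trunk <- r(trunk); neck <- r(neck); legs <- r(legs)
  upper_arm <- r(upper_arm); lower_arm <- r(lower_arm); wrist <- r(wrist)
  load_score <- r(load_score); coupling_score <- r(coupling_score)
  activity_score <- r(activity_score)
  stopifnot(all(trunk %in% 1:5), all(neck %in% 1:3), all(legs %in% 1:4),
            all(upper_arm %in% 1:6), all(lower_arm %in% 1:2),
            all(wrist %in% 1:3), all(load_score %in% 0:3),
            all(coupling_score %in% 0:3), all(activity_score %in% 0:3))
  score_a <- pmin(tb$A[cbind(trunk, neck, legs)] + load_score, 12L)
  score_b <- pmin(tb$B[cbind(upper_arm, lower_arm, wrist)] + coupling_score,
                  12L)
  score_c <- tb$C[cbind(score_a, score_b)]
  data.frame(score_a = score_a, score_b = score_b, score_c = score_c,
             final = score_c + activity_score)
}

#' REBA score from joint angles
#'
#' Bins the eight angles, applies the configured modifiers, and walks the
#' REBA scoring tables. Arms are scored per side and the worse side's
#' Score B is used; per-side scores are returned for per-joint reporting.
#'
#' @param angles Named vector from [joint_angles()].
#' @param config A [reba_config()].
#' @return A `reba_result` list: `angles`, `scores` (per joint, incl. both
#'   arm sides), `score_a`, `score_b`, `score_c`, `final_score`,
#'   `risk_level`, `suggestion`.
#' @export
reba_score <- function(angles, config = reba_config()) {
  need <- c("trunk", "neck")
  legs_av <- !is.na(angles[c("leg_l", "leg_r")])
  arm_l <- !any(is.na(angles[c("upper_arm_l", "lower_arm_l")]))
  arm_r <- !any(is.na(angles[c("upper_arm_r", "lower_arm_r")]))
  bad <- c(need[is.na(angles[need])],
           if (!any(legs_av)) "legs", if (!arm_l && !arm_r) "arms")
  if (length(bad))
    stop("angle(s) unavailable: ", paste(bad, collapse = ", "))
  trunk_s <- min(trunk_bin(angles[["trunk"]]) + config$trunk_twist, 5L)
  neck_s <- min(neck_bin(angles[["neck"]]) + config$neck_twist, 3L)
  knee <- max(angles[c("leg_l", "leg_r")], na.rm = TRUE)
  legs_s <- min(1L + config$leg_raised + knee_increment(knee), 4L)
  arm_side <- function(ua, la) {
    if (is.na(ua) || is.na(la)) return(NULL)
    ua_s <- max(1L, min(upper_arm_bin(ua) + config$shoulder_raised +
                          config$arm_abducted - config$arm_supported, 6L))
    la_s <- lower_arm_bin(la)
    list(ua = ua_s, la = la_s,
         b = reba_tables()$B[ua_s, la_s, config$wrist_score])
  }
  left <- arm_side(angles[["upper_arm_l"]], angles[["lower_arm_l"]])
  right <- arm_side(angles[["upper_arm_r"]], angles[["lower_arm_r"]])
  worse <- if (is.null(left)) right
           else if (is.null(right)) left
           else if (right$b >= left$b) right else left
  load_score <- (if (config$load_kg > 10) 2L
                 else if (config$load_kg >= 5) 1L else 0L) + config$shock
  coupling_score <- match(config$coupling,
                          c("good", "fair", "poor", "unacceptable")) - 1L
  activity <- config$static + config$repeated + config$rapid_change
  res <- reba_from_scores(trunk_s, neck_s, legs_s, worse$ua, worse$la,
                          config$wrist_score, load_score, coupling_score,
                          activity)
  rl <- risk_level(res$final)
  structure(list(
    angles = angles,
    scores = list(trunk = trunk_s, neck = neck_s, legs = legs_s,
                  upper_arm_l = if (is.null(left)) NA_integer_ else left$ua,
                  upper_arm_r = if (is.null(right)) NA_integer_ else right$ua,
                  lower_arm_l = if (is.null(left)) NA_integer_ else left$la,
                  lower_arm_r = if (is.null(right)) NA_integer_ else right$la,
                  wrist = config$wrist_score),
    score_a = res$score_a, score_b = res$score_b, score_c = res$score_c,
    final_score = res$final, risk_level = rl$risk,
    suggestion = rl$suggestion), class = "reba_result")
}

#' @export
print.reba_result <- function(x, ...) {
  cat("<reba_result> final", x$final_score, "-", x$risk_level,
      paste0("(", x$suggestion, ")"), "\n")
  invisible(x)
}

#' REBA risk level for a final score
#'
#' Maps final REBA scores to the published action-level bins:
#' 1 Negligible, 2-3 Low, 4-7 Medium, 8-10 High, 11-15 Very high.
#'
#' @param score Integer final score(s) in 1..15.
#' @return Data frame with columns `score`, `action_level`, `risk`,
#'   `suggestion`.
#' @export
risk_level <- function(score) {
  if (any(is.na(score)) || any(score < 1 | score > 15))
    stop("REBA final score must lie in [1, 15]")
  lev <- findInterval(score, c(1, 2, 4, 8, 11))
  data.frame(
    score = score,
    action_level = lev - 1L,
    risk = c("Negligible", "Low", "Medium", "High", "Very high")[lev],
    suggestion = c("None necessary", "Maybe necessary", "Necessary",
                   "Necessary soon", "Necessary now")[lev])
}

#' Score every frame of a sequence
#'
#' Frames whose required angles are unavailable get `NA` scores.
#'
#' @param seq A [skeleton_sequence].
#' @param config A [reba_config()].
#' @param conf_min Keypoint absence threshold.
#' @return Data frame, one row per frame: frame index, the 8 angles,
#'   per-joint scores, A/B/C, final score and risk level.
#' @export
reba_score_sequence <- function(seq, config = reba_config(),
                                conf_min = 0.1) {
  ang <- joint_angles_sequence(seq, conf_min)
  T_ <- nrow(ang)
  out <- data.frame(frame = seq$frame_index, ang,
                    trunk_s = NA_integer_, neck_s = NA_integer_,
                    legs_s = NA_integer_, upper_arm_s = NA_integer_,
                    lower_arm_s = NA_integer_, wrist_s = NA_integer_,
                    score_a = NA_integer_, score_b = NA_integer_,
                    score_c = NA_integer_, final = NA_integer_,
                    risk = NA_character_)
  for (t in seq_len(T_)) {
    r <- tryCatch(reba_score(ang[t, ], config), error = function(e) NULL)
    if (is.null(r)) next
    ua <- max(r$scores$upper_arm_l, r$scores$upper_arm_r, na.rm = TRUE)
    la <- max(r$scores$lower_arm_l, r$scores$lower_arm_r, na.rm = TRUE)
    out[t, c("trunk_s", "neck_s", "legs_s", "upper_arm_s", "lower_arm_s",
             "wrist_s", "score_a", "score_b", "score_c", "final")] <-
      c(r$scores$trunk, r$scores$neck, r$scores$legs, ua, la,
        r$scores$wrist, r$score_a, r$score_b, r$score_c, r$final_score)
    out$risk[t] <- r$risk_level
  }
  out
}
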