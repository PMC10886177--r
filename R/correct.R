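# Misidentification correction: frames flagged misidentified are rewritten
# to the window's dominant action, the keypoints implicated by the
# bone-length anomaly are re-synthesized by interpolation between the
# nearest clean frames of the dominant action, and keypoint trajectories
# are Kalman-smoothed afterwards.

#' Kalman filter parameters
#'
#' Scalar constant-state model per coordinate: `A = C = 1`, `B = 0` by
#' default (adjacent time steps share the same characteristics, control
#' input unused). `Q` and `R` are process and measurement noise
#' covariances in squared pixels.
#'
#' @param A,B,C State transition, control input, and observation scalars.
#' @param Q Process noise covariance (>= 0), default 1e-3.
#' @param R Measurement noise covariance (> 0), default 1e-2.
#' @param x0 Initial state; `NULL` (default) uses the first measurement.
#' @param P0 Initial covariance (>= 0), default 1.
#' @return A `kalman_params` list.
#' @export
kalman_params <- function(A = 1, B = 0, C = 1, Q = 1e-3, R = 1e-2,
                          x0 = NULL, P0 = 1) {
  if (Q < 0) stop("Q must be non-negative")
  if (R <= 0) stop("R must be positive")
  if (P0 < 0) stop("P0 must be non-negative")
  structure(list(A = A, B = B, C = C, Q = Q, R = R, x0 = x0, P0 = P0),
            class = "kalman_params")
}

#' Kalman-smooth a scalar time series
#'
#' Runs the standard predict/update recursion (prior state
#' `x- = A x + B u`, prior covariance `P- = A P A + Q`, gain
#' `K = P- C / (C P- C + R)`, posterior `x = x- + K (y - C x-)`,
#' `P = (1 - K C) P-`) and returns the posterior estimates.
#'
#' @param series Numeric measurements, nonempty, no `NA`.
#' @param params A [kalman_params()].
#' @param u Control input (scalar or per-step vector), default 0.
#' @return Numeric vector of posterior state estimates, same length.
#' @export
kalman_smooth <- function(series, params = kalman_params(), u = 0) {
  n <- length(series)
  if (n == 0L) stop("series must be nonempty")
  if (anyNA(series)) stop("series must not contain NA")
  if (params$R <= 0) stop("R must be positive")
  u <- rep_len(u, n)
  A <- params$A; B <- params$B; C <- params$C
  x <- if (is.null(params$x0)) series[1L] else params$x0
  P <- params$P0
  out <- numeric(n)
  for (k in seq_len(n)) {
    xp <- A * x + B * u[k]
    Pp <- A * P * A + params$Q
    K <- Pp * C / (C * Pp * C + params$R)
    x <- xp + K * (series[k] - C * xp)
    P <- (1 - K * C) * Pp
    out[k] <- x
  }
  out
}

#' Kalman-smooth all keypoint trajectories of a sequence
#'
#' Each keypoint's x and y series is smoothed independently. Absent
#' keypoints are skipped: the filter runs over the observed subsequence
#' only and absent frames are left untouched.
#'
#' @param seq A [skeleton_sequence].
#' @param params A [kalman_params()].
#' @param conf_min Keypoint absence threshold.
#' @return The smoothed [skeleton_sequence].
#' @export
smooth_sequence <- function(seq, params = kalman_params(), conf_min = 0.1) {
  arr <- seq$arr
  T_ <- n_frames(seq)
  absent <- (arr[, , 3L] < conf_min) | (arr[, , 1L] == 0 & arr[, , 2L] == 0)
  if (is.null(dim(absent))) absent <- matrix(absent, nrow = T_)
  for (k in seq_len(25L)) {
    obs <- which(!absent[, k])
    if (length(obs) < 2L) next
    arr[obs, k, 1L] <- kalman_smooth(arr[obs, k, 1L], params)
    arr[obs, k, 2L] <- kalman_smooth(arr[obs, k, 2L], params)
  }
  out <- seq
  out$arr <- arr
  out
}

# anchors for correction: nearest complete frames of the dominant action
.dominant_anchor <- function(side, t, ok, span) {
  idx <- if (side == "before") rev(seq(max(1L, t - span), t - 1L))
         else seq(t + 1L, min(length(ok), t + span))
  if (t == 1L && side == "before") return(NA_integer_)
  if (t >= length(ok) && side == "after") return(NA_integer_)
  hit <- idx[ok[idx]]
  if (length(hit)) hit[1L] else NA_integer_
}

#' Correct one misidentified frame
#'
#' Replaces the frame's action label with the window's dominant label and
#' re-synthesizes the keypoints implicated by the bone-length anomaly (the
#' flagged links' distal subtrees) by linear interpolation between the
#' nearest complete frames of the dominant action inside the window. When
#' no dominant action exists (proportion <= the dominance threshold) or no
#' same-label anchors are found, the frame is left as-is and flagged
#' uncorrectable.
#'
#' @param seq A [skeleton_sequence].
#' @param t Frame position (1-based), classified misidentified.
#' @param reports Integrity report from [classify_sequence()].
#' @param weights [action_weights] for the sequence.
#' @param span Window half-width (default 10 frames).
#' @param dominance Dominance threshold (default 0.6).
#' @param conf_sentinel Confidence for re-synthesized keypoints.
#' @param topology Skeleton topology.
#' @return List: `frame` (corrected [skeleton_frame]), `corrected`
#'   (logical), `label` (dominant label or `NA`), `keypoints` (ids
#'   re-synthesized).
#' @export
correct_frame <- function(seq, t, reports, weights, span = 10L,
                          dominance = 0.6, conf_sentinel = 0.5,
                          topology = body25_topology()) {
  T_ <- n_frames(seq)
  win <- max(1L, t - span):min(T_, t + span)
  labs <- argmax_labels(weights)
  het <- action_heterogeneity(weights[win, , drop = FALSE], labs[t],
                              dominance)
  fr <- get_frame(seq, t)
  if (is.na(het$dominant))
    return(list(frame = fr, corrected = FALSE, label = NA_character_,
                keypoints = integer()))
  ok <- labs == het$dominant & reports$status == "complete"
  s <- .dominant_anchor("before", t, ok, span)
  e <- .dominant_anchor("after", t, ok, span)
  if (is.na(s) || is.na(e))
    return(list(frame = fr, corrected = FALSE, label = het$dominant,
                keypoints = integer()))
  link_str <- reports$implicated_links[t]
  kps <- integer()
  if (nzchar(link_str)) {
    links <- as.integer(strsplit(link_str, ",")[[1L]])
    subtrees <- link_subtrees(topology)
    kps <- sort(unique(unlist(subtrees[links])))
  }
  kp <- unclass(fr)
  for (k in kps) {
    w <- (t - s) / (e - s)
    kp[k + 1L, 1:2] <- (1 - w) * seq$arr[s, k + 1L, 1:2] +
      w * seq$arr[e, k + 1L, 1:2]
    kp[k + 1L, 3L] <- conf_sentinel
  }
  list(frame = skeleton_frame(kp, frame_index = attr(fr, "frame_index")),
       corrected = TRUE, label = het$dominant, keypoints = kps)
}

#' Correct all misidentified frames and smooth trajectories
#'
#' Applies [correct_frame()] to every frame the report flags as
#' misidentified, rewrites the corrected frames' action weights to the
#' dominant label (one-hot), optionally Kalman-smooths all trajectories,
#' and re-discriminates to measure the post-correction misidentification
#' rate.
#'
#' @param seq A [skeleton_sequence].
#' @param reports Integrity report from [classify_sequence()].
#' @param weights [action_weights] for the sequence.
#' @param span,dominance,conf_min,tau,persistence,policy,len_floor_px
#'   Discrimination / correction parameters (see [classify_sequence()]).
#' @param kalman A [kalman_params()] for smoothing.
#' @param smooth Apply Kalman smoothing after correction (default TRUE).
#' @return List: `seq`, `weights` (updated), `reports` (post-correction
#'   re-discrimination), `misid_rate_before`, `misid_rate_after` (percent),
#'   `uncorrectable` (frame positions left unchanged).
#' @export
correct_sequence <- function(seq, reports, weights, span = 10L,
                             dominance = 0.6, conf_min = 0.1, tau = 0.2,
                             persistence = 2L, policy = "any",
                             len_floor_px = 50,
                             kalman = kalman_params(), smooth = TRUE) {
  T_ <- n_frames(seq)
  bad <- which(reports$status == "misidentified")
  out <- seq
  w <- unclass(weights)
  uncorrectable <- integer()
  for (t in bad) {
    res <- correct_frame(seq, t, reports, weights, span, dominance)
    if (!res$corrected) { uncorrectable <- c(uncorrectable, t); next }
    out$arr[t, , ] <- unclass(res$frame)
    w[t, ] <- 0
    w[t, res$label] <- 1
  }
  weights2 <- action_weights(w, frame_index = attr(weights, "frame_index"))
  if (smooth) out <- smooth_sequence(out, kalman, conf_min)
  reports2 <- classify_sequence(out, weights2, conf_min = conf_min,
                                tau = tau, persistence = persistence,
                                span = span, dominance = dominance,
                                policy = policy,
                                len_floor_px = len_floor_px)
  list(seq = out, weights = weights2, reports = reports2,
       misid_rate_before = 100 * length(bad) / T_,
       misid_rate_after =
         100 * mean(reports2$status == "misidentified"),
       uncorrectable = uncorrectable)
}
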