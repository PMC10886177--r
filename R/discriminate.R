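# Frame-integrity discrimination. Each frame is classified as complete,
# missing, or misidentified by combining (i) keypoint presence, (ii)
# diagonal anomalies of the temporal kinematic chain (squared-bone-length
# changes against the last trusted frame) and (iii) heterogeneity of the
# per-frame action weights within a sliding window. The learned
# discriminator this stands in for is plug-compatible: anything that can
# produce the same report columns may replace classify_sequence().

#' Detect absent keypoints in a frame
#'
#' @param frame A [skeleton_frame].
#' @param conf_min Absence threshold: confidence below it, or coordinates
#'   exactly (0, 0), marks a keypoint absent.
#' @return Integer vector of absent keypoint ids (possibly empty).
#' @export
detect_missing <- function(frame, conf_min = 0.1) {
  which(absent_keypoints(frame, conf_min)) - 1L
}

#' Bone-length anomaly between two frames
#'
#' Computes the temporal kinematic chain between frames `t` and `t + i` and
#' reports the largest relative squared-bone-length change,
#' `max_j |Phi_jj| / max(Psi_jj(t), floor^2)`. The length floor keeps short,
#' noise-dominated bones (the facial links) from dominating the ratio.
#'
#' @param seq A [skeleton_sequence].
#' @param t Frame position (1-based).
#' @param i Temporal interval in frames (default 1).
#' @param tau Relative threshold above which the anomaly flag raises
#'   (default 0.2).
#' @param conf_min Keypoint absence threshold.
#' @param len_floor_px Reference-length floor in pixels (default 50).
#' @param topology Skeleton topology.
#' @return List: `evaluable` (FALSE when either frame has absent keypoints,
#'   the "route to compensation first" signal), `flag`, `magnitude`, and
#'   `links` (indices of links whose relative change exceeds `tau`).
#' @export
phi_anomaly <- function(seq, t, i = 1L, tau = 0.2, conf_min = 0.1,
                        len_floor_px = 50, topology = body25_topology()) {
  t2 <- t + i
  if (t < 1L || t2 > n_frames(seq)) stop("frame positions out of range")
  f1 <- get_frame(seq, t)
  f2 <- get_frame(seq, t2)
  if (any(absent_keypoints(f1, conf_min)) || any(absent_keypoints(f2, conf_min)))
    return(list(evaluable = FALSE, flag = NA, magnitude = NA_real_,
                links = integer()))
  K1 <- build_link_matrix(f1, topology, conf_min)
  K2 <- build_link_matrix(f2, topology, conf_min)
  phi <- temporal_chain(K1, K2, interval = i)
  rel <- abs(diag(phi)) / pmax(diag(gram(K1)), len_floor_px^2)
  list(evaluable = TRUE, flag = max(rel) > tau, magnitude = max(rel),
       links = which(rel > tau))
}

#' Dominance and heterogeneity of action weights in a window
#'
#' The dominant action of a window is the modal argmax label when its share
#' strictly exceeds the dominance threshold; a frame is heterogeneous when
#' a dominant action exists and the frame's own label differs from it.
#'
#' @param weights_window [action_weights] rows (or any weight matrix with
#'   labelled columns) covering the window.
#' @param center_label The label of the frame under scrutiny.
#' @param dominance Strict dominance threshold (default 0.6).
#' @return List: `heterogeneous`, `dominant` (label or `NA`), `proportion`.
#' @export
action_heterogeneity <- function(weights_window, center_label,
                                 dominance = 0.6) {
  if (is.null(dim(weights_window)) || nrow(weights_window) == 0L)
    stop("window must be nonempty")
  labs <- colnames(weights_window)[max.col(unclass(weights_window),
                                           ties.method = "first")]
  counts <- table(labs)
  prop <- max(counts) / length(labs)
  dominant <- if (prop > dominance) names(counts)[which.max(counts)]
              else NA_character_
  list(heterogeneous = !is.na(dominant) && center_label != dominant,
       dominant = dominant, proportion = as.numeric(prop))
}

# integer-label heterogeneity scan over all frames (window +/- span)
heterogeneity_scan <- function(labels_int, n_labels, span, dominance) {
  T_ <- length(labels_int)
  dominant <- integer(T_); prop <- numeric(T_); het <- logical(T_)
  for (t in seq_len(T_)) {
    w <- labels_int[max(1L, t - span):min(T_, t + span)]
    counts <- tabulate(w, n_labels)
    prop[t] <- max(counts) / length(w)
    dominant[t] <- if (prop[t] > dominance) which.max(counts) else NA_integer_
    het[t] <- !is.na(dominant[t]) && labels_int[t] != dominant[t]
  }
  list(dominant = dominant, proportion = prop, heterogeneous = het)
}

#' Classify every frame as complete, missing, or misidentified
#'
#' Missing takes precedence (any absent keypoint). Among non-missing
#' frames, each frame's squared bone lengths are compared against the
#' per-link median profile over the sequence -- the trusted reference under
#' the constant-bone-length premise, robust up to ~50% corrupted frames.
#' Bone-length anomalies must persist for `persistence` consecutive frames
#' to count (single-frame jitter is ignored). A frame is misidentified when the persistent bone anomaly
#' and/or action-weight heterogeneity fires, per `policy`.
#'
#' @param seq A [skeleton_sequence].
#' @param weights Optional [action_weights] (one row per frame); `NULL`
#'   disables the heterogeneity channel.
#' @param conf_min Keypoint absence threshold (default 0.1).
#' @param tau Bone-anomaly threshold (default 0.2).
#' @param persistence Consecutive anomalous frames required (default 2).
#' @param span Heterogeneity window half-width in frames (default 10).
#' @param dominance Dominance threshold (default 0.6, strict).
#' @param policy `"any"` (default): anomaly OR heterogeneity flags
#'   misidentification; `"both"`: require both channels.
#' @param len_floor_px Bone-length floor for the anomaly ratio.
#' @param topology Skeleton topology.
#' @return Integrity report: a data frame with one row per frame and
#'   columns `frame`, `status`, `missing_ids` (comma-separated),
#'   `n_missing`, `phi_eval`, `phi_flag`, `phi_mag`, `implicated_links`
#'   (comma-separated link indices), `heterogeneous`, `dominant`,
#'   `center_label`, `dominant_prop`.
#' @export
classify_sequence <- function(seq, weights = NULL, conf_min = 0.1,
                              tau = 0.2, persistence = 2L, span = 10L,
                              dominance = 0.6, policy = c("any", "both"),
                              len_floor_px = 50,
                              topology = body25_topology()) {
  policy <- match.arg(policy)
  T_ <- n_frames(seq)
  arr <- seq$arr
  absent <- (arr[, , 3L] < conf_min) |
    (arr[, , 1L] == 0 & arr[, , 2L] == 0)      # T x 25
  if (is.null(dim(absent))) absent <- matrix(absent, nrow = T_)
  n_missing <- rowSums(absent)
  missing_ids <- apply(absent, 1L, function(a)
    paste(which(a) - 1L, collapse = ","))

  # bone anomaly against the last trusted frame
  links <- topology$links
  phi_eval <- n_missing == 0L
  phi_flag <- rep(FALSE, T_)
  phi_mag <- rep(NA_real_, T_)
  implicated <- character(T_)
  xs <- arr[, , 1L, drop = TRUE]; ys <- arr[, , 2L, drop = TRUE]
  if (T_ == 1L) { xs <- matrix(xs, 1L); ys <- matrix(ys, 1L) }
  bx <- xs[, links[, 2L] + 1L, drop = FALSE] - xs[, links[, 1L] + 1L, drop = FALSE]
  by <- ys[, links[, 2L] + 1L, drop = FALSE] - ys[, links[, 1L] + 1L, drop = FALSE]
  len2 <- bx^2 + by^2                          # T x L squared bone lengths
  # Reference profile: bone lengths are constant under the kinematic-chain
  # premise, so the per-link median over evaluable frames is the trusted
  # squared-length profile. Comparing every frame against it (rather than
  # chaining frame to frame) keeps a single noise-outlier frame from
  # poisoning the reference and flags whole corruption events, not just
  # their onsets.
  if (any(phi_eval)) {
    med <- apply(len2[phi_eval, , drop = FALSE], 2L, stats::median)
    floor2 <- pmax(med, len_floor_px^2)
    rel <- abs(sweep(len2, 2L, med)) / rep(floor2, each = T_)
    for (t in which(phi_eval)) {
      phi_mag[t] <- max(rel[t, ])
      if (phi_mag[t] > tau) {
        phi_flag[t] <- TRUE
        implicated[t] <- paste(which(rel[t, ] > tau), collapse = ",")
      }
    }
  }
  # persistence: keep anomaly runs of >= `persistence` consecutive frames
  if (persistence > 1L) {
    r <- rle(phi_flag)
    r$values[r$values & r$lengths < persistence] <- FALSE
    phi_keep <- inverse.rle(r)
  } else phi_keep <- phi_flag

  # heterogeneity channel
  het <- rep(FALSE, T_); dominant <- rep(NA_character_, T_)
  prop <- rep(NA_real_, T_); center <- rep(NA_character_, T_)
  if (!is.null(weights)) {
    labs <- argmax_labels(weights)
    li <- match(labs, colnames(weights))
    hs <- heterogeneity_scan(li, ncol(weights), span, dominance)
    het <- hs$heterogeneous
    dominant <- colnames(weights)[hs$dominant]
    prop <- hs$proportion
    center <- labs
  }

  status <- rep("complete", T_)
  misid <- if (policy == "any") (phi_keep | het) else (phi_keep & het)
  status[misid] <- "misidentified"
  status[n_missing > 0L] <- "missing"
  data.frame(frame = seq$frame_index, status = status,
             missing_ids = missing_ids, n_missing = n_missing,
             phi_eval = phi_eval, phi_flag = phi_keep, phi_mag = phi_mag,
             implicated_links = implicated, heterogeneous = het,
             dominant = dominant, center_label = center,
             dominant_prop = prop, stringsAsFactors = FALSE)
}

#' Classify a single frame
#'
#' Convenience wrapper extracting one row of [classify_sequence()].
#'
#' @param seq A [skeleton_sequence].
#' @param t Frame position (1-based).
#' @param weights Optional [action_weights].
#' @param ... Passed to [classify_sequence()].
#' @return One-row integrity report (see [classify_sequence()]).
#' @export
classify_frame <- function(seq, t, weights = NULL, ...) {
  reports <- classify_sequence(seq, weights, ...)
  reports[t, , drop = FALSE]
}
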