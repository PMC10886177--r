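#' Construct a skeleton frame
#'
#' One time step of a 2D pose: 25 keypoints, each (x, y, confidence) in
#' image-pixel coordinates (y grows downward). A keypoint is "absent" when
#' its confidence falls below the absence threshold or its coordinates are
#' exactly (0, 0) -- the convention OpenPose uses for undetected points.
#'
#' @param keypoints Numeric 25 x 3 matrix, columns x, y, confidence.
#' @param frame_index Non-negative integer frame index (0-based).
#' @return A `skeleton_frame`: the keypoint matrix with an index attribute.
#' @export
skeleton_frame <- function(keypoints, frame_index = 0L) {
  keypoints <- as.matrix(keypoints)
  if (!is.numeric(keypoints) || ncol(keypoints) != 3L)
    stop("keypoints must be a numeric matrix with columns x, y, confidence")
  if (nrow(keypoints) != 25L)
    stop("a BODY_25 frame has exactly 25 keypoint slots, got ", nrow(keypoints))
  if (any(keypoints[, 3L] < 0 | keypoints[, 3L] > 1))
    stop("confidence must lie in [0, 1]")
  if (frame_index < 0) stop("frame_index must be non-negative")
  colnames(keypoints) <- c("x", "y", "confidence")
  structure(keypoints, frame_index = as.integer(frame_index),
            class = c("skeleton_frame", "matrix", "array"))
}

#' @export
print.skeleton_frame <- function(x, ...) {
  cat("<skeleton_frame> index", attr(x, "frame_index"),
      "-", sum(!absent_keypoints(x)), "of 25 keypoints present\n")
  invisible(x)
}

#' Which keypoints of a frame are absent?
#'
#' @param frame A `skeleton_frame` (or any 25 x 3 keypoint matrix).
#' @param conf_min Absence threshold on confidence (default 0.1).
#' @return Logical vector of length 25; position `i + 1` refers to
#'   keypoint id `i`.
#' @export
absent_keypoints <- function(frame, conf_min = 0.1) {
  frame[, 3L] < conf_min | (frame[, 1L] == 0 & frame[, 2L] == 0)
}

#' Construct a skeleton sequence
#'
#' Time-ordered skeleton frames stored densely as a T x 25 x 3 array
#' (frames x keypoints x (x, y, confidence)).
#'
#' @param frames Either a T x 25 x 3 numeric array or a list of
#'   `skeleton_frame` objects.
#' @param fps Frames per second (default 50, the sampling rate the repair
#'   windows are tuned for).
#' @param frame_index Optional integer vector of frame indices; defaults to
#'   `0:(T-1)`. Must be strictly increasing.
#' @return A `skeleton_sequence` with elements `arr`, `fps`, `frame_index`.
#' @export
skeleton_sequence <- function(frames, fps = 50, frame_index = NULL) {
  if (is.list(frames)) {
    idx <- vapply(frames, function(f) attr(f, "frame_index"), integer(1))
    arr <- array(NA_real_, dim = c(length(frames), 25L, 3L))
    for (i in seq_along(frames)) arr[i, , ] <- unclass(frames[[i]])
    if (is.null(frame_index)) frame_index <- idx
  } else {
    arr <- frames
    if (length(dim(arr)) != 3L || dim(arr)[2L] != 25L || dim(arr)[3L] != 3L)
      stop("frames must be a T x 25 x 3 array")
    if (is.null(frame_index)) frame_index <- seq_len(dim(arr)[1L]) - 1L
  }
  if (fps <= 0) stop("fps must be positive")
  if (any(diff(frame_index) <= 0))
    stop("frame indices must be strictly increasing")
  dimnames(arr) <- list(NULL, NULL, c("x", "y", "confidence"))
  structure(list(arr = arr, fps = as.numeric(fps),
                 frame_index = as.integer(frame_index)),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat("<skeleton_sequence> ", n_frames(x), " frames @ ", x$fps, " Hz\n",
      sep = "")
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$arr)[1L]

#' Extract one frame of a sequence
#' @param seq A `skeleton_sequence`.
#' @param t Frame position (1-based).
#' @return A `skeleton_frame`.
#' @export
get_frame <- function(seq, t) {
  skeleton_frame(seq$arr[t, , ], frame_index = seq$frame_index[t])
}

#' Build the link (bone-vector) matrix K
#'
#' Column `j` of K is the 2D bone vector `child - parent` of link `j` in
#' topology order, so K is a 2 x L matrix. Bone vectors cancel global
#' translation by construction.
#'
#' @param frame A `skeleton_frame` (or 25 x 3 keypoint matrix).
#' @param topology A `skeleton_topology` (default [body25_topology()]).
#' @param conf_min Absence threshold forwarded to [absent_keypoints()].
#' @return 2 x L numeric matrix (pixels).
#' @export
build_link_matrix <- function(frame, topology = body25_topology(),
                              conf_min = 0.1) {
  links <- topology$links
  need <- sort(unique(as.integer(links)))
  miss <- need[absent_keypoints(frame, conf_min)[need + 1L]]
  if (length(miss))
    stop(incomplete_frame_error(miss, attr(frame, "frame_index")))
  xy <- unclass(frame)[, 1:2, drop = FALSE]
  t(xy[links[, 2L] + 1L, , drop = FALSE] - xy[links[, 1L] + 1L, , drop = FALSE])
}

incomplete_frame_error <- function(missing_ids, frame_index = NULL) {
  structure(
    class = c("incomplete_frame_error", "error", "condition"),
    list(message = paste0("incomplete frame",
                          if (!is.null(frame_index)) paste0(" ", frame_index),
                          ": absent keypoint id(s) ",
                          paste(missing_ids, collapse = ", ")),
         call = NULL, missing_ids = missing_ids))
}

#' Gram matrix of a link matrix
#'
#' `Psi = t(K) %*% K`. Diagonal entries are squared link lengths; the
#' off-diagonal entry (i, j) is the dot product of bones i and j (callers
#' may normalize to angles). Psi is invariant to rotation and translation
#' of the underlying keypoints.
#'
#' @param K 2 x L link matrix.
#' @return L x L symmetric positive semidefinite matrix (pixels^2).
#' @export
gram <- function(K) {
  if (nrow(K) != 2L) stop("K must have 2 rows (x; y)")
  crossprod(K)
}

#' Temporal kinematic chain matrix
#'
#' The frame-to-frame change of the link Gram matrix,
#' `Phi = gram(K_{t+i}) - gram(K_t)`. Its diagonal tracks changes in
#' squared bone lengths -- zero under any rigid motion, nonzero when a
#' keypoint jumps off its bone, which is the misidentification signal.
#'
#' @param K_t,K_t_plus_i 2 x L link matrices of the two frames, same
#'   topology order.
#' @param interval Temporal interval i (frames) between them, stored on the
#'   result.
#' @return L x L symmetric matrix with attribute `interval`.
#' @export
temporal_chain <- function(K_t, K_t_plus_i, interval = 1L) {
  if (!all(dim(K_t) == dim(K_t_plus_i)))
    stop("link matrices must share dimensions (same topology)")
  structure(gram(K_t_plus_i) - gram(K_t), interval = as.integer(interval))
}
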