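# Missing-skeleton compensation: anchored linear interpolation. For each
# absent keypoint the nearest frames (within a bounded traversal span on
# each side) where that keypoint was actually observed serve as anchors;
# the gap is filled by linear interpolation, matching the constant-velocity
# assumption within the missing region. Repair is per keypoint: a partially
# observed frame keeps its observed points untouched.

#' Find interpolation anchors around a missing frame
#'
#' Searches up to `max_span` frames on each side of `t` for the nearest
#' usable anchor. With `keypoint = NULL` an anchor is a frame classified
#' complete (per `reports`, or with no absent keypoint when `reports` is
#' `NULL`); with a keypoint id, an anchor is any frame where that keypoint
#' is observed.
#'
#' @param seq A [skeleton_sequence].
#' @param t Missing frame position (1-based).
#' @param reports Optional integrity report from [classify_sequence()].
#' @param max_span Traversal bound per side, in frames (default 10).
#' @param keypoint Optional keypoint id (0-24) for per-keypoint anchors.
#' @param conf_min Keypoint absence threshold.
#' @return List `(start_index, end_index, n_missing)` with 1-based frame
#'   positions and the gap length `end - start - 1`, or `NULL` when no
#'   anchor exists on one side within the span (the uncompensable signal).
#' @export
find_anchors <- function(seq, t, reports = NULL, max_span = 10L,
                         keypoint = NULL, conf_min = 0.1) {
  T_ <- n_frames(seq)
  usable <- if (!is.null(keypoint)) {
    !(seq$arr[, keypoint + 1L, 3L] < conf_min |
        (seq$arr[, keypoint + 1L, 1L] == 0 & seq$arr[, keypoint + 1L, 2L] == 0))
  } else if (!is.null(reports)) {
    reports$status == "complete"
  } else {
    rowSums((seq$arr[, , 3L] < conf_min) |
              (seq$arr[, , 1L] == 0 & seq$arr[, , 2L] == 0)) == 0L
  }
  lo <- max(1L, t - max_span); hi <- min(T_, t + max_span)
  before <- which(usable[lo:(t - 1L)]) + lo - 1L
  after <- if (t < T_) which(usable[(t + 1L):hi]) + t else integer()
  if (t == 1L || !length(before) || !length(after)) return(NULL)
  s <- max(before); e <- min(after)
  list(start_index = s, end_index = e, n_missing = e - s - 1L)
}

#' Linear interpolation between two anchor points
#'
#' Point `i` of `n` is `(1 - t) * Ps + t * Pe` with `t = i / (n + 1)`,
#' applied per coordinate.
#'
#' @param Ps,Pe Numeric anchor points (any equal length, typically x/y
#'   pairs).
#' @param n Number of interior points to synthesize.
#' @return `n` x `length(Ps)` matrix of interpolated points (0 rows when
#'   `n = 0`).
#' @export
interpolate_missing <- function(Ps, Pe, n) {
  if (n < 0) stop("n must be non-negative")
  if (length(Ps) != length(Pe)) stop("anchor points must have equal length")
  if (n == 0) return(matrix(numeric(), 0L, length(Ps)))
  tt <- seq_len(n) / (n + 1)
  outer(1 - tt, Ps) + outer(tt, Pe)
}

#' Compensate missing keypoints of a sequence
#'
#' Every absent keypoint with an observed anchor within `max_span` frames
#' on both sides is replaced by its linear interpolation between those
#' anchors; anchors are original observations only (never previously
#' synthesized points). Synthesized keypoints carry the sentinel confidence
#' so measured and inferred points stay distinguishable downstream.
#' Sequence-boundary gaps and gaps wider than the span remain absent
#' (residual missing).
#'
#' @param seq A [skeleton_sequence].
#' @param reports Optional integrity report; statuses of fully repaired
#'   frames are updated from "missing" to "complete" in the returned copy
#'   (re-discrimination is still recommended, and is what [run_pipeline()]
#'   does).
#' @param max_span Traversal bound per side (default 10 frames).
#' @param conf_min Keypoint absence threshold.
#' @param conf_sentinel Confidence assigned to synthesized keypoints
#'   (default 0.5).
#' @return List: `seq` (compensated), `reports` (updated or `NULL`),
#'   `residual` (data frame of per-joint-group missing rates, in percent,
#'   before and after compensation).
#' @export
compensate_sequence <- function(seq, reports = NULL, max_span = 10L,
                                conf_min = 0.1, conf_sentinel = 0.5) {
  arr <- seq$arr
  T_ <- n_frames(seq)
  absent <- (arr[, , 3L] < conf_min) | (arr[, , 1L] == 0 & arr[, , 2L] == 0)
  if (is.null(dim(absent))) absent <- matrix(absent, nrow = T_)
  for (k in seq_len(25L)) {
    miss <- which(absent[, k])
    if (!length(miss)) next
    present <- which(!absent[, k])
    if (!length(present)) next
    # nearest observed frame before and after every frame
    prev_p <- cummax(ifelse(absent[, k], 0L, seq_len(T_)))
    nxt <- rev(cummax(rev(ifelse(absent[, k], 0L, T_ + 1L - seq_len(T_)))))
    next_p <- ifelse(nxt == 0L, NA_integer_, T_ + 1L - nxt)
    s <- prev_p[miss]; e <- next_p[miss]
    ok <- s >= 1L & !is.na(e) & (miss - s) <= max_span & (e - miss) <= max_span
    if (!any(ok)) next
    m <- miss[ok]; s <- s[ok]; e <- e[ok]
    w <- (m - s) / (e - s)
    arr[cbind(m, k, 1L)] <- (1 - w) * arr[cbind(s, k, 1L)] + w * arr[cbind(e, k, 1L)]
    arr[cbind(m, k, 2L)] <- (1 - w) * arr[cbind(s, k, 2L)] + w * arr[cbind(e, k, 2L)]
    arr[cbind(m, k, 3L)] <- conf_sentinel
  }
  out <- seq
  out$arr <- arr
  groups <- body25_joint_groups()
  rate <- function(a) vapply(groups, function(ids)
    100 * mean(apply(a[, ids + 1L, drop = FALSE], 1L, any)), numeric(1))
  absent_after <- (arr[, , 3L] < conf_min) |
    (arr[, , 1L] == 0 & arr[, , 2L] == 0)
  if (is.null(dim(absent_after))) absent_after <- matrix(absent_after, nrow = T_)
  residual <- data.frame(group = names(groups),
                         before_pct = rate(absent),
                         after_pct = rate(absent_after),
                         row.names = NULL)
  if (!is.null(reports)) {
    repaired <- reports$status == "missing" & rowSums(absent_after) == 0L
    reports$status[repaired] <- "complete"
    reports$missing_ids[repaired] <- ""
    reports$n_missing[repaired] <- 0L
  }
  list(seq = out, reports = reports, residual = residual)
}
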