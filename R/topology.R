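#' BODY_25 keypoint names
#'
#' Keypoint names in the OpenPose BODY_25 numbering (ids 0--24). Position
#' `i + 1` of the vector is keypoint id `i`.
#'
#' @return Character vector of length 25.
#' @export
body25_keypoints <- function() {
  c("Nose", "Neck", "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist", "MidHip",
    "RHip", "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar",
    "LBigToe", "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel")
}

#' Skeleton topology (link list)
#'
#' A skeleton topology is an ordered list of links (bones), each a
#' (parent, child) pair of keypoint ids. The order is fixed so that the
#' columns of every link matrix built from it are reproducible.
#'
#' @param links Integer matrix with two columns (`parent`, `child`) of
#'   keypoint ids, one row per link.
#' @param n_keypoints Number of keypoint slots the ids index into.
#'
#' @return An object of class `skeleton_topology` with elements `links`
#'   (L x 2 integer matrix) and `n_keypoints`.
#' @export
skeleton_topology <- function(links, n_keypoints = 25L) {
  links <- matrix(as.integer(links), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  if (any(links < 0L) || any(links >= n_keypoints))
    stop("link ids must lie in [0, ", n_keypoints - 1L, "]")
  if (any(links[, 1L] == links[, 2L]))
    stop("self-links are not allowed")
  structure(list(links = links, n_keypoints = as.integer(n_keypoints)),
            class = "skeleton_topology")
}

#' @export
print.skeleton_topology <- function(x, ...) {
  cat("<skeleton_topology> ", nrow(x$links), " links over ",
      x$n_keypoints, " keypoints\n", sep = "")
  invisible(x)
}

#' Number of links in a topology
#' @param topology A `skeleton_topology`.
#' @return Integer link count L.
#' @export
n_links <- function(topology) nrow(topology$links)

#' The BODY_25 tree topology
#'
#' The 24-link tree over the BODY_25 keypoints, rooted at MidHip (8).
#' Link order is fixed (torso, head, right arm, left arm, right leg and
#' foot, left leg and foot) and versioned: column `j` of every link matrix
#' is the bone `links[j, "child"] - links[j, "parent"]`.
#'
#' @return A `skeleton_topology` with 24 links.
#' @export
body25_topology <- function() {
  links <- rbind(
    c(8L, 1L),            # trunk: MidHip -> Neck
    c(1L, 0L),            # Neck -> Nose
    c(0L, 15L), c(15L, 17L),  # right eye, ear
    c(0L, 16L), c(16L, 18L),  # left eye, ear
    c(1L, 2L), c(2L, 3L), c(3L, 4L),      # right arm
    c(1L, 5L), c(5L, 6L), c(6L, 7L),      # left arm
    c(8L, 9L), c(9L, 10L), c(10L, 11L),   # right leg
    c(11L, 22L), c(22L, 23L), c(11L, 24L),  # right foot
    c(8L, 12L), c(12L, 13L), c(13L, 14L),   # left leg
    c(14L, 19L), c(19L, 20L), c(14L, 21L))  # left foot
  skeleton_topology(links, 25L)
}

#' Keypoint ids of the eight REBA joint groups
#'
#' Groups mirror the per-joint reporting granularity used for missing-rate
#' tables: trunk, neck, legs and arms split by side.
#'
#' @return Named list of integer keypoint-id vectors.
#' @export
body25_joint_groups <- function() {
  list(
    "Trunk"       = c(1L, 8L),
    "Neck"        = c(0L, 1L),
    "Leg-R"       = c(9L, 10L, 11L),
    "Leg-L"       = c(12L, 13L, 14L),
    "Upper arm-R" = c(2L, 3L),
    "Upper arm-L" = c(5L, 6L),
    "Lower arm-R" = c(3L, 4L),
    "Lower arm-L" = c(6L, 7L))
}

#' Keypoints downstream of each link (distal subtree)
#'
#' For link j, the set of keypoint ids in the subtree hanging off its child
#' (child included). Used to decide which keypoints to re-synthesize when a
#' link's length is violated.
#'
#' @param topology A `skeleton_topology`.
#' @return List of integer vectors, one per link, in link order.
#' @export
link_subtrees <- function(topology) {
  links <- topology$links
  children <- lapply(seq_len(topology$n_keypoints) - 1L, function(p)
    links[links[, 1L] == p, 2L])
  descend <- function(k) {
    out <- k
    for (c in children[[k + 1L]]) out <- c(out, descend(c))
    out
  }
  lapply(seq_len(nrow(links)), function(j) descend(links[j, 2L]))
}
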