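# Shared fixtures: tiny frames, rigid transforms, and scaled-down clip
# factories. Everything is built in code at test time.

# a frame with all 25 keypoints at given coordinates (default: distinct,
# non-degenerate positions from the synthetic neutral stance), conf 0.9
neutral_frame <- function(frame_index = 0L) {
  xy <- skelrepair:::synthetic_pose(skelrepair:::synthetic_neutral())
  skeleton_frame(cbind(xy, 0.9), frame_index = frame_index)
}

# apply a rigid transform (rotation by theta radians + translation) to a
# frame's keypoints
rigid_transform <- function(frame, theta = 0, dx = 0, dy = 0) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  kp <- unclass(frame)
  kp[, 1:2] <- t(R %*% t(kp[, 1:2, drop = FALSE])) +
    matrix(c(dx, dy), nrow(kp), 2L, byrow = TRUE)
  skeleton_frame(kp, frame_index = attr(frame, "frame_index"))
}

# two-link toy topology over 25 keypoint slots: links (0,1) and (0,2)
toy_topology <- function() skeleton_topology(rbind(c(0L, 1L), c(0L, 2L)))

# frame placing keypoints 0..2 and leaving the rest far away but present;
# the parent sits off the origin so it is not mistaken for an absent point
toy_frame <- function(p0 = c(10, 10), p1 = p0 + c(3, 0), p2 = p0 + c(0, 4)) {
  kp <- cbind(matrix(rep(c(500, 500), each = 25L), 25L, 2L), 0.9)
  kp[1L, 1:2] <- p0; kp[2L, 1:2] <- p1; kp[3L, 1:2] <- p2
  skeleton_frame(kp)
}

# random K matrix with L links (columns), coordinates in [-50, 50]
random_K <- function(L = 5L) matrix(stats::runif(2L * L, -50, 50), 2L, L)

# small labelled clip set for ST-GCN tests
make_clips <- function(n, len, seed0, noise_px = 2) {
  seqs <- vector("list", n); labs <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- if (i %% 2L == 0L) "bend" else "lift"
    g <- generate_sequence(data.frame(label = lab, frames = len),
                           noise_px = noise_px, seed = seed0 + i)
    seqs[[i]] <- g$seq
    labs[[i]] <- g$labels
  }
  list(seqs = seqs, labs = labs)
}
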