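# Readers/writers for the OpenPose BODY_25 per-frame JSON dialect, the
# actions sidecar, run manifests, and the end-to-end pipeline.

#' Read a skeleton sequence from OpenPose-dialect JSON
#'
#' Accepts either a single JSON file holding an array of per-frame objects,
#' or a directory of per-frame `*_keypoints.json` files (lexicographic
#' order). Each frame object carries `people`, a list of person records
#' with a flat 75-value `pose_keypoints_2d` (x, y, confidence for 25
#' keypoints). An empty `people` array yields a frame with all keypoints
#' absent. Person association is assumed done upstream: `person` selects
#' which record to read.
#'
#' @param path JSON file or directory.
#' @param person 1-based person index (default 1).
#' @param fps Frames per second recorded in the sequence (default 50).
#' @return A [skeleton_sequence].
#' @export
read_openpose_json <- function(path, person = 1L, fps = 50) {
  frames <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "_keypoints\\.json$",
                             full.names = TRUE))
    if (!length(files)) stop("no *_keypoints.json files in ", path)
    lapply(files, function(f) jsonlite::fromJSON(f, simplifyVector = FALSE))
  } else {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.null(x$people)) list(x) else x
  }
  arr <- array(0, dim = c(length(frames), 25L, 3L))
  for (i in seq_along(frames)) {
    ppl <- frames[[i]]$people
    if (is.null(ppl) || length(ppl) < person) next   # all-absent frame
    kp <- unlist(ppl[[person]]$pose_keypoints_2d)
    if (length(kp) != 75L)
      stop("frame ", i, ": expected 75 keypoint values, got ", length(kp))
    arr[i, , ] <- matrix(kp, 25L, 3L, byrow = TRUE)
  }
  fi <- vapply(frames, function(f)
    if (is.null(f$frame_index)) NA_integer_ else as.integer(f$frame_index),
    integer(1))
  if (anyNA(fi)) fi <- seq_along(frames) - 1L
  skeleton_sequence(arr, fps = fps, frame_index = fi)
}

#' Write a skeleton sequence as OpenPose-dialect JSON
#'
#' One array of frame objects; coordinates and confidences are serialized
#' at 3 decimal places, so write-then-read round-trips exactly at that
#' precision.
#'
#' @param seq A [skeleton_sequence].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_openpose_json <- function(seq, path) {
  frames <- lapply(seq_len(n_frames(seq)), function(t) {
    kp <- round(as.numeric(t(seq$arr[t, , ])), 3)
    list(frame_index = seq$frame_index[t],
         people = list(list(pose_keypoints_2d = kp)))
  })
  jsonlite::write_json(frames, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write per-frame action weights (actions JSON sidecar)
#'
#' The actions sidecar is an array of `{frame_index, weights: {label:
#' value}}` objects, the exchange format for externally computed
#' classifiers.
#'
#' @param weights An [action_weights] matrix.
#' @param path File path.
#' @return `read_actions_json`: an [action_weights]; `write_actions_json`:
#'   `path`, invisibly.
#' @export
write_actions_json <- function(weights, path) {
  fi <- attr(weights, "frame_index")
  rows <- lapply(seq_len(nrow(weights)), function(i)
    list(frame_index = fi[i],
         weights = as.list(stats::setNames(round(unclass(weights)[i, ], 6),
                                           colnames(weights)))))
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_actions_json
#' @export
read_actions_json <- function(path) {
  rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  labels <- names(rows[[1L]]$weights)
  w <- t(vapply(rows, function(r) unlist(r$weights[labels]),
                numeric(length(labels))))
  colnames(w) <- labels
  w <- w / rowSums(w)   # renormalize rounded rows
  action_weights(w, frame_index = vapply(rows, function(r)
    as.integer(r$frame_index), integer(1)))
}

#' Pipeline configuration
#'
#' Bundles every threshold, span and noise parameter of the pipeline with
#' its documented default: absence confidence 0.1, bone-anomaly threshold
#' tau 0.2 with 2-frame persistence and a 50 px length floor, traversal
#' span 10 frames per side, action dominance 0.6 (strict), Kalman Q = 1e-3
#' / R = 1e-2 px^2, and the default synthetic fixture (2 labels x 1000
#' frames at 50 Hz, noise 1.5 px, 10% injected missing in 5-frame bursts,
#' 5% injected misidentification of magnitude 0.5 lasting 4 frames, mock
#' classifier confusion 0.02).
#'
#' @param ... Overrides for any default listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    conf_min = 0.1, tau = 0.2, persistence = 2L, span = 10L,
    dominance = 0.6, policy = "any", len_floor_px = 50,
    conf_sentinel = 0.5, kalman = kalman_params(), smooth = TRUE,
    reba = reba_config(), fps = 50, seed = 1L,
    # synthetic fixture
    n_frames = 2000L, labels = c("bend", "lift"), noise_px = 1.5,
    missing_rate = 0.10, burst_len = 5L,
    misid_rate = 0.05, misid_magnitude = 0.5, misid_duration = 4L,
    misid_mode = "limb_displace", confusion = 0.02)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Build the default corrupted synthetic fixture
#'
#' Generates the scripted sequence, injects misidentification events and
#' then missing bursts into the noisy detector-style observation, and
#' produces mock action weights. `truth` is the noise-free kinematic
#' sequence -- the role an independent sensor-based reference plays when
#' evaluating against real recordings. All randomness derives from
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return List: `truth` (noise-free sequence), `labels`, `observed`
#'   (noisy, uncorrupted), `seq` (noisy and corrupted), `weights`, `logs`
#'   (corruption logs, in restoration order).
#' @export
synthetic_fixture <- function(config = pipeline_config()) {
  half <- config$n_frames %/% 2L
  script <- data.frame(label = config$labels,
                       frames = c(half, config$n_frames - half))
  gen <- generate_sequence(script, fps = config$fps,
                           noise_px = config$noise_px, seed = config$seed)
  mis <- inject_misidentification(gen$seq, config$misid_rate,
                                  mode = config$misid_mode,
                                  magnitude = config$misid_magnitude,
                                  duration = config$misid_duration,
                                  seed = config$seed + 1L)
  msg <- inject_missing(mis$seq, config$missing_rate,
                        burst_len = config$burst_len,
                        seed = config$seed + 2L)
  weights <- mock_classify(gen$labels, confusion = config$confusion,
                           seed = config$seed + 3L)
  list(truth = gen$truth, labels = gen$labels, observed = gen$seq,
       seq = msg$seq, weights = weights, logs = list(msg$log, mis$log))
}

#' Run the full repair and scoring pipeline
#'
#' Discriminate, compensate, re-discriminate, correct (with Kalman
#' smoothing), score REBA, and evaluate against ground truth when it is
#' available. With `seq = NULL` the default synthetic fixture from
#' [synthetic_fixture()] is used, in which case ground-truth metrics (MAE
#' before/after repair, REBA accuracy) are included in the summary.
#'
#' @param config A [pipeline_config()].
#' @param seq Optional input [skeleton_sequence] (e.g. from
#'   [read_openpose_json()]).
#' @param weights Optional [action_weights]; required when `seq` is given
#'   and the heterogeneity channel is wanted.
#' @param truth Optional ground-truth [skeleton_sequence] aligned with
#'   `seq`.
#' @return List with the repaired sequence (`seq`), final integrity
#'   reports, REBA score table (`scores`), per-stage rates and metrics
#'   (`summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), seq = NULL,
                         weights = NULL, truth = NULL) {
  if (is.null(seq)) {
    fx <- synthetic_fixture(config)
    seq <- fx$seq; weights <- fx$weights; truth <- fx$truth
  }
  cls <- function(s, w) classify_sequence(
    s, w, conf_min = config$conf_min, tau = config$tau,
    persistence = config$persistence, span = config$span,
    dominance = config$dominance, policy = config$policy,
    len_floor_px = config$len_floor_px)
  reports0 <- cls(seq, weights)
  rates_before <- corruption_rates(reports0)
  comp <- compensate_sequence(seq, reports0, max_span = config$span,
                              conf_min = config$conf_min,
                              conf_sentinel = config$conf_sentinel)
  reports1 <- cls(comp$seq, weights)
  corr <- correct_sequence(comp$seq, reports1, weights,
                           span = config$span, dominance = config$dominance,
                           conf_min = config$conf_min, tau = config$tau,
                           persistence = config$persistence,
                           policy = config$policy,
                           len_floor_px = config$len_floor_px,
                           kalman = config$kalman, smooth = config$smooth)
  rates_after <- corruption_rates(corr$reports)
  scores <- reba_score_sequence(corr$seq, config$reba, config$conf_min)
  summary <- list(
    n_frames = n_frames(seq),
    missing_before_pct = rates_before$missing,
    missing_after_pct = rates_after$missing,
    misid_before_pct = rates_before$misidentification,
    misid_after_pct = rates_after$misidentification,
    residual = comp$residual,
    uncorrectable = corr$uncorrectable)
  if (!is.null(truth)) {
    ang_truth <- joint_angles_sequence(truth, config$conf_min)
    ang_before <- joint_angles_sequence(seq, config$conf_min)
    ang_after <- joint_angles_sequence(corr$seq, config$conf_min)
    per_joint <- function(a) vapply(seq_len(ncol(a)), function(j)
      as.numeric(mae(a[, j], ang_truth[, j])), numeric(1))
    summary$mae_before <- stats::setNames(per_joint(ang_before),
                                          colnames(ang_truth))
    summary$mae_after <- stats::setNames(per_joint(ang_after),
                                         colnames(ang_truth))
    truth_scores <- reba_score_sequence(truth, config$reba, config$conf_min)
    summary$reba_accuracy <- as.numeric(
      reba_accuracy(scores$final, truth_scores$final))
  }
  list(seq = corr$seq, reports = corr$reports, weights = corr$weights,
       scores = scores, summary = summary, config = config)
}

#' Write pipeline outputs to disk
#'
#' Sequence as OpenPose-dialect JSON, integrity reports and REBA scores as
#' CSV, plus a run manifest (JSON) echoing the seed and every threshold
#' used, for provenance.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(poses = file.path(dir, "poses_final.json"),
             reports = file.path(dir, "reports.csv"),
             scores = file.path(dir, "scores.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_openpose_json(result$seq, paths[["poses"]])
  utils::write.csv(result$reports, paths[["reports"]], row.names = FALSE)
  utils::write.csv(result$scores, paths[["scores"]], row.names = FALSE)
  cfg <- unclass(result$config)
  cfg$kalman <- unclass(cfg$kalman)
  cfg$reba <- unclass(cfg$reba)
  jsonlite::write_json(cfg, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths
}
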