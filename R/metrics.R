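# Evaluation metrics over frame-aligned paired series: mean absolute error
# of joint angles, REBA score accuracy, and missing/misidentification
# rates. Frames unavailable in either series are excluded pairwise and
# counted.

#' Mean absolute error between aligned series
#'
#' @param a,b Numeric series of equal length. Pairs with `NA` in either are
#'   excluded and counted in the `n_excluded` attribute.
#' @return MAE (same units as the inputs) with attributes `n_used`,
#'   `n_excluded`.
#' @export
mae <- function(a, b) {
  if (length(a) != length(b)) stop("series must be aligned (equal length)")
  if (!length(a)) stop("series must be nonempty")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no aligned non-missing pairs")
  structure(mean(abs(a[ok] - b[ok])),
            n_used = sum(ok), n_excluded = sum(!ok))
}

#' REBA score accuracy (percent agreement)
#'
#' `100 * F_m / F`: the share of frames whose final REBA score matches the
#' reference. Pairs with `NA` in either series are excluded pairwise.
#'
#' @param scores,truth Integer series of final REBA scores, aligned.
#' @return Percentage in `[0, 100]` with attributes `n_used`,
#'   `n_excluded`.
#' @export
reba_accuracy <- function(scores, truth) {
  if (length(scores) != length(truth)) stop("series must be aligned")
  if (!length(scores)) stop("series must be nonempty")
  ok <- !is.na(scores) & !is.na(truth)
  if (!any(ok)) stop("no aligned non-missing pairs")
  structure(100 * mean(scores[ok] == truth[ok]),
            n_used = sum(ok), n_excluded = sum(!ok))
}

#' Missing and misidentification rates from an integrity report
#'
#' Missing rates are per joint group (a frame counts when any keypoint of
#' the group is absent); the misidentification rate is a single overall
#' figure across all joints.
#'
#' @param reports Integrity report from [classify_sequence()].
#' @param joint_groups Named list of keypoint-id vectors (default
#'   [body25_joint_groups()]).
#' @return List: `missing` (named percentage vector per group),
#'   `misidentification` (single percentage).
#' @export
corruption_rates <- function(reports, joint_groups = body25_joint_groups()) {
  ids <- lapply(strsplit(reports$missing_ids, ","), function(x)
    as.integer(x[nzchar(x)]))
  missing <- vapply(joint_groups, function(g)
    100 * mean(vapply(ids, function(i) any(g %in% i), logical(1))),
    numeric(1))
  list(missing = missing,
       misidentification = 100 * mean(reports$status == "misidentified"))
}
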