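# Per-frame action weights. The repair pipeline only consumes normalized
# weight vectors, so any producer can stand behind this interface: the
# deterministic mock below, the miniature ST-GCN (stgcn.R), or externally
# computed weights read from an actions JSON file.

#' Construct an action-weights table
#'
#' @param weights Numeric T x A matrix, one row per frame, columns named by
#'   action label. Rows must be nonnegative and sum to 1 (within 1e-6).
#' @param frame_index Optional integer frame indices (default `0:(T-1)`).
#' @return An `action_weights` object (the matrix with an index attribute).
#' @export
action_weights <- function(weights, frame_index = NULL) {
  weights <- as.matrix(weights)
  if (is.null(colnames(weights))) stop("weight columns must be named by label")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (any(abs(rowSums(weights) - 1) > 1e-6))
    stop("each frame's weights must sum to 1")
  if (is.null(frame_index)) frame_index <- seq_len(nrow(weights)) - 1L
  structure(weights, frame_index = as.integer(frame_index),
            class = c("action_weights", "matrix", "array"))
}

#' Per-frame argmax labels of an action-weights table
#' @param weights An `action_weights` matrix.
#' @return Character vector of labels, one per frame.
#' @export
argmax_labels <- function(weights) {
  colnames(weights)[max.col(unclass(weights), ties.method = "first")]
}

#' Deterministic mock action classifier
#'
#' Turns a script of true per-frame labels into one-hot action weights,
#' flipping each frame's label to a uniformly chosen other label with
#' probability `confusion`. Reproducible under `seed`; the plumbing
#' counterpart to a trained classifier for pipeline testing.
#'
#' @param script Character vector of true per-frame labels.
#' @param confusion Label-flip probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param labels Label universe (default the labels present in `script`;
#'   must contain all of them).
#' @return An [action_weights] matrix, one-hot rows.
#' @export
mock_classify <- function(script, confusion = 0, seed = 1L, labels = NULL) {
  if (!length(script)) stop("script must be nonempty")
  stopifnot(confusion >= 0, confusion < 1)
  if (is.null(labels)) labels <- sort(unique(script))
  unknown <- setdiff(script, labels)
  if (length(unknown))
    stop("unknown label(s) in script: ", paste(unknown, collapse = ", "))
  out <- script
  if (confusion > 0 && length(labels) > 1L) {
    local_seed(seed, {
      flip <- stats::runif(length(script)) < confusion
      for (i in which(flip))
        out[i] <- sample(setdiff(labels, script[i]), 1L)
    })
  }
  w <- matrix(0, length(script), length(labels),
              dimnames = list(NULL, labels))
  w[cbind(seq_along(out), match(out, labels))] <- 1
  action_weights(w)
}
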