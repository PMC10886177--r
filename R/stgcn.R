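# Miniature spatial-temporal graph convolutional action classifier.
#
# The smallest structure exhibiting the ST-GCN topology: two spatial
# graph-convolution blocks with residual connections, then two
# spatial-temporal blocks (graph conv + temporal conv, kernel 9) chained by
# dense concatenation, mean-pooled over keypoints into a per-frame softmax.
# Trained by Adam on cross-entropy, entirely in base R (CPU, desk scale).
# Hidden width 32 throughout; adjacency is the BODY_25 graph with self
# loops, symmetrically normalized.

# features are arrays A[V, C, T]; two reshape helpers
.to_vt <- function(A) {                 # -> (V*T) x C
  d <- dim(A)
  M <- aperm(A, c(1L, 3L, 2L))
  dim(M) <- c(d[1L] * d[3L], d[2L])
  M
}
.from_vt <- function(M, V, T_) {        # inverse of .to_vt
  C <- ncol(M)
  dim(M) <- c(V, T_, C)
  aperm(M, c(1L, 3L, 2L))
}

.adj_mul <- function(Adj, A) {          # Adj %*% A[, , t] for every t
  d <- dim(A)
  dim(A) <- c(d[1L], d[2L] * d[3L])
  out <- Adj %*% A
  dim(out) <- d
  out
}

.chan_mix <- function(A, W) {           # A[,c_in,] %*% W -> [,c_out,]
  d <- dim(A)
  .from_vt(.to_vt(A) %*% W, d[1L], d[3L])
}

.shift_t <- function(A, k) {            # A[, , t + k], zero-padded
  d <- dim(A)
  out <- array(0, d)
  T_ <- d[3L]
  if (k >= 0) {
    if (k < T_) out[, , seq_len(T_ - k)] <- A[, , (k + 1L):T_, drop = FALSE]
  } else {
    if (-k < T_) out[, , (1L - k):T_] <- A[, , seq_len(T_ + k), drop = FALSE]
  }
  out
}

.tconv_fwd <- function(A, Ws) {         # kernel length = length(Ws), 'same'
  half <- (length(Ws) - 1L) %/% 2L
  out <- NULL
  for (j in seq_along(Ws)) {
    term <- .chan_mix(.shift_t(A, j - 1L - half), Ws[[j]])
    out <- if (is.null(out)) term else out + term
  }
  out
}

.tconv_bwd <- function(A, Ws, dY) {
  half <- (length(Ws) - 1L) %/% 2L
  d <- dim(A)
  dA <- array(0, d)
  dWs <- vector("list", length(Ws))
  for (j in seq_along(Ws)) {
    k <- j - 1L - half
    Ashift <- .shift_t(A, k)
    dWs[[j]] <- crossprod(.to_vt(Ashift), .to_vt(dY))
    dA <- dA + .from_vt(.to_vt(.shift_t(dY, -k)) %*% t(Ws[[j]]), d[1L], d[3L])
  }
  list(dA = dA, dWs = dWs)
}

# normalized adjacency for the BODY_25 graph (self loops, D^-1/2 A D^-1/2)
stgcn_adjacency <- function(topology = body25_topology()) {
  V <- topology$n_keypoints
  A <- diag(V)
  for (j in seq_len(nrow(topology$links))) {
    a <- topology$links[j, 1L] + 1L
    b <- topology$links[j, 2L] + 1L
    A[a, b] <- A[b, a] <- 1
  }
  dinv <- 1 / sqrt(rowSums(A))
  A * outer(dinv, dinv)
}

# per-frame input features: keypoints centered on MidHip, scaled by trunk
# length; V x 2 x T array
stgcn_features <- function(seq) {
  arr <- seq$arr
  T_ <- dim(arr)[1L]
  A <- array(0, c(25L, 2L, T_))
  for (t in seq_len(T_)) {
    xy <- arr[t, , 1:2]
    root <- xy[9L, ]
    scale <- sqrt(sum((xy[2L, ] - root)^2))
    if (!is.finite(scale) || scale < 1e-6) scale <- 1
    A[, , t] <- t(t(xy) - root) / scale
  }
  A
}

stgcn_init <- function(n_classes, hidden = 32L, kernel = 9L) {
  g <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(
    W1  = g(2L, hidden), W1r = g(2L, hidden),
    W2  = g(hidden, hidden),
    W3  = g(hidden, hidden),
    TW1 = lapply(seq_len(kernel), function(i) g(hidden, hidden) / kernel),
    W4  = g(2L * hidden, hidden),
    TW2 = lapply(seq_len(kernel), function(i) g(hidden, hidden) / kernel),
    Wc  = g(3L * hidden, n_classes),
    bc  = rep(0, n_classes))
}

stgcn_forward <- function(par, A0, Adj) {
  V <- dim(A0)[1L]; T_ <- dim(A0)[3L]
  relu <- function(x) x * (x > 0)
  Z1 <- .chan_mix(.adj_mul(Adj, A0), par$W1) + .chan_mix(A0, par$W1r)
  H1 <- relu(Z1)
  Z2 <- .chan_mix(.adj_mul(Adj, H1), par$W2) + H1
  H2 <- relu(Z2)
  G1z <- .chan_mix(.adj_mul(Adj, H2), par$W3); G1 <- relu(G1z)
  T1z <- .tconv_fwd(G1, par$TW1); T1 <- relu(T1z)
  D1 <- array(0, c(V, 2L * dim(T1)[2L], T_))
  D1[, seq_len(dim(H2)[2L]), ] <- H2
  D1[, dim(H2)[2L] + seq_len(dim(T1)[2L]), ] <- T1
  G2z <- .chan_mix(.adj_mul(Adj, D1), par$W4); G2 <- relu(G2z)
  T2z <- .tconv_fwd(G2, par$TW2); T2 <- relu(T2z)
  hid <- dim(H2)[2L]
  P <- array(0, c(V, 3L * hid, T_))
  P[, seq_len(hid), ] <- H2
  P[, hid + seq_len(hid), ] <- T1
  P[, 2L * hid + seq_len(hid), ] <- T2
  F_ <- t(apply(P, c(2L, 3L), mean))              # T x 3*hidden
  logits <- sweep(F_ %*% par$Wc, 2L, par$bc, "+") # T x classes
  list(A0 = A0, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, G1z = G1z, G1 = G1,
       T1z = T1z, T1 = T1, D1 = D1, G2z = G2z, G2 = G2, T2z = T2z, T2 = T2,
       F_ = F_, logits = logits)
}

.softmax_rows <- function(L) {
  m <- apply(L, 1L, max)
  e <- exp(L - m)
  e / rowSums(e)
}

stgcn_backward <- function(par, cache, Adj, y_idx) {
  V <- dim(cache$A0)[1L]; T_ <- dim(cache$A0)[3L]
  hid <- dim(cache$H2)[2L]
  Pr <- .softmax_rows(cache$logits)
  dlogits <- Pr
  dlogits[cbind(seq_len(T_), y_idx)] <- dlogits[cbind(seq_len(T_), y_idx)] - 1
  dlogits <- dlogits / T_
  gWc <- crossprod(cache$F_, dlogits)
  gbc <- colSums(dlogits)
  dF <- dlogits %*% t(par$Wc)                    # T x 3*hidden
  # un-pool: gradient spread uniformly over keypoints
  dP <- array(0, c(V, 3L * hid, T_))
  for (c in seq_len(3L * hid)) dP[, c, ] <- matrix(dF[, c], V, T_,
                                                   byrow = TRUE) / V
  dH2 <- dP[, seq_len(hid), , drop = FALSE]
  dT1 <- dP[, hid + seq_len(hid), , drop = FALSE]
  dT2 <- dP[, 2L * hid + seq_len(hid), , drop = FALSE]
  # ST block 2
  dT2z <- dT2 * (cache$T2z > 0)
  tb2 <- .tconv_bwd(cache$G2, par$TW2, dT2z)
  dG2z <- tb2$dA * (cache$G2z > 0)
  AD1 <- .adj_mul(Adj, cache$D1)
  gW4 <- crossprod(.to_vt(AD1), .to_vt(dG2z))
  dD1 <- .adj_mul(Adj, .from_vt(.to_vt(dG2z) %*% t(par$W4), V, T_))
  dH2 <- dH2 + dD1[, seq_len(hid), , drop = FALSE]
  dT1 <- dT1 + dD1[, hid + seq_len(hid), , drop = FALSE]
  # ST block 1
  dT1z <- dT1 * (cache$T1z > 0)
  tb1 <- .tconv_bwd(cache$G1, par$TW1, dT1z)
  dG1z <- tb1$dA * (cache$G1z > 0)
  AH2 <- .adj_mul(Adj, cache$H2)
  gW3 <- crossprod(.to_vt(AH2), .to_vt(dG1z))
  dH2 <- dH2 + .adj_mul(Adj, .from_vt(.to_vt(dG1z) %*% t(par$W3), V, T_))
  # spatial block 2 (identity residual)
  dZ2 <- dH2 * (cache$Z2 > 0)
  AH1 <- .adj_mul(Adj, cache$H1)
  gW2 <- crossprod(.to_vt(AH1), .to_vt(dZ2))
  dH1 <- .adj_mul(Adj, .from_vt(.to_vt(dZ2) %*% t(par$W2), V, T_)) + dZ2
  # spatial block 1 (projected residual)
  dZ1 <- dH1 * (cache$Z1 > 0)
  AA0 <- .adj_mul(Adj, cache$A0)
  gW1 <- crossprod(.to_vt(AA0), .to_vt(dZ1))
  gW1r <- crossprod(.to_vt(cache$A0), .to_vt(dZ1))
  list(W1 = gW1, W1r = gW1r, W2 = gW2, W3 = gW3, TW1 = tb1$dWs,
       W4 = gW4, TW2 = tb2$dWs, Wc = gWc, bc = gbc)
}

# flatten / unflatten parameter lists for the Adam update
.par_flatten <- function(p) unlist(p, use.names = FALSE)
.par_unflatten <- function(vec, template) {
  relist_ <- function(tpl, pos) {
    if (is.list(tpl)) {
      out <- tpl
      for (i in seq_along(tpl)) {
        r <- relist_(tpl[[i]], pos)
        out[[i]] <- r$val
        pos <- r$pos
      }
      return(list(val = out, pos = pos))
    }
    n <- length(tpl)
    val <- vec[pos:(pos + n - 1L)]
    if (is.matrix(tpl)) dim(val) <- dim(tpl)
    list(val = val, pos = pos + n)
  }
  relist_(template, 1L)$val
}

#' Train the miniature ST-GCN action classifier
#'
#' @param sequences List of [skeleton_sequence] objects (training clips).
#' @param labels List of character vectors, per-frame true labels aligned
#'   with `sequences`.
#' @param epochs Training epochs (default 30).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param hidden Hidden channel width (default 32).
#' @param lr Adam learning rate (default 0.01).
#' @param batch_size Sequences per Adam step (default 16).
#' @return An object of class `stgcn` holding the trained parameters, the
#'   class labels, final training loss (`loss`) and per-frame training
#'   accuracy (`train_accuracy`).
#' @export
stgcn_train <- function(sequences, labels, epochs = 30L, seed = 1L,
                        hidden = 32L, lr = 0.01, batch_size = 16L) {
  stopifnot(length(sequences) == length(labels), length(sequences) > 0)
  classes <- sort(unique(unlist(labels)))
  if (length(classes) < 2L) stop("need at least 2 action classes")
  Adj <- stgcn_adjacency()
  feats <- lapply(sequences, stgcn_features)
  yidx <- lapply(labels, function(l) match(l, classes))
  n <- length(feats)
  par <- m <- v <- NULL
  step <- 0L
  local_seed(seed, {
    par <- stgcn_init(length(classes), hidden = hidden)
    vec <- .par_flatten(par)
    m <- numeric(length(vec)); v <- numeric(length(vec))
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (b0 in seq(1L, n, by = batch_size)) {
        batch <- ord[b0:min(b0 + batch_size - 1L, n)]
        gacc <- NULL
        for (s in batch) {
          cache <- stgcn_forward(par, feats[[s]], Adj)
          g <- stgcn_backward(par, cache, Adj, yidx[[s]])
          gv <- .par_flatten(g)
          gacc <- if (is.null(gacc)) gv else gacc + gv
        }
        gacc <- gacc / length(batch)
        step <- step + 1L
        pv <- .par_flatten(par)
        m <- 0.9 * m + 0.1 * gacc
        v <- 0.999 * v + 0.001 * gacc^2
        mhat <- m / (1 - 0.9^step)
        vhat <- v / (1 - 0.999^step)
        pv <- pv - lr * mhat / (sqrt(vhat) + 1e-8)
        par <- .par_unflatten(pv, par)
      }
    }
  })
  # final training loss / accuracy
  loss <- 0; correct <- 0L; total <- 0L
  for (s in seq_len(n)) {
    cache <- stgcn_forward(par, feats[[s]], Adj)
    Pr <- .softmax_rows(cache$logits)
    T_ <- nrow(Pr)
    loss <- loss + -sum(log(pmax(Pr[cbind(seq_len(T_), yidx[[s]])], 1e-12)))
    correct <- correct + sum(max.col(Pr, ties.method = "first") == yidx[[s]])
    total <- total + T_
  }
  structure(list(par = par, classes = classes, Adj = Adj, hidden = hidden,
                 kernel = 9L, loss = loss / total,
                 train_accuracy = correct / total),
            class = "stgcn")
}

#' @export
print.stgcn <- function(x, ...) {
  cat("<stgcn> classes:", paste(x$classes, collapse = ", "),
      sprintf("| train acc %.3f, loss %.4f\n", x$train_accuracy, x$loss))
  invisible(x)
}

#' Per-frame action weights from a trained ST-GCN
#'
#' Sequences shorter than the temporal receptive field are replicate-edge
#' padded before classification and the padding is trimmed from the output.
#'
#' @param model A trained `stgcn` object.
#' @param seq A [skeleton_sequence].
#' @return An [action_weights] matrix (rows sum to 1).
#' @export
stgcn_classify <- function(model, seq) {
  T_ <- n_frames(seq)
  A0 <- stgcn_features(seq)
  rf <- model$kernel
  if (T_ < rf) {  # replicate-edge pad to the receptive field
    pad <- rf - T_
    left <- pad %/% 2L
    idx <- c(rep(1L, left), seq_len(T_), rep(T_, pad - left))
    A0 <- A0[, , idx, drop = FALSE]
  }
  cache <- stgcn_forward(model$par, A0, model$Adj)
  Pr <- .softmax_rows(cache$logits)
  if (T_ < rf) {
    left <- (rf - T_) %/% 2L
    Pr <- Pr[left + seq_len(T_), , drop = FALSE]
  }
  colnames(Pr) <- model$classes
  action_weights(Pr, frame_index = seq$frame_index)
}
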