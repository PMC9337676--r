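# Small 1D convolutional network for R-peak offset regression.
#
# Architecture (input: one z-scored 3-s BCG window, L0 = round(3 * fs)):
#   conv(16 filters, kernel 11) -> ReLU -> max-pool 4
#   conv(32, kernel 7)          -> ReLU -> max-pool 4
#   conv(32, kernel 5)          -> ReLU -> global average
#   dense 64 -> ReLU -> dense 1 -> scale * tanh   (offset in seconds)
#
# Activations are stored channel-major as (C, L, B) vectors (channel
# fastest), so a convolution is one BLAS matmul on an im2col expansion
# and its (F, L_out * B) output is already in layout — no transposes in
# the hot path. The im2col gather, the gradient scatter and max-pooling
# run in compiled code (src/cnn_ops.cpp). Training is plain minibatch SGD
# with a fixed step and a seeded shuffle, so runs are bit-reproducible on
# a given BLAS.

.cnn_cache <- new.env(parent = emptyenv())

# global average over L of a (C, L, B) layout via a cached selector matrix
gap_geom <- function(C, L) {
  key <- paste("gap", C, L, sep = "x")
  A <- .cnn_cache[[key]]
  if (is.null(A)) {
    A <- matrix(0, C, C * L)
    for (c in 1:C) A[c, c + (0:(L - 1L)) * C] <- 1 / L
    .cnn_cache[[key]] <- A
  }
  A
}

#' Training stopping criteria
#'
#' Training stops when the epoch mean loss drops below `error_tol` and the
#' absolute epoch-to-epoch improvement falls below `margin_tol`, or after
#' `max_epochs`.
#'
#' @param error_tol epoch mean-squared-error tolerance (seconds^2),
#'   default 1e-4.
#' @param margin_tol absolute loss-improvement tolerance, default 1e-4.
#' @param max_epochs hard epoch cap, default 500.
#' @return a `stopping_criteria` list.
#' @export
stopping_criteria <- function(error_tol = 1e-4, margin_tol = 1e-4,
                              max_epochs = 500L) {
  if (error_tol <= 0 || margin_tol <= 0) {
    stop("tolerances must be > 0", call. = FALSE)
  }
  structure(list(error_tol = error_tol, margin_tol = margin_tol,
                 max_epochs = as.integer(max_epochs)),
            class = "stopping_criteria")
}

cnn_init <- function(input_len, scale = 1.5, seed = 1L) {
  with_seed(seed, {
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nc)),
                                  nr, nc)
    l1 <- input_len - 11L + 1L
    p1 <- l1 %/% 4L
    l2 <- p1 - 7L + 1L
    p2 <- l2 %/% 4L
    l3 <- p2 - 5L + 1L
    list(W1 = he(16L, 1L * 11L), b1 = numeric(16L),
         W2 = he(32L, 16L * 7L), b2 = numeric(32L),
         W3 = he(32L, 32L * 5L), b3 = numeric(32L),
         W4 = he(64L, 32L), b4 = numeric(64L),
         # zero-init output layer: the head starts at offset 0, far from
         # the tanh saturation region, which keeps plain SGD stable
         W5 = matrix(0, 1L, 64L), b5 = numeric(1L),
         input_len = as.integer(input_len), scale = scale,
         dims = c(l1 = l1, p1 = p1, l2 = l2, p2 = p2, l3 = l3))
  })
}

# forward pass; X is (n_windows x input_len); returns predictions (seconds)
# and, if `keep` is TRUE, the layer caches for backprop
cnn_fwd <- function(par, X, keep = FALSE) {
  B <- nrow(X)
  L0 <- ncol(X)
  d <- as.integer(par$dims)   # l1, p1, l2, p2, l3
  A <- gap_geom(32L, d[5])

  x0 <- as.numeric(t(X))                    # (C=1, L0, B) layout
  c1 <- .conv_relu_fwd(x0, par$W1, par$b1, 1L, L0, B, 11L, TRUE)
  p1 <- .pool4_fwd(c1$out, 16L, d[1], B)
  c2 <- .conv_relu_fwd(p1$out, par$W2, par$b2, 16L, d[2], B, 7L, TRUE)
  p2 <- .pool4_fwd(c2$out, 32L, d[3], B)
  c3 <- .conv_relu_fwd(p2$out, par$W3, par$b3, 32L, d[4], B, 5L, TRUE)
  G <- A %*% matrix(c3$out, ncol = B)       # (32, B)
  Hpre <- par$W4 %*% G + par$b4
  H <- pmax(Hpre, 0)
  z <- as.numeric(par$W5 %*% H + par$b5)
  th <- tanh(z)
  pred <- par$scale * th
  if (!keep) return(pred)
  list(pred = pred, th = th, H = H, Hpre = Hpre, G = G, B = B, A = A,
       c1 = c1, p1 = p1, c2 = c2, p2 = p2, c3 = c3)
}

# backward pass for MSE loss; returns gradient list matching `par`
cnn_bwd <- function(par, X, y, fw) {
  B <- fw$B
  d <- as.integer(par$dims)
  dpred <- 2 * (fw$pred - y) / B
  dz <- dpred * par$scale * (1 - fw$th^2)
  dW5 <- matrix(dz, 1L) %*% t(fw$H)
  db5 <- sum(dz)
  dH <- crossprod(par$W5, matrix(dz, 1L)) * (fw$Hpre > 0)
  dW4 <- tcrossprod(dH, fw$G)
  db4 <- rowSums(dH)
  dG <- crossprod(par$W4, dH)               # (32, B)
  dr3 <- as.numeric(crossprod(fw$A, dG))    # (32*l3, B) layout
  b3g <- .conv_relu_bwd(dr3, fw$c3$out, fw$c3$Xcol, par$W3,
                        32L, d[4], B, 5L, TRUE, TRUE)
  dp2 <- .pool4_bwd(b3g$dX, fw$p2$amax, 32L * d[3] * B)
  b2g <- .conv_relu_bwd(dp2, fw$c2$out, fw$c2$Xcol, par$W2,
                        16L, d[2], B, 7L, TRUE, TRUE)
  dp1 <- .pool4_bwd(b2g$dX, fw$p1$amax, 16L * d[1] * B)
  b1g <- .conv_relu_bwd(dp1, fw$c1$out, fw$c1$Xcol, par$W1,
                        1L, par$input_len, B, 11L, TRUE, FALSE)
  list(W1 = b1g$dW, b1 = as.numeric(b1g$db), W2 = b2g$dW,
       b2 = as.numeric(b2g$db), W3 = b3g$dW, b3 = as.numeric(b3g$db),
       W4 = dW4, b4 = db4, W5 = dW5, b5 = db5)
}

cnn_loss <- function(par, X, y) mean((cnn_fwd(par, X) - y)^2)

# forward-only inference in fixed-size chunks (last chunk zero-padded) so
# the per-geometry index cache stays bounded
cnn_predict_batched <- function(par, X, chunk = 256L) {
  n <- nrow(X)
  if (n <= chunk) {
    pad <- chunk - n
    Xp <- if (pad > 0) rbind(X, matrix(0, pad, ncol(X))) else X
    return(cnn_fwd(par, Xp)[seq_len(n)])
  }
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- cnn_predict_batched(par, X[s:e, , drop = FALSE], chunk)
  }
  out
}

# plain minibatch SGD with fixed step and seeded shuffling; the data is
# processed in fixed-size minibatches (a short trailing batch is folded
# into the previous one so layer geometries stay cacheable)
cnn_train_loop <- function(par, X, y, criteria, lr = 0.05, batch_size = 64L,
                           seed = 1L) {
  n <- nrow(X)
  batch_size <- min(batch_size, n)
  wnames <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4", "W5", "b5")
  loss_log <- numeric(criteria$max_epochs)
  prev <- Inf
  n_ep <- 0L
  starts <- seq(1L, n, by = batch_size)
  ends <- pmin(starts + batch_size - 1L, n)
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1L)
      < batch_size / 2) {
    starts <- starts[-length(starts)]
    ends[length(starts)] <- n
    ends <- ends[seq_along(starts)]
  }
  with_seed(seed, {
    for (epoch in seq_len(criteria$max_epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (bi in seq_along(starts)) {
        sel <- ord[starts[bi]:ends[bi]]
        Xb <- X[sel, , drop = FALSE]
        yb <- y[sel]
        fw <- cnn_fwd(par, Xb, keep = TRUE)
        gr <- cnn_bwd(par, Xb, yb, fw)
        for (w in wnames) par[[w]] <- par[[w]] - lr * gr[[w]]
        tot <- tot + sum((fw$pred - yb)^2)
      }
      loss <- tot / n
      n_ep <- epoch
      loss_log[epoch] <- loss
      if (loss < criteria$error_tol && abs(prev - loss) < criteria$margin_tol) {
        break
      }
      prev <- loss
    }
  })
  list(par = par,
       log = data.frame(epoch = seq_len(n_ep), loss = loss_log[seq_len(n_ep)]))
}

#' Save or load a trained peak model as structured text
#'
#' Weights are serialized to JSON with full double precision, so the round
#' trip reproduces predictions exactly.
#'
#' @param model a `peak_model` from [train_peak_model()].
#' @param path file path (`.json`).
#' @return `save_peak_model` invisibly returns `path`; `load_peak_model`
#'   the restored model.
#' @export
save_peak_model <- function(model, path) {
  stopifnot(inherits(model, "peak_model"))
  ser <- model
  class(ser) <- NULL
  ser$par$dims <- as.list(ser$par$dims)
  # weights as %.17g strings: 17 significant digits round-trip IEEE
  # doubles exactly, which plain JSON numbers do not guarantee
  for (w in c("W1", "W2", "W3", "W4", "W5")) {
    v <- ser$par[[w]]
    ser$par[[w]] <- list(nrow = nrow(v),
                         values = sprintf("%.17g", as.numeric(v)))
  }
  for (b in c("b1", "b2", "b3", "b4", "b5")) {
    ser$par[[b]] <- sprintf("%.17g", ser$par[[b]])
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_peak_model
#' @export
load_peak_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- raw$par
  for (w in c("W1", "W2", "W3", "W4", "W5")) {
    par[[w]] <- matrix(as.numeric(par[[w]]$values),
                       nrow = as.integer(par[[w]]$nrow))
  }
  for (b in c("b1", "b2", "b3", "b4", "b5")) par[[b]] <- as.numeric(par[[b]])
  par$dims <- unlist(par$dims)
  structure(list(par = par, fs = raw$fs, window_s = raw$window_s,
                 trained = isTRUE(raw$trained),
                 log = as.data.frame(raw$log), meta = raw$meta),
            class = "peak_model")
}

#' @export
print.peak_model <- function(x, ...) {
  cat(sprintf(
    "<peak_model> 1D CNN, input %d samples (%g s @ %g Hz), %s\n",
    x$par$input_len, x$window_s, x$fs,
    if (x$trained) sprintf("trained %d epochs, final loss %.3g",
                           nrow(x$log), x$log$loss[nrow(x$log)])
    else "untrained"))
  invisible(x)
}
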