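# Minimal multilayer-perceptron machinery: dense layers with tanh hidden
# activations and a linear output, reverse-mode gradients (backprop),
# forward-mode directional derivatives (for Jacobians), and Adam. All
# parameters are plain R matrices so the whole model is serialisable and
# bit-reproducible; matrix products go through BLAS.

#' Create a multilayer perceptron
#'
#' Dense network with tanh hidden units and a linear output layer. Weights
#' are Glorot-initialised from the current R random number stream.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @return an `mlp` object (lists of weight matrices `W` and bias vectors
#'   `b`).
#' @export
mlp_new <- function(sizes) {
  stopifnot(length(sizes) >= 2)
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    s <- sqrt(2 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0, s),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, sizes = as.integer(sizes)), class = "mlp")
}

#' Forward pass
#' @param net an `mlp`.
#' @param x input matrix, one row per sample (a vector is taken as one row).
#' @param keep_cache keep layer activations for [mlp_backward()].
#' @return list with `out` (n x d_out) and, if requested, `cache`.
#' @export
mlp_forward <- function(net, x, keep_cache = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (any(!is.finite(x))) stop("non-finite network input")
  nl <- length(net$W)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- x
  h <- x
  for (l in seq_len(nl)) {
    h <- sweep(h %*% net$W[[l]], 2L, net$b[[l]], `+`)
    if (l < nl) h <- tanh(h)
    acts[[l + 1L]] <- h
  }
  list(out = h, cache = if (keep_cache) acts)
}

#' Reverse-mode gradients
#'
#' Backpropagates `dout` (gradient of a scalar loss with respect to the
#' network output) through the cached forward pass.
#'
#' @param net an `mlp`.
#' @param cache activations from `mlp_forward(..., keep_cache = TRUE)`.
#' @param dout n x d_out gradient matrix.
#' @return list with `dW`, `db` (same shapes as the parameters) and `dx`
#'   (gradient with respect to the input).
#' @export
mlp_backward <- function(net, cache, dout) {
  nl <- length(net$W)
  dW <- vector("list", nl); db <- vector("list", nl)
  delta <- dout
  for (l in rev(seq_len(nl))) {
    if (l < nl) delta <- delta * (1 - cache[[l + 1L]]^2)  # through tanh
    dW[[l]] <- crossprod(cache[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- tcrossprod(delta, net$W[[l]])
  }
  list(dW = dW, db = db, dx = delta)
}

#' Forward-mode directional derivatives
#'
#' Propagates `k` tangent directions through the network at a single input
#' point, giving `J %*% t(V)` columns without finite differences. Used for
#' exact Jacobians with few inputs (e.g. per-property attribution).
#'
#' @param net an `mlp`.
#' @param x single input (vector or 1-row matrix).
#' @param v k x d_in matrix of tangent directions (default: identity, full
#'   Jacobian).
#' @return list with `out` (1 x d_out) and `jvp` (k x d_out matrix of
#'   directional derivatives).
#' @export
mlp_jvp <- function(net, x, v = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  d_in <- ncol(x)
  if (is.null(v)) v <- diag(d_in)
  nl <- length(net$W)
  h <- x
  t_h <- v
  for (l in seq_len(nl)) {
    h <- sweep(h %*% net$W[[l]], 2L, net$b[[l]], `+`)
    t_h <- t_h %*% net$W[[l]]
    if (l < nl) {
      h <- tanh(h)
      t_h <- sweep(t_h, 2L, as.numeric(1 - h^2), `*`)
    }
  }
  list(out = h, jvp = t_h)
}

# --- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

# params/grads: list(W = list(...), b = list(...)); returns updated params
# and state.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (grp in names(params)) {
    for (l in seq_along(params[[grp]])) {
      g <- grads[[grp]][[l]]
      state$m[[grp]][[l]] <- beta1 * state$m[[grp]][[l]] + (1 - beta1) * g
      state$v[[grp]][[l]] <- beta2 * state$v[[grp]][[l]] + (1 - beta2) * g^2
      mhat <- state$m[[grp]][[l]] / bc1
      vhat <- state$v[[grp]][[l]] / bc2
      params[[grp]][[l]] <- params[[grp]][[l]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
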