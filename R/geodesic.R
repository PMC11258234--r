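# Geodesic interpolation between two points of the property space: optimise
# a discretised path whose image under the (property-)encoder has minimal
# squared length in latent space, with a small property-space regulariser.
# The encoder is either the trained model's property encoder or any object
# providing the same two primitives (a linear encoder is used in tests,
# where the geodesic has a closed form: the straight line).

# The optimizer works in the encoder's input coordinates ("work"
# coordinates): z-scored properties for a trained model (raw property units
# differ by orders of magnitude, which would let the path regulariser drown
# the latent term), identity for plain test encoders.

path_to_work <- function(encoder, y) UseMethod("path_to_work")
path_from_work <- function(encoder, yw) UseMethod("path_from_work")

#' @export
path_to_work.default <- function(encoder, y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  y
}
#' @export
path_from_work.default <- function(encoder, yw) yw
#' @export
path_to_work.inverse_model <- function(encoder, y) std_props(encoder, y)
#' @export
path_from_work.inverse_model <- function(encoder, yw) unstd_props(encoder, yw)

# mean latent image of path points in work coordinates (rows)
encode_path <- function(encoder, y) UseMethod("encode_path")

#' @export
encode_path.inverse_model <- function(encoder, yw) {
  out <- mlp_forward(encoder$prop, yw)$out
  out[, seq_len(encoder$latent), drop = FALSE]
}

#' @export
encode_path.linear_encoder <- function(encoder, y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  sweep(y %*% encoder$W, 2L, encoder$b, `+`)
}

# vector-Jacobian product: gradient wrt work coords of sum(dz * z(y))
encode_path_vjp <- function(encoder, y, dz) UseMethod("encode_path_vjp")

#' @export
encode_path_vjp.inverse_model <- function(encoder, yw, dz) {
  f <- mlp_forward(encoder$prop, yw, keep_cache = TRUE)
  dout <- cbind(dz, matrix(0, nrow(dz), encoder$latent))  # mean head only
  mlp_backward(encoder$prop, f$cache, dout)$dx
}

#' @export
encode_path_vjp.linear_encoder <- function(encoder, y, dz)
  tcrossprod(dz, encoder$W)

#' A fixed linear encoder (mainly for validation)
#'
#' Encodes `z = y %*% W + b`. Under a linear encoder the geodesic between two
#' property points is exactly the straight line, which gives the optimizer a
#' closed-form check.
#'
#' @param W d_y x latent weight matrix.
#' @param b latent offset (default zero).
#' @return a `linear_encoder`.
#' @export
linear_encoder <- function(W, b = NULL) {
  W <- as.matrix(W)
  if (is.null(b)) b <- numeric(ncol(W))
  structure(list(W = W, b = b), class = "linear_encoder")
}

#' Initialise a linear interpolation path in property space
#'
#' `N - 1` interior points linearly interpolated between the endpoint
#' property vectors (`y_i = y_0 + (i/N) (y_N - y_0)`), with the latent image
#' and, for a full model, the decoded structures attached.
#'
#' @param encoder an `inverse_model` or `linear_encoder`.
#' @param y_start,y_end raw endpoint property vectors.
#' @param n_steps number of segments `N` (the path has `N + 1` points);
#'   at least 2.
#' @return a `geodesic_path`: `y` ((N+1) x d matrix of raw property
#'   points), `y_work` (the same path in the encoder's input coordinates,
#'   where the optimisation happens), `z`, `structures` (list or NULL),
#'   `loss_history`, `converged`.
#' @export
init_linear_path <- function(encoder, y_start, y_end, n_steps = 6L) {
  stopifnot(n_steps >= 2L)
  frac <- seq(0, 1, length.out = n_steps + 1L)
  y <- outer(1 - frac, as.numeric(y_start)) + outer(frac, as.numeric(y_end))
  yw <- path_to_work(encoder, y)
  path <- structure(list(y = y, y_work = yw, z = encode_path(encoder, yw),
                         structures = NULL, loss_history = numeric(0),
                         converged = FALSE, n_steps = n_steps),
                    class = "geodesic_path")
  decode_path_structures(encoder, path)
}

decode_path_structures <- function(encoder, path) {
  if (inherits(encoder, "inverse_model") && !is.null(encoder$layout)) {
    path$structures <- lapply(seq_len(nrow(path$y)), function(i)
      tryCatch(property_to_structure(encoder, path$y[i, ])$molecule,
               error = function(e) NULL))
  }
  path
}

#' @export
print.geodesic_path <- function(x, ...) {
  cat("<geodesic_path>", nrow(x$y) - 1L, "segments;",
      if (x$converged) "converged" else "not converged",
      if (length(x$loss_history))
        paste0("; final loss ", signif(utils::tail(x$loss_history, 1L), 6)),
      "\n")
  invisible(x)
}

#' Geodesic path loss and its gradient
#'
#' `L = sum ||z_{i+1} - z_i||^2 + eps_reg * sum ||y_{i+1} - y_i||^2`, with
#' `z_i` the latent image of `y_i`. The gradient is taken with respect to
#' the property points by backpropagation through the encoder; endpoint
#' gradients are zeroed (the endpoints are data).
#'
#' @param encoder an `inverse_model` or `linear_encoder`.
#' @param y path matrix in the encoder's input coordinates, one row per
#'   point (z-scored properties for a trained model -- the `y_work` field of
#'   a path; identical to the property points for encoders without
#'   standardization).
#' @param eps_reg property-space regularisation weight (`<< 1`).
#' @return list with `loss` and `grad` (same shape as `y`, endpoint rows
#'   zero).
#' @export
geodesic_loss <- function(encoder, y, eps_reg = 1e-2) {
  z <- encode_path(encoder, y)
  n <- nrow(y)
  dzseg <- z[-1L, , drop = FALSE] - z[-n, , drop = FALSE]
  dyseg <- y[-1L, , drop = FALSE] - y[-n, , drop = FALSE]
  loss <- sum(dzseg^2) + eps_reg * sum(dyseg^2)
  if (!is.finite(loss)) stop("non-finite geodesic loss")
  # d loss / d z_i = 2 (z_i - z_{i-1}) - 2 (z_{i+1} - z_i)
  dz <- rbind(-2 * dzseg[1L, , drop = FALSE], matrix(0, n - 2L, ncol(z)),
              2 * dzseg[n - 1L, , drop = FALSE])
  if (n > 2L)
    dz[2:(n - 1L), ] <- 2 * (dzseg[seq_len(n - 2L), , drop = FALSE] -
                               dzseg[2:(n - 1L), , drop = FALSE])
  grad <- encode_path_vjp(encoder, y, dz)
  dyg <- rbind(-2 * dyseg[1L, , drop = FALSE], matrix(0, n - 2L, ncol(y)),
               2 * dyseg[n - 1L, , drop = FALSE])
  if (n > 2L)
    dyg[2:(n - 1L), ] <- 2 * (dyseg[seq_len(n - 2L), , drop = FALSE] -
                                dyseg[2:(n - 1L), , drop = FALSE])
  grad <- grad + eps_reg * dyg
  grad[c(1L, n), ] <- 0
  list(loss = loss, grad = grad)
}

#' Optimise a geodesic path
#'
#' Gradient descent with backtracking line search on the interior property
#' points (endpoints fixed). Accepted steps never increase the loss;
#' optimisation stops when the interior gradient norm drops below `tol` or
#' after `max_iter` iterations (the path is then flagged unconverged).
#'
#' @param encoder an `inverse_model` or `linear_encoder`.
#' @param path a `geodesic_path` from [init_linear_path()].
#' @param eps_reg property-space regularisation weight.
#' @param step initial step size.
#' @param tol gradient-norm convergence threshold.
#' @param max_iter iteration budget.
#' @return the optimised `geodesic_path` with `loss_history`, `converged`,
#'   updated `z`, and re-decoded `structures`.
#' @export
optimize_path <- function(encoder, path, eps_reg = 1e-2, step = 1e-2,
                          tol = 1e-4, max_iter = 5000L) {
  y <- if (!is.null(path$y_work)) path$y_work else path_to_work(encoder, path$y)
  n <- nrow(y)
  cur <- geodesic_loss(encoder, y, eps_reg)
  history <- cur$loss
  converged <- FALSE
  s <- step
  y_prev <- NULL
  g_prev <- NULL
  for (it in seq_len(max_iter)) {
    gnorm <- sqrt(sum(cur$grad^2))
    if (gnorm < tol) { converged <- TRUE; break }
    # Barzilai-Borwein spectral step (adapts to the local curvature; vital
    # on ill-conditioned paths), safeguarded by monotone backtracking
    if (!is.null(y_prev)) {
      dy <- y - y_prev
      dg <- cur$grad - g_prev
      s_bb <- sum(dy * dg) / sum(dg * dg)
      if (is.finite(s_bb) && s_bb > 0) s <- s_bb
    }
    accepted <- FALSE
    s_try <- s
    while (s_try > 1e-16) {
      cand <- y - s_try * cur$grad
      cand[c(1L, n), ] <- y[c(1L, n), ]   # endpoints never move
      new <- geodesic_loss(encoder, cand, eps_reg)
      # accept any non-increase up to rounding: near the optimum the true
      # decrease per step falls below the loss's floating-point resolution,
      # but the iterates (driven by the exact gradient) still progress
      if (new$loss <= cur$loss + 1e-12 * max(1, abs(cur$loss))) {
        y_prev <- y; g_prev <- cur$grad
        y <- cand; cur <- new; accepted <- TRUE
        break
      }
      s_try <- s_try / 2
    }
    if (!accepted) break  # no descent direction at machine step size
    history <- c(history, cur$loss)
  }
  path$y_work <- y
  raw <- path_from_work(encoder, y)
  raw[c(1L, n), ] <- path$y[c(1L, n), ]  # endpoints are data, bit-exact
  path$y <- raw
  path$z <- encode_path(encoder, y)
  path$loss_history <- history
  path$converged <- converged
  decode_path_structures(encoder, path)
}

#' Export a path as an XYZ sequence
#'
#' One XYZ file per path point, indexed `i = 0 .. N`, suitable as initial
#' guesses for an external transition-path refinement (e.g. a nudged elastic
#' band engine).
#'
#' @param path a `geodesic_path` with decoded structures.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of file paths, invisibly.
#' @export
write_path_xyz <- function(path, dir, prefix = "step") {
  if (is.null(path$structures)) stop("path has no decoded structures")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(path$structures)) {
    mol <- path$structures[[i]]
    if (is.null(mol)) next
    f <- file.path(dir, sprintf("%s_%d.xyz", prefix, i - 1L))
    write_xyz(mol, f, comment = sprintf("path point %d", i - 1L))
    files <- c(files, f)
  }
  invisible(files)
}
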