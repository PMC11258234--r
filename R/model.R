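#' Joint structure/property latent model
#'
#' The inverse-mapping model couples three networks over a shared latent
#' space of dimension `latent`:
#' a structure encoder `q_phi(z | x)` over flattened padded Coulomb-matrix
#' vectors `x`, a decoder `p_theta(x | z)`, and a property encoder
#' `p_psi(z | y)` over the property vectors `y`. Encoders output the mean and
#' log-variance of a diagonal Gaussian; the decoder and the property-encoder
#' likelihoods are diagonal Gaussians with fixed unit variance, so their
#' negative log-likelihoods reduce to squared errors plus constants.
#'
#' Training minimises
#' `beta * D_KL[q_phi(z|x) || N(0, I)] - E[log p_theta(x|z)] -
#'  tau * E[log p_psi(z|y)]`
#' with `z` drawn by the reparameterization trick; with `tau = 0` and
#' `beta = 1` this is exactly the standard evidence lower bound. At inference
#' the latent is the property-encoder mean (the maximum-likelihood latent for
#' a property vector), never sampled.
#'
#' @param d_x length of the Coulomb-matrix vector.
#' @param d_y number of properties.
#' @param latent latent dimension.
#' @param enc_hidden,dec_hidden,prop_hidden hidden-layer widths of the three
#'   networks.
#' @param beta weight of the KL regularizer.
#' @param tau weight of the property-likelihood term.
#' @param layout optional [cm_layout] carried along for decoding.
#' @param prop_set property names, in model order.
#' @return an `inverse_model` (untrained; standardization statistics are identity
#'   until fitted).
#' @export
inverse_model <- function(d_x, d_y, latent = 16L,
                      enc_hidden = c(128L, 128L), dec_hidden = c(128L, 128L),
                      prop_hidden = c(64L, 64L), beta = 4e-3, tau = 1.0,
                      layout = NULL, prop_set = NULL) {
  structure(list(
    enc = mlp_new(c(d_x, enc_hidden, 2L * latent)),
    dec = mlp_new(c(latent, dec_hidden, d_x)),
    prop = mlp_new(c(d_y, prop_hidden, 2L * latent)),
    d_x = as.integer(d_x), d_y = as.integer(d_y), latent = as.integer(latent),
    beta = beta, tau = tau, layout = layout,
    prop_set = prop_set,
    # fixed per-entry reconstruction precision (heteroscedastic Gaussian
    # likelihood); a weight w_j corresponds to variance 1/w_j on entry j
    recon_weight = rep(1, d_x),
    scalers = list(cm_scale = 1,
                   prop_center = numeric(d_y), prop_scale = rep(1, d_y))
  ), class = "inverse_model")
}

#' @export
print.inverse_model <- function(x, ...) {
  cat("<inverse_model> x-dim", x$d_x, "| properties", x$d_y, "| latent",
      x$latent, "| beta", x$beta, "| tau", x$tau,
      if (isTRUE(x$trained)) "| trained" else "| untrained", "\n")
  invisible(x)
}

# standardisation helpers -----------------------------------------------------

std_cm <- function(model, x) x / model$scalers$cm_scale
unstd_cm <- function(model, x) x * model$scalers$cm_scale

std_props <- function(model, y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  sweep(sweep(y, 2L, model$scalers$prop_center), 2L,
        model$scalers$prop_scale, `/`)
}
unstd_props <- function(model, y) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  sweep(sweep(y, 2L, model$scalers$prop_scale, `*`), 2L,
        model$scalers$prop_center, `+`)
}

# Encoder heads emit (mu, s); the log-variance is the smooth bound
# logvar = B * tanh(s / B), keeping sigma in [exp(-B/2), exp(B/2)] and the
# likelihood terms bounded (prevents the classic sigma-collapse divergence).
# `dlv` is d logvar / d s, needed by the backward pass.
split_gauss <- function(out, latent, bound = 10) {
  mu <- out[, seq_len(latent), drop = FALSE]
  s <- out[, latent + seq_len(latent), drop = FALSE]
  logvar <- bound * tanh(s / bound)
  list(mu = mu, sigma = exp(0.5 * logvar), logvar = logvar,
       dlv = 1 - (logvar / bound)^2)
}

#' Encode structures into the latent Gaussian
#'
#' @param model a trained or untrained `inverse_model`.
#' @param x raw Coulomb-matrix vectors (one row per molecule); standardized
#'   internally with the model statistics.
#' @return list with matrices `mu`, `sigma` (strictly positive) and `logvar`.
#' @export
encode_structure <- function(model, x) {
  out <- mlp_forward(model$enc, std_cm(model, x))$out
  split_gauss(out, model$latent)
}

#' Encode property vectors into the latent Gaussian
#'
#' @param model an `inverse_model`.
#' @param y raw property vectors (one row per molecule, model property
#'   order); standardized internally.
#' @return list with matrices `mu`, `sigma`, `logvar`.
#' @export
encode_properties <- function(model, y) {
  out <- mlp_forward(model$prop, std_props(model, y))$out
  split_gauss(out, model$latent)
}

#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' Closed form `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param mu mean vector, or matrix with one row per sample.
#' @param sigma standard deviations (> 0), same shape.
#' @return nonnegative scalar (vector input) or per-row vector (matrix
#'   input).
#' @export
kl_divergence <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  term <- 0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma))
  if (is.null(dim(mu))) sum(term) else rowSums(term)
}

#' Random Coulomb-matrix mask
#'
#' Draws a binary vector `b` of Bernoulli(p) slot indicators and forms the
#' mask `M = 2 * outer(b, b)`; entries where the target matrix is zero
#' (padding) are then set to the leak value 0.1. Multiplying the per-entry
#' reconstruction loss by `M` trains the model to treat molecular fragments
#' independently while keeping a weak signal on the padding. The factor 2
#' restores the expected diagonal weight to 1 (off-diagonal entries keep
#' expectation `2 p^2 = 0.5`). Uses the current R random number stream.
#'
#' @param L matrix size.
#' @param target the target padded Coulomb matrix (its zero entries define
#'   the padding); `NULL` applies no leak.
#' @param p Bernoulli probability.
#' @param leak value placed on padding entries.
#' @return L x L mask matrix.
#' @export
make_mask <- function(L, target = NULL, p = 0.5, leak = 0.1) {
  b <- stats::rbinom(L, 1L, p)
  m <- 2 * outer(b, b)
  if (!is.null(target)) {
    tm <- if (inherits(target, "padded_cm")) target$matrix else target
    m[tm == 0] <- leak
  }
  m
}

# Gaussian NLL of x under N(mean, I), elementwise weights w (masking);
# returns per-sample values. Constant included so the all-ones mask equals
# the unmasked loss exactly.
weighted_gauss_nll <- function(x, mean, w = NULL) {
  se <- 0.5 * (x - mean)^2 + 0.5 * log(2 * pi)
  if (!is.null(w)) se <- se * w
  rowSums(se)
}

#' Joint training loss on a batch
#'
#' Evaluates (and optionally differentiates) the joint objective
#' `beta * KL + reconstruction NLL + tau * property NLL` on a batch, using
#' the reparameterization trick `z = mu + sigma * eps`. All inputs are raw;
#' standardization is internal.
#'
#' @param model an `inverse_model`.
#' @param x raw Coulomb-matrix vectors (n x d_x).
#' @param y raw property vectors (n x d_y).
#' @param eps reparameterization noise (n x latent); drawn from the current
#'   RNG when `NULL`. Pass zeros for a deterministic evaluation.
#' @param mask_w optional n x d_x matrix of per-entry loss weights in vector
#'   form (see [mask_to_weights()]); replaces the plain reconstruction term.
#' @param grads also compute parameter gradients (used by [fit_inverse_model()]).
#' @return list with `total`, `kl`, `recon`, `prop_nll` (batch means) and,
#'   when `grads = TRUE`, gradient lists for the three networks.
#' @export
joint_loss <- function(model, x, y, eps = NULL, mask_w = NULL, grads = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  n <- nrow(x)
  stopifnot(nrow(y) == n, ncol(x) == model$d_x, ncol(y) == model$d_y)
  xs <- std_cm(model, x)
  ys <- std_props(model, y)
  if (is.null(eps))
    eps <- matrix(stats::rnorm(n * model$latent), n, model$latent)
  stopifnot(nrow(eps) == n, ncol(eps) == model$latent)
  if (!is.null(mask_w)) stopifnot(nrow(mask_w) == n, ncol(mask_w) == model$d_x)

  rw <- model$recon_weight
  if (!is.null(rw) && any(rw != 1)) {
    rwm <- matrix(rw, n, model$d_x, byrow = TRUE)
    mask_w <- if (is.null(mask_w)) rwm else mask_w * rwm
  }

  fe <- mlp_forward(model$enc, xs, keep_cache = grads)
  ge <- split_gauss(fe$out, model$latent)
  z <- ge$mu + ge$sigma * eps
  fd <- mlp_forward(model$dec, z, keep_cache = grads)
  fp <- mlp_forward(model$prop, ys, keep_cache = grads)
  gp <- split_gauss(fp$out, model$latent)

  kl <- mean(kl_divergence(ge$mu, ge$sigma))
  recon <- mean(weighted_gauss_nll(xs, fd$out, mask_w))
  # fixed unit-variance likelihood for p_psi: NLL is a squared error + const
  prop_nll <- mean(rowSums(0.5 * ((z - gp$mu)^2 + log(2 * pi))))
  out <- list(total = model$beta * kl + recon + model$tau * prop_nll,
              kl = kl, recon = recon, prop_nll = prop_nll)
  if (!grads) return(out)

  # reconstruction -> decoder -> z
  dxhat <- (fd$out - xs) / n
  if (!is.null(mask_w)) dxhat <- dxhat * mask_w
  bd <- mlp_backward(model$dec, fd$cache, dxhat)
  dz <- bd$dx
  # property NLL -> psi parameters and z (unit variance: plain residual)
  r <- z - gp$mu
  dz <- dz + model$tau * r / n
  dmu_psi <- -model$tau * r / n
  bp <- mlp_backward(model$prop, fp$cache,
                     cbind(dmu_psi, matrix(0, n, model$latent)))
  # z = mu + exp(0.5 lv) * eps, plus KL direct terms
  dmu_phi <- dz + model$beta * ge$mu / n
  dlv_phi <- dz * eps * 0.5 * ge$sigma +
    model$beta * 0.5 * (ge$sigma^2 - 1) / n
  be <- mlp_backward(model$enc, fe$cache,
                     cbind(dmu_phi, dlv_phi * ge$dlv))

  out$grads <- list(enc = list(W = be$dW, b = be$db),
                    dec = list(W = bd$dW, b = bd$db),
                    prop = list(W = bp$dW, b = bp$db))
  out
}

#' Convert full Coulomb-matrix masks to vector-form loss weights
#'
#' The network exchanges the upper triangle of the padded matrix, so an
#' `L x L` mask is reduced to the matching weight vector.
#'
#' @param masks list of L x L mask matrices (one per sample).
#' @return n x (L(L+1)/2) weight matrix.
#' @export
mask_to_weights <- function(masks) {
  t(vapply(masks, function(m) m[upper.tri(m, diag = TRUE)],
           numeric(nrow(masks[[1L]]) * (nrow(masks[[1L]]) + 1) / 2)))
}

#' Masked reconstruction loss
#'
#' The masked replacement of the reconstruction term: each per-entry
#' negative log-likelihood is multiplied by its mask value before summing.
#'
#' @param model an `inverse_model`.
#' @param x raw Coulomb-matrix vectors.
#' @param z latent points to decode (n x latent).
#' @param masks list of L x L masks from [make_mask()].
#' @return batch-mean masked reconstruction loss.
#' @export
masked_reconstruction_loss <- function(model, x, z, masks) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  w <- mask_to_weights(masks)
  stopifnot(ncol(w) == model$d_x)
  xs <- std_cm(model, x)
  xhat <- mlp_forward(model$dec, z)$out
  mean(weighted_gauss_nll(xs, xhat, w))
}

#' Train the joint model
#'
#' Adam on minibatches of the joint loss; properties are z-scored and
#' Coulomb-matrix vectors scaled by their global maximum, with statistics
#' from the training split only. Fully deterministic given `seed`.
#'
#' @param dataset a `molinverse_dataset` from [make_dataset()].
#' @param properties names of the properties to train on (default: all in
#'   the dataset).
#' @param epochs,batch,lr optimisation settings.
#' @param latent,enc_hidden,dec_hidden,prop_hidden architecture settings.
#' @param beta,tau loss weights.
#' @param masking enable random fragment masking of the reconstruction term.
#' @param diag_weight reconstruction precision on the diagonal entries of
#'   the padded matrix (the composition carriers): the likelihood is a
#'   heteroscedastic Gaussian with variance `1/diag_weight` on diagonal
#'   entries and 1 elsewhere, sharpening the occupied/empty readout.
#' @param prop_jitter property-noise augmentation: per minibatch, fresh
#'   Gaussian noise with standard deviation `prop_jitter * scale` (nominal
#'   per-property scale from [property_registry()], when the property names
#'   match it) is added to the property inputs. Regularises the property
#'   encoder against measurement-level noise; 0 disables.
#' @param seed RNG seed (initialisation, shuffling, reparameterization
#'   noise, masks, augmentation).
#' @param verbose print the epoch losses.
#' @return a trained `inverse_model` with a `history` data.frame attached
#'   (per-epoch train/validation loss components).
#' @export
fit_inverse_model <- function(dataset, properties = colnames(dataset$properties),
                      epochs = 1200L, batch = 64L, lr = 2e-3, latent = 16L,
                      enc_hidden = c(256L, 256L), dec_hidden = c(256L, 256L),
                      prop_hidden = c(128L, 128L), beta = 0.02, tau = 1.0,
                      masking = FALSE, diag_weight = 9, prop_jitter = 0.05,
                      seed = 1L, verbose = FALSE) {
  stopifnot(inherits(dataset, "molinverse_dataset"),
            all(properties %in% colnames(dataset$properties)))
  set.seed(seed)
  tr <- dataset$split == "train"
  va <- dataset$split == "val"
  x_tr <- dataset$cm[tr, , drop = FALSE]
  y_tr <- dataset$properties[tr, properties, drop = FALSE]
  x_va <- dataset$cm[va, , drop = FALSE]
  y_va <- dataset$properties[va, properties, drop = FALSE]

  model <- inverse_model(ncol(x_tr), length(properties), latent = latent,
                     enc_hidden = enc_hidden, dec_hidden = dec_hidden,
                     prop_hidden = prop_hidden, beta = beta, tau = tau,
                     layout = dataset$layout, prop_set = properties)
  L <- dataset$layout$size
  diag_idx <- cumsum(seq_len(L))  # (j, j) positions in the upper triangle
  model$recon_weight[diag_idx] <- diag_weight
  ctr <- colMeans(y_tr)
  scl <- apply(y_tr, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  model$scalers <- list(cm_scale = max(abs(x_tr)),
                        prop_center = ctr, prop_scale = scl)

  states <- list(enc = adam_state(list(W = model$enc$W, b = model$enc$b)),
                 dec = adam_state(list(W = model$dec$W, b = model$dec$b)),
                 prop = adam_state(list(W = model$prop$W, b = model$prop$b)))
  n_tr <- nrow(x_tr)
  hist <- vector("list", epochs)
  reg <- property_registry()
  jit_sd <- prop_jitter * ifelse(properties %in% reg$name,
                                 reg$scale[match(properties, reg$name)], 0)
  for (ep in seq_len(epochs)) {
    # step decay: full rate for the first half, then 0.3x, then 0.1x
    lr_ep <- lr * if (ep <= 0.5 * epochs) 1 else if (ep <= 0.8 * epochs) 0.3
                  else 0.1
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = batch)
    comp <- c(total = 0, kl = 0, recon = 0, prop_nll = 0)
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1L, n_tr)]
      mw <- NULL
      if (masking) {
        masks <- lapply(idx, function(i)
          make_mask(L, target = dataset$padded[[i]]))
        mw <- mask_to_weights(masks)
      }
      yb <- y_tr[idx, , drop = FALSE]
      if (any(jit_sd > 0))
        yb <- yb + matrix(stats::rnorm(length(yb), 0, rep(jit_sd,
                                                          each = nrow(yb))),
                          nrow(yb))
      jl <- joint_loss(model, x_tr[idx, , drop = FALSE], yb,
                       mask_w = mw, grads = TRUE)
      if (!is.finite(jl$total))
        stop("training diverged (non-finite loss) at epoch ", ep)
      for (nm in c("enc", "dec", "prop")) {
        up <- adam_step(list(W = model[[nm]]$W, b = model[[nm]]$b),
                        jl$grads[[nm]], states[[nm]], lr = lr_ep)
        model[[nm]]$W <- up$params$W
        model[[nm]]$b <- up$params$b
        states[[nm]] <- up$state
      }
      w <- length(idx) / n_tr
      comp <- comp + w * unlist(jl[c("total", "kl", "recon", "prop_nll")])
    }
    vl <- joint_loss(model, x_va, y_va)
    hist[[ep]] <- data.frame(epoch = ep, t(comp),
                             val_total = vl$total, val_kl = vl$kl,
                             val_recon = vl$recon, val_prop_nll = vl$prop_nll)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, comp["total"],
                      vl$total))
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Map a property vector to a structure
#'
#' The inference path of the inverse mapping: the latent is the
#' property-encoder mean (no sampling), decoded to a Coulomb-matrix vector,
#' un-standardized, symmetrized into a padded Coulomb matrix, and inverted
#' into a molecule (composition from the diagonal, geometry by classical
#' multidimensional scaling).
#'
#' @param model a trained `inverse_model` with a layout.
#' @param y raw property vector (model property order).
#' @param invert also invert the decoded matrix into a molecule (set to
#'   `FALSE` to inspect the raw decoded representation, e.g. for an
#'   untrained model whose output decodes to no molecule).
#' @return list with `padded` (the decoded `padded_cm`), `molecule` (NULL
#'   when `invert = FALSE`), and `z` (the latent point used).
#' @export
property_to_structure <- function(model, y, invert = TRUE) {
  stopifnot(!is.null(model$layout))
  z <- encode_properties(model, y)$mu
  xhat <- unstd_cm(model, mlp_forward(model$dec, z)$out)
  padded <- cm_from_vector(as.numeric(xhat), model$layout)
  list(padded = padded,
       molecule = if (invert) reconstruct_molecule(padded),
       z = as.numeric(z))
}

#' Latent self-consistency of a property vector
#'
#' `||Delta z|| = ||z - z_tilde||` where `z` is the property-encoder mean
#' and `z_tilde` the structure-encoder mean of the decoded (reconstructed)
#' Coulomb-matrix vector. Small values indicate that the generated structure
#' re-encodes to where the properties said it should live; the quantity is a
#' practical proxy for reconstruction quality and is used to filter
#' generated molecules.
#'
#' @param model a trained `inverse_model`.
#' @param y raw property vector.
#' @return nonnegative scalar.
#' @export
self_consistency_delta <- function(model, y) {
  z <- encode_properties(model, y)$mu
  xhat <- mlp_forward(model$dec, z)$out         # standardized units
  zt <- mlp_forward(model$enc, xhat)$out[, seq_len(model$latent), drop = FALSE]
  sqrt(sum((z - zt)^2))
}

#' Save / load a model
#'
#' Single-file archive (RDS) containing parameters, scalers, layout, and
#' training history.
#'
#' @param model an `inverse_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_inverse_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_inverse_model
#' @export
load_inverse_model <- function(path) readRDS(path)
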