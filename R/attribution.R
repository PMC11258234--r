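#' Jacobian of the decoded Coulomb matrix with respect to the properties
#'
#' Differentiates the inference path (property-encoder mean composed with the
#' decoder) by exact forward-mode propagation: `J[i, j] = d CM_i / d y_j`,
#' with the output taken as the decoded upper-triangle vector in raw Coulomb
#' units and the gradient taken with respect to standardized properties so
#' that entries are comparable across property units.
#'
#' @param model an `inverse_model`.
#' @param y raw property vector.
#' @param standardized_props differentiate with respect to z-scored
#'   properties (default) or raw property units.
#' @return d_x by d_y Jacobian matrix.
#' @export
property_jacobian <- function(model, y, standardized_props = TRUE) {
  ys <- std_props(model, y)
  jp <- mlp_jvp(model$prop, ys)              # d (mu, logvar) / d y_std
  jmu <- jp$jvp[, seq_len(model$latent), drop = FALSE]
  z <- jp$out[, seq_len(model$latent), drop = FALSE]
  jd <- mlp_jvp(model$dec, z, v = jmu)       # chain through the decoder
  jac <- t(jd$jvp) * model$scalers$cm_scale  # d_x x d_y, raw CM units
  if (!standardized_props)
    jac <- sweep(jac, 2L, model$scalers$prop_scale, `/`)
  jac
}

#' Select the best-reconstructed molecules
#'
#' The attribution subset: up to `count` molecules with correct composition
#' and RMSD at or under the cutoff, in ascending RMSD order (ties broken by
#' identifier for determinism). Warns when fewer qualify.
#'
#' @param reports a reconstruction report table (see
#'   [evaluate_reconstruction()]) with columns `id`, `composition_correct`,
#'   `rmsd`.
#' @param rmsd_cutoff maximum admissible RMSD in Angstrom.
#' @param count number of molecules wanted.
#' @return integer vector of `id` values.
#' @export
select_best_reconstructed <- function(reports, rmsd_cutoff = 0.2,
                                      count = 150L) {
  ok <- reports[reports$composition_correct & !is.na(reports$rmsd) &
                  reports$rmsd <= rmsd_cutoff, , drop = FALSE]
  ok <- ok[order(ok$rmsd, ok$id), , drop = FALSE]
  if (nrow(ok) < count)
    warning("only ", nrow(ok), " molecules qualify (requested ", count, ")")
  utils::head(ok$id, count)
}

#' Gradient attribution map over properties
#'
#' For each property `j`, the mean over the selected molecules of the
#' Euclidean norm of the Jacobian column `d CM / d y_j`: properties whose
#' perturbation moves the decoded structure most receive the largest
#' scores. Scores are nonnegative; with `normalize = TRUE` they are divided
#' by the maximum.
#'
#' @param model an `inverse_model`.
#' @param y_subset matrix of raw property vectors (one row per selected
#'   molecule).
#' @param normalize scale so the largest score is 1.
#' @return data.frame with `property`, `attribution`, and (if requested)
#'   `attribution_norm`, in model property order.
#' @export
attribution_map <- function(model, y_subset, normalize = TRUE) {
  if (is.null(dim(y_subset))) y_subset <- matrix(y_subset, nrow = 1L)
  if (nrow(y_subset) == 0L) stop("empty molecule subset")
  acc <- matrix(0, nrow(y_subset), model$d_y)
  for (k in seq_len(nrow(y_subset))) {
    jac <- property_jacobian(model, y_subset[k, ])
    acc[k, ] <- sqrt(colSums(jac^2))
  }
  a <- colMeans(acc)
  out <- data.frame(property = if (!is.null(model$prop_set)) model$prop_set
                    else paste0("p", seq_len(model$d_y)),
                    attribution = a, stringsAsFactors = FALSE)
  if (normalize) out$attribution_norm <- a / max(a)
  out
}

#' Principal-component projection of latent points
#'
#' Mean-centered PCA scores with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive), used to compare
#' the structure-encoder and property-encoder latent clouds.
#'
#' @param latents matrix of latent points (one row per molecule).
#' @param n_components number of components to keep.
#' @return list with `scores` (n x n_components), `explained` (variance
#'   fractions), and `rotation`.
#' @export
latent_projection <- function(latents, n_components = 2L) {
  latents <- as.matrix(latents)
  if (nrow(latents) < n_components)
    stop("need at least ", n_components, " samples")
  pc <- stats::prcomp(latents, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  if (k < n_components)
    warning("degenerate covariance: only ", k, " components available")
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]; if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  ev <- pc$sdev^2
  list(scores = scores, explained = ev[seq_len(k)] / sum(ev), rotation = rot)
}
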