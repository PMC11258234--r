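#' Gaussian-mixture model of the property space
#'
#' Fits full-covariance Gaussian mixtures to the (z-scored) property table by
#' EM over a grid of component counts and keeps the mixture preferred by the
#' Bayesian information criterion. Fitting is delegated to mclust
#' (`modelNames = "VVV"`, deterministic model-based hierarchical
#' initialisation), so repeated fits on the same data are identical; the
#' conditional-sampling machinery on top of the mixture is implemented here.
#'
#' @param properties numeric matrix of raw property values (one row per
#'   molecule, named columns).
#' @param k_grid candidate component counts.
#' @param seed recorded RNG seed (fitting itself is deterministic).
#' @param reg ridge added to a component covariance if it is numerically
#'   singular.
#' @return a `property_mixture`: weights `w`, means `mu` (d x K), covariances
#'   `sigma` (d x d x K), `bic` per candidate K, the chosen `K`, the property
#'   `names`, and the standardization `center`/`scale`.
#' @export
fit_mixture <- function(properties, k_grid = 1:9, seed = 1L, reg = 1e-6) {
  properties <- as.matrix(properties)
  stopifnot(nrow(properties) >= max(k_grid))
  set.seed(seed)
  ctr <- colMeans(properties)
  scl <- apply(properties, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  zs <- scale(properties, center = ctr, scale = scl)
  fit <- mclust::Mclust(zs, G = k_grid, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit)) stop("mixture fitting failed for every candidate K")
  K <- fit$G
  sig <- fit$parameters$variance$sigma
  for (k in seq_len(K)) {
    ev <- eigen(sig[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < reg) {
      sig[, , k] <- sig[, , k] + diag(reg, ncol(zs))
      message("regularized covariance of component ", k)
    }
  }
  structure(list(
    w = as.numeric(fit$parameters$pro),
    mu = matrix(fit$parameters$mean, ncol = K),
    sigma = sig, K = K,
    bic = fit$BIC[, "VVV"],
    names = colnames(properties),
    center = ctr, scale = scl
  ), class = "property_mixture")
}

#' @export
print.property_mixture <- function(x, ...) {
  cat("<property_mixture>", x$K, "components over", length(x$names),
      "properties\n")
  invisible(x)
}

# standardize target values for the targeted property indices
std_targets <- function(mixture, idx, values)
  (values - mixture$center[idx]) / mixture$scale[idx]

#' Most likely component for a property target
#'
#' The component maximising the marginal Gaussian density of the targeted
#' coordinates at the target values (marginalisation of a Gaussian is the
#' sub-vector/sub-matrix restriction). Component weights enter only through
#' an additive constant per component and a common rescaling leaves the
#' argmax unchanged.
#'
#' @param mixture a `property_mixture`.
#' @param targeted names (or indices) of the targeted properties.
#' @param values raw target values, same order.
#' @return component index.
#' @export
select_component <- function(mixture, targeted, values) {
  idx <- if (is.character(targeted)) match(targeted, mixture$names)
         else as.integer(targeted)
  if (anyNA(idx)) stop("unknown targeted property")
  vs <- std_targets(mixture, idx, values)
  ll <- vapply(seq_len(mixture$K), function(k) {
    mu <- mixture$mu[idx, k]
    sg <- mixture$sigma[idx, idx, k, drop = FALSE][, , 1L]
    sg <- matrix(sg, length(idx), length(idx))
    log(mixture$w[k]) + mvn_logpdf(vs, mu, sg)
  }, numeric(1))
  which.max(ll)
}

# log density of a multivariate normal at one point
mvn_logpdf <- function(x, mu, sigma) {
  d <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) chol(sigma + diag(1e-10, d)))
  q <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(q^2))
}

#' Conditional Gaussian of the non-targeted properties
#'
#' Standard conditioning of a multivariate Gaussian: with the coordinates
#' partitioned into targeted (`m`) and non-targeted (`n`) blocks,
#' `mu_tilde = mu_n + Sigma_nm Sigma_mm^-1 (m_bar - mu_m)` and
#' `Sigma_tilde = Sigma_nn - Sigma_nm Sigma_mm^-1 Sigma_mn` (independent of
#' the target values).
#'
#' @param mu mean vector of the component.
#' @param sigma covariance matrix of the component.
#' @param targeted indices of the targeted coordinates.
#' @param values conditioning values on the targeted coordinates.
#' @param reg ridge used if `Sigma_mm` is singular (with a warning).
#' @return list with `mu` (conditional mean of the non-targeted block),
#'   `sigma` (conditional covariance, symmetric PSD), and `free` (indices of
#'   the non-targeted coordinates).
#' @export
conditional_gaussian <- function(mu, sigma, targeted, values, reg = 1e-8) {
  m <- as.integer(targeted)
  n <- setdiff(seq_along(mu), m)
  smm <- sigma[m, m, drop = FALSE]
  if (inherits(tryCatch(chol(smm), error = identity), "error")) {
    warning("singular targeted covariance block; regularizing")
    smm <- smm + diag(reg, length(m))
  }
  snm <- sigma[n, m, drop = FALSE]
  gain <- snm %*% solve(smm)
  mu_t <- mu[n] + as.numeric(gain %*% (values - mu[m]))
  sg_t <- sigma[n, n, drop = FALSE] - gain %*% sigma[m, n, drop = FALSE]
  sg_t <- (sg_t + t(sg_t)) / 2
  list(mu = mu_t, sigma = sg_t, free = n)
}

#' Sample the conditional Gaussian and assemble full property vectors
#'
#' Draws the non-targeted properties and reinserts the fixed targets in
#' canonical coordinate order. Uses the current R random number stream.
#'
#' @param cond result of [conditional_gaussian()].
#' @param targeted indices of the targeted coordinates.
#' @param values the fixed target values.
#' @param n number of draws.
#' @param d total property dimension.
#' @return n x d matrix of property vectors.
#' @export
conditional_sample <- function(cond, targeted, values, n, d) {
  free <- cond$free
  if (max(abs(cond$sigma)) < 1e-14) {
    draws <- matrix(rep(cond$mu, each = n), n)
  } else {
    draws <- MASS::mvrnorm(n, cond$mu, cond$sigma)
    if (n == 1L) draws <- matrix(draws, 1L)
  }
  out <- matrix(0, n, d)
  out[, free] <- draws
  out[, as.integer(targeted)] <- matrix(rep(values, each = n), n)
  out
}

#' Targeted conditional generation of molecules
#'
#' The full generation pipeline: pick the mixture component most likely to
#' produce the target values, condition its Gaussian on them, sample full
#' property vectors, map each through the model to a structure, score each
#' sample with the latent self-consistency `||Delta z||`, apply a geometric
#' sanity screen (no heavy-atom pair closer than 0.8 Angstrom; contact graph
#' connected at 2.0 Angstrom), keep the samples whose `||Delta z||` falls in
#' the acceptance interval, and rank ascending by `||Delta z||`.
#'
#' @param model a trained `inverse_model`.
#' @param mixture a `property_mixture` over the same property set.
#' @param targeted names of the targeted properties.
#' @param values raw target values.
#' @param n_samples number of property draws.
#' @param interval `||Delta z||` acceptance interval (default the standard
#'   `[0, 0.4]` band; adjust per target when it proves too loose or too
#'   stringent).
#' @param screen apply the geometric sanity screen.
#' @return list with `results` (data.frame: sample id, `dz`, `kept`, screen
#'   flags, sampled properties) and `molecules` (the surviving molecules, in
#'   rank order), plus the chosen `component`.
#' @export
generate_targeted <- function(model, mixture, targeted, values,
                              n_samples = 50L, interval = c(0, 0.4),
                              screen = TRUE) {
  stopifnot(identical(model$prop_set, mixture$names))
  idx <- match(targeted, mixture$names)
  if (anyNA(idx)) stop("unknown targeted property")
  k <- select_component(mixture, idx, values)
  vs <- std_targets(mixture, idx, values)
  cond <- conditional_gaussian(mixture$mu[, k], mixture$sigma[, , k], idx, vs)
  ys <- conditional_sample(cond, idx, vs, n_samples, length(mixture$names))
  y_raw <- sweep(sweep(ys, 2L, mixture$scale, `*`), 2L, mixture$center, `+`)
  colnames(y_raw) <- mixture$names

  dz <- numeric(n_samples)
  valid <- logical(n_samples)
  screened <- logical(n_samples)
  mols <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    dz[s] <- self_consistency_delta(model, y_raw[s, ])
    res <- tryCatch(property_to_structure(model, y_raw[s, ]),
                    error = function(e) NULL)
    valid[s] <- !is.null(res)
    if (valid[s]) {
      mols[[s]] <- res$molecule
      screened[s] <- !screen || geometry_sane(res$molecule)
    }
  }
  kept <- valid & screened & dz >= interval[1] & dz <= interval[2]
  if (!any(kept))
    message("no sample survived the ||Delta z|| interval [",
            interval[1], ", ", interval[2],
            "]; it may be excessively stringent for this target")
  ord <- order(dz)
  results <- data.frame(sample = ord, dz = dz[ord], valid = valid[ord],
                        screened = screened[ord], kept = kept[ord])
  results <- cbind(results, y_raw[ord, , drop = FALSE])
  list(results = results, molecules = mols[ord[kept[ord]]],
       component = k)
}

# minimum-distance and connectivity screen for generated geometries
geometry_sane <- function(mol, min_dist = 0.8, contact = 2.0) {
  n <- length(mol$species)
  if (n == 1L) return(TRUE)
  d <- as.matrix(stats::dist(mol$coords))
  if (min(d[upper.tri(d)]) < min_dist) return(FALSE)
  # connected components of the contact graph by label propagation
  adj <- d <= contact & upper.tri(d) | t(d <= contact & upper.tri(d))
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[c(i, which(adj[i, ]))]),
                  numeric(1))
    if (all(new == comp)) break
    comp <- new
  }
  length(unique(comp)) == 1L
}

#' Relative target error of a generated molecule
#'
#' `epsilon = |y_calc - y_t| / delta_y * 100`, where `delta_y` is the extent
#' of the property's spectrum across the dataset: the figure of merit for
#' targeted generation.
#'
#' @param y_calc realised property value.
#' @param y_target targeted value.
#' @param y_range property range `delta_y` (> 0).
#' @return error in percent.
#' @export
target_error <- function(y_calc, y_target, y_range) {
  if (any(y_range <= 0)) stop("property range must be positive")
  abs(y_calc - y_target) / y_range * 100
}
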