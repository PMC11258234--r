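#' Minimal heavy-atom RMSD under rigid superposition
#'
#' Kabsch superposition: both molecules are centred, the optimal rotation is
#' obtained from the SVD of the cross-covariance, and the RMSD of the aligned
#' coordinates is returned. Atom correspondence is positional (canonical slot
#' order); no combinatorial matching is attempted. With
#' `allow_reflection = TRUE` the minimum over both handedness branches of the
#' orthogonal alignment is taken, which is the natural convention for
#' Coulomb-matrix reconstructions since the representation is blind to
#' chirality.
#'
#' @param a,b [molecule] objects with identical composition in the same order.
#' @param allow_reflection also consider improper (det = -1) alignments.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(a, b, allow_reflection = TRUE) {
  stopifnot(inherits(a, "molecule"), inherits(b, "molecule"))
  if (length(a$species) != length(b$species) || any(a$species != b$species))
    stop("RMSD undefined: compositions differ")
  p <- scale(a$coords, scale = FALSE)
  q <- scale(b$coords, scale = FALSE)
  n <- nrow(p)
  if (n == 1L) return(0)
  s <- svd(crossprod(p, q))
  # evaluate the aligned residual directly (the closed-form trace expression
  # loses ~sqrt(eps) of precision to cancellation near zero RMSD)
  resid <- function(r) sqrt(mean(rowSums((p %*% r - q)^2)))
  flip <- sign(det(tcrossprod(s$u, s$v)))
  d_proper <- c(1, 1, if (flip == 0) 1 else flip)
  best <- resid(s$u %*% (d_proper * t(s$v)))
  if (allow_reflection && flip < 0)
    best <- min(best, resid(tcrossprod(s$u, s$v)))
  best
}

#' Are two molecules mirror images (an enantiomeric pair)?
#'
#' TRUE when the reflection-allowed RMSD is below `tol` but the proper
#' (rotation-only) RMSD is not: the structures coincide only through an
#' improper transformation. Such pairs look identical to the Coulomb-matrix
#' representation and must be excluded as endpoints of an interpolation.
#'
#' @param a,b [molecule] objects with identical composition.
#' @param tol coincidence tolerance in Angstrom.
#' @return logical.
#' @export
mirror_image_check <- function(a, b, tol = 1e-3) {
  r_refl <- heavy_atom_rmsd(a, b, allow_reflection = TRUE)
  r_prop <- heavy_atom_rmsd(a, b, allow_reflection = FALSE)
  r_refl < tol && r_prop >= tol
}
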