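#' Coulomb matrix of a molecule
#'
#' The Coulomb matrix is the rotation- and translation-invariant descriptor
#' with diagonal `0.5 * Z_i^2.4` and off-diagonal `Z_i * Z_j / |r_i - r_j|`
#' (distances in Angstrom). It is exactly invertible up to chirality: the
#' composition is recovered from the diagonal, the geometry from the
#' off-diagonal entries by classical multidimensional scaling.
#'
#' @param mol a [molecule].
#' @return symmetric numeric matrix, one row/column per atom.
#' @examples
#' coulomb_matrix(molecule(6, c(0, 0, 0)))  # 0.5 * 6^2.4
#' @export
coulomb_matrix <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  z <- as.numeric(mol$species)
  n <- length(z)
  d <- as.matrix(stats::dist(mol$coords))
  if (n > 1L && min(d[upper.tri(d)]) <= 0)
    stop("degenerate geometry: coincident atoms give an infinite Coulomb entry")
  m <- outer(z, z) / (d + diag(n))  # diagonal placeholder, overwritten next
  diag(m) <- 0.5 * z^2.4
  m
}

#' Species-block padding layout
#'
#' Fixes the size and block structure of padded Coulomb matrices: one block of
#' slots per allowed element, blocks ordered by ascending atomic number. Slot
#' counts are normally taken from the per-species maxima of a dataset.
#'
#' @param counts integer vector of slot counts per element.
#' @param elements atomic numbers the layout admits (default carbon, nitrogen,
#'   oxygen). Recycled order is ascending atomic number regardless of input
#'   order.
#' @return a `cm_layout` object with fields `elements`, `counts`, `size`, and
#'   `slot_species` (the element owning each slot).
#' @export
cm_layout <- function(counts, elements = c(6L, 7L, 8L)) {
  elements <- as.integer(elements)
  counts <- as.integer(counts)
  stopifnot(length(counts) == length(elements), all(counts >= 0))
  ord <- order(elements)
  elements <- elements[ord]
  counts <- counts[ord]
  structure(list(
    elements = elements,
    counts = counts,
    size = sum(counts),
    slot_species = rep(elements, counts)
  ), class = "cm_layout")
}

#' Layout inferred from a set of molecules
#'
#' Slot counts are the dataset maxima of the per-species atom counts, the
#' convention used for network input standardisation.
#'
#' @param mols list of [molecule] objects.
#' @param elements allowed atomic numbers.
#' @return a [cm_layout].
#' @export
layout_from_molecules <- function(mols, elements = c(6L, 7L, 8L)) {
  counts <- vapply(sort(as.integer(elements)), function(e)
    max(vapply(mols, function(m) sum(m$species == e), integer(1))), integer(1))
  cm_layout(counts, sort(as.integer(elements)))
}

#' Pad and canonicalise a Coulomb matrix
#'
#' Places each atom into the slot block of its species and, within a block,
#' orders atoms by descending Coulomb-matrix row norm (the sorted-Coulomb-
#' matrix convention), which makes the padded representation invariant to the
#' input atom order. Remaining slots are zero.
#'
#' @param cm unpadded Coulomb matrix as returned by [coulomb_matrix()].
#' @param species atomic numbers of the atoms (rows of `cm`).
#' @param layout a [cm_layout].
#' @return a `padded_cm` object: `matrix` (size x size), `layout`,
#'   `occupied` (slot indices that hold atoms), and `atom_order` (the input
#'   atom permutation that fills the slots in order).
#' @export
canonicalize_and_pad <- function(cm, species, layout) {
  stopifnot(inherits(layout, "cm_layout"))
  species <- as.integer(species)
  n <- length(species)
  stopifnot(nrow(cm) == n, ncol(cm) == n)
  if (any(!species %in% layout$elements))
    stop("species outside the layout element set: ",
         paste(setdiff(species, layout$elements), collapse = ", "))
  # canonical atom order: blocks by ascending Z, descending row norm inside
  rown <- sqrt(rowSums(cm^2))
  ord <- integer(0)
  slots <- integer(0)
  offset <- 0L
  for (b in seq_along(layout$elements)) {
    e <- layout$elements[b]
    idx <- which(species == e)
    if (length(idx) > layout$counts[b])
      stop("layout capacity exceeded for element ", e, ": ",
           length(idx), " atoms, ", layout$counts[b], " slots")
    idx <- idx[order(-rown[idx])]
    ord <- c(ord, idx)
    slots <- c(slots, offset + seq_along(idx))
    offset <- offset + layout$counts[b]
  }
  L <- layout$size
  m <- matrix(0, L, L)
  m[slots, slots] <- cm[ord, ord]
  structure(list(matrix = m, layout = layout, occupied = slots,
                 atom_order = ord),
            class = "padded_cm")
}

#' Build and pad in one step
#' @param mol a [molecule].
#' @param layout a [cm_layout].
#' @return a `padded_cm`.
#' @export
padded_coulomb_matrix <- function(mol, layout)
  canonicalize_and_pad(coulomb_matrix(mol), mol$species, layout)

#' @export
print.padded_cm <- function(x, ...) {
  cat("<padded_cm> ", x$layout$size, "x", x$layout$size, ", ",
      length(x$occupied), " occupied slots\n", sep = "")
  invisible(x)
}

#' Flatten a padded Coulomb matrix for network I/O
#'
#' The network exchanges the upper triangle (including the diagonal) in
#' column-major order; length `L * (L + 1) / 2`.
#'
#' @param padded a `padded_cm` or a plain symmetric matrix.
#' @return numeric vector.
#' @export
cm_vector <- function(padded) {
  m <- if (inherits(padded, "padded_cm")) padded$matrix else padded
  m[upper.tri(m, diag = TRUE)]
}

#' Rebuild a symmetric matrix from its flattened upper triangle
#'
#' The decoder emits the upper triangle only, so the matrix is symmetric by
#' construction -- both triangles are filled from the same entries.
#'
#' @param vec flattened upper triangle (column-major, diagonal included).
#' @param layout a [cm_layout] giving the matrix size.
#' @return a `padded_cm` (with `occupied` left unset; use
#'   [infer_composition()] on noisy matrices).
#' @export
cm_from_vector <- function(vec, layout) {
  L <- layout$size
  stopifnot(length(vec) == L * (L + 1) / 2)
  m <- matrix(0, L, L)
  m[upper.tri(m, diag = TRUE)] <- vec
  m <- m + t(m) - diag(diag(m))
  structure(list(matrix = m, layout = layout, occupied = NULL),
            class = "padded_cm")
}

#' Recover the composition from a (possibly noisy) padded Coulomb matrix
#'
#' Each diagonal entry `d` is mapped through the inverse of the diagonal rule,
#' `Zt = (2 d)^(1/2.4)`, and assigned the nearest value in `{0} + allowed
#' elements`; 0 marks an empty slot. Total on any input: negative diagonals
#' map to 0.
#'
#' @param padded a `padded_cm`.
#' @return list with `species` (atomic numbers of occupied slots, in slot
#'   order) and `slots` (their slot indices).
#' @export
infer_composition <- function(padded) {
  stopifnot(inherits(padded, "padded_cm"))
  d <- diag(padded$matrix)
  zt <- (2 * pmax(d, 0))^(1 / 2.4)
  cand <- c(0L, padded$layout$elements)
  pick <- cand[max.col(-abs(outer(zt, as.numeric(cand), `-`)), ties.method = "first")]
  occ <- which(pick > 0L)
  list(species = as.integer(pick[occ]), slots = occ)
}

#' Interatomic distances encoded in a padded Coulomb matrix
#'
#' Inverts the off-diagonal rule: `d_ij = Z_i * Z_j / M_ij` for occupied slot
#' pairs.
#'
#' @param padded a `padded_cm`.
#' @param composition result of [infer_composition()]; recomputed if missing.
#' @return symmetric distance matrix (Angstrom) over the occupied slots.
#' @export
cm_to_distances <- function(padded, composition = NULL) {
  if (is.null(composition)) composition <- infer_composition(padded)
  z <- as.numeric(composition$species)
  s <- composition$slots
  n <- length(s)
  if (n == 0L) stop("empty molecule: no occupied slots")
  m <- padded$matrix[s, s, drop = FALSE]
  if (n == 1L) return(matrix(0, 1, 1))
  off <- m[upper.tri(m)]
  if (any(off <= 0))
    stop("invalid Coulomb matrix: nonpositive off-diagonal for an occupied pair")
  d <- outer(z, z) / m
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Classical multidimensional scaling into 3D
#'
#' Double-centers the squared-distance matrix, eigendecomposes, and keeps the
#' three largest eigenvalues clamped at zero, so 3D coordinates are always
#' produced even for noisy, non-embeddable inputs. The output is defined up to
#' rotation, translation, and reflection.
#'
#' @param edm square symmetric distance matrix with zero diagonal.
#' @return n x 3 coordinate matrix.
#' @export
cmds_embed <- function(edm) {
  edm <- as.matrix(edm)
  n <- nrow(edm)
  stopifnot(ncol(edm) == n)
  if (any(!is.finite(edm)) || any(edm < 0))
    stop("distance matrix must be finite and nonnegative")
  if (max(abs(edm - t(edm))) > 1e-8 || max(abs(diag(edm))) > 1e-8)
    stop("distance matrix must be symmetric with zero diagonal")
  if (n == 1L) return(matrix(0, 1, 3))
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (edm^2) %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  k <- min(3L, n)
  lam <- pmax(e$values[seq_len(k)], 0)
  x <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  if (k < 3L) x <- cbind(x, matrix(0, n, 3L - k))
  x
}

#' Reconstruct a molecule from a padded Coulomb matrix
#'
#' Composition from the diagonal, distances from the off-diagonals, Cartesian
#' coordinates by [cmds_embed()]. Exact inverse of build-and-pad up to a rigid
#' motion and possibly a reflection (the Coulomb matrix is blind to
#' chirality).
#'
#' @param padded a `padded_cm`.
#' @return a [molecule].
#' @export
reconstruct_molecule <- function(padded) {
  comp <- infer_composition(padded)
  if (length(comp$species) == 0L)
    stop("empty molecule: all diagonal entries decode to empty slots")
  d <- cm_to_distances(padded, comp)
  molecule(comp$species, cmds_embed(d), min_dist = 0)
}

#' Relative Coulomb-matrix reconstruction error
#'
#' `Delta = |c_tilde - c| / |c| * 100`, Euclidean norms, both matrices taken
#' as vectors. The standard figure of merit for reconstruction quality when
#' the composition may be wrong (RMSD is undefined there).
#'
#' @param c_ref reference Coulomb-matrix vector.
#' @param c_tilde reconstructed Coulomb-matrix vector.
#' @return error in percent (>= 0).
#' @export
relative_cm_error <- function(c_ref, c_tilde) {
  c_ref <- as.numeric(c_ref); c_tilde <- as.numeric(c_tilde)
  stopifnot(length(c_ref) == length(c_tilde))
  nref <- sqrt(sum(c_ref^2))
  if (nref == 0) stop("reference Coulomb matrix has zero norm")
  sqrt(sum((c_tilde - c_ref)^2)) / nref * 100
}
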