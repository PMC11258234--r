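#' Specification of a synthetic dataset
#'
#' Parameters of the desk-scale synthetic chemical space the package trains
#' and tests on: heavy-atom-only molecules with up to `max_atoms` atoms drawn
#' from `elements`, grown by sequential attachment with bond lengths in
#' `bond_range`, plus the synthetic 17-property vectors of
#' [synthetic_properties()].
#'
#' @param n number of molecules.
#' @param elements allowed atomic numbers.
#' @param max_atoms maximum heavy-atom count.
#' @param bond_range attachment distance range in Angstrom; must lie inside
#'   (0.8, 2.5).
#' @param noise_sd relative property noise (see [synthetic_properties()]).
#' @param seed RNG seed used by [make_dataset()].
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n = 1000L, elements = c(6L, 7L, 8L), max_atoms = 7L,
                           bond_range = c(1.2, 1.6), noise_sd = 0.05,
                           seed = 1L) {
  stopifnot(n >= 1, max_atoms >= 1, length(bond_range) == 2,
            bond_range[1] > 0.8, bond_range[2] < 2.5,
            bond_range[1] <= bond_range[2], noise_sd >= 0)
  structure(list(n = as.integer(n), elements = sort(as.integer(elements)),
                 max_atoms = as.integer(max_atoms),
                 bond_range = as.numeric(bond_range),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# All composition multisets with 1..max_atoms atoms over the element set,
# as a matrix of per-element counts (one row per multiset).
enumerate_compositions <- function(elements, max_atoms) {
  k <- length(elements)
  rows <- list()
  grid <- do.call(expand.grid, rep(list(0:max_atoms), k))
  tot <- rowSums(grid)
  grid <- as.matrix(grid[tot >= 1 & tot <= max_atoms, , drop = FALSE])
  dimnames(grid) <- list(NULL, as.character(elements))
  grid
}

#' Draw one synthetic molecule
#'
#' The composition is uniform over all multisets of at most `max_atoms`
#' atoms from the element set. The geometry is grown by sequential
#' attachment: each new atom is placed at a uniform distance in `bond_range`
#' from a uniformly chosen existing atom, in a uniform random direction,
#' rejecting placements that bring any pair closer than `0.8 *
#' bond_range[1]`. The contact graph is connected by construction. Uses the
#' current R random number stream.
#'
#' @param spec a [synthetic_spec].
#' @param tries rejection budget per atom before the geometry is restarted.
#' @return a [molecule].
#' @export
sample_molecule <- function(spec, tries = 200L) {
  comps <- enumerate_compositions(spec$elements, spec$max_atoms)
  cnt <- comps[sample.int(nrow(comps), 1L), ]
  pool <- rep(spec$elements, cnt)
  species <- pool[sample.int(length(pool))]  # random placement order
  n <- length(species)
  floor_d <- 0.8 * spec$bond_range[1]
  repeat {
    coords <- matrix(0, n, 3)
    ok <- TRUE
    for (i in seq_len(n)[-1]) {
      placed <- FALSE
      for (t in seq_len(tries)) {
        anchor <- coords[sample.int(i - 1L, 1L), ]
        u <- stats::runif(1, spec$bond_range[1], spec$bond_range[2])
        v <- stats::rnorm(3)
        pos <- anchor + u * v / sqrt(sum(v^2))
        dd <- sqrt(rowSums(sweep(coords[seq_len(i - 1L), , drop = FALSE],
                                 2, pos)^2))
        if (all(dd >= floor_d)) {
          coords[i, ] <- pos
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(molecule(species, coords))
  }
}

#' Generate a full synthetic dataset
#'
#' Draws `spec$n` molecules, computes their synthetic property vectors and
#' padded Coulomb matrices (layout from the dataset per-species maxima), and
#' assigns train/validation/test splits in 70/5/25 proportion. Fully
#' deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec].
#' @return a `molinverse_dataset`: list with `molecules`, `properties`
#'   (n x 17 matrix), `cm` (n x D matrix of flattened padded Coulomb
#'   matrices), `padded` (list of `padded_cm`), `layout`, `split`
#'   (factor train/val/test), and `spec`.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  mols <- replicate(spec$n, sample_molecule(spec), simplify = FALSE)
  props <- t(vapply(mols, synthetic_properties, numeric(17),
                    noise_sd = spec$noise_sd))
  colnames(props) <- property_names()
  layout <- layout_from_molecules(mols, spec$elements)
  padded <- lapply(mols, padded_coulomb_matrix, layout = layout)
  cm <- t(vapply(padded, cm_vector,
                 numeric(layout$size * (layout$size + 1) / 2)))
  n_train <- floor(0.70 * spec$n)
  n_val <- floor(0.05 * spec$n)
  split <- factor(c(rep("train", n_train), rep("val", n_val),
                    rep("test", spec$n - n_train - n_val)),
                  levels = c("train", "val", "test"))
  structure(list(molecules = mols, properties = props, cm = cm,
                 padded = padded, layout = layout, split = split,
                 spec = spec),
            class = "molinverse_dataset")
}

#' @export
print.molinverse_dataset <- function(x, ...) {
  cat("<molinverse_dataset> n =", length(x$molecules),
      "| layout", x$layout$size, "slots | splits:",
      paste(table(x$split), collapse = "/"), "\n")
  invisible(x)
}
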