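#' Heavy-atom molecule
#'
#' A minimal container for a heavy-atom-only molecule: atomic numbers plus
#' Cartesian coordinates in Angstrom. Hydrogens are implicit throughout the
#' package; only the heavy-atom scaffold is represented.
#'
#' @param species integer vector of atomic numbers.
#' @param coords numeric matrix with one row per atom and 3 columns (x, y, z),
#'   in Angstrom.
#' @param min_dist smallest allowed interatomic distance in Angstrom; pairs
#'   closer than this are rejected as degenerate geometry.
#' @return An object of class `molecule` with fields `species` and `coords`.
#' @examples
#' m <- molecule(c(6, 8), rbind(c(0, 0, 0), c(1.2, 0, 0)))
#' @export
molecule <- function(species, coords, min_dist = 1e-6) {
  species <- as.integer(species)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(species) < 1L) stop("a molecule needs at least one atom")
  if (nrow(coords) != length(species))
    stop("species and coords disagree on the number of atoms")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (length(species) > 1L) {
    d <- stats::dist(coords)
    if (min(d) < min_dist)
      stop("degenerate geometry: atoms closer than ", min_dist, " Angstrom")
  }
  structure(list(species = species, coords = coords), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", length(x$species), " heavy atoms: ",
      paste(element_symbol(x$species), collapse = ""), "\n", sep = "")
  invisible(x)
}

# Symbol <-> atomic number tables for the elements this package meets in
# practice (organic subset + H for file I/O).
.elements <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L, S = 16L, Cl = 17L)

#' Element symbols for atomic numbers
#' @param z integer vector of atomic numbers.
#' @return character vector of element symbols.
#' @export
element_symbol <- function(z) {
  idx <- match(as.integer(z), .elements)
  if (anyNA(idx)) stop("unknown atomic number: ", paste(z[is.na(idx)], collapse = ", "))
  names(.elements)[idx]
}

#' Atomic numbers for element symbols
#' @param sym character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(sym) {
  z <- .elements[as.character(sym)]
  if (anyNA(z)) stop("unknown element symbol: ", paste(sym[is.na(z)], collapse = ", "))
  unname(z)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then one `symbol x y z` row
#' per atom (coordinates in Angstrom).
#'
#' @param path file path.
#' @return a [molecule].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || n < 1L) stop("malformed XYZ header in ", path)
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  sym <- vapply(rows, `[[`, "", 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecule(atomic_number(sym), xyz)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a [molecule].
#' @param path output file path.
#' @param comment comment placed on the second line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "") {
  sym <- element_symbol(mol$species)
  body <- sprintf("%-2s %14.8f %14.8f %14.8f",
                  sym, mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  writeLines(c(length(sym), comment, body), path)
  invisible(path)
}
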