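#' Load a QM7-X-style dataset from its HDF5 distribution
#'
#' Reads HDF5 files following the QM7-X layout (one group per molecule, one
#' subgroup per conformation with `atNUM`/`atXYZ` arrays and scalar property
#' datasets; conformation names ending in `opt` mark equilibrium structures)
#' and keeps equilibrium conformations whose heavy atoms are within
#' `elements` and number at most `max_heavy`. Hydrogens are dropped
#' (implicit-hydrogen convention). Properties are extracted by the keys of
#' `property_keys`, mapping each model property name to its dataset key;
#' records missing a requested key are dropped with a message.
#'
#' The HDF5 parsing is delegated to a bundled Python helper (h5py), since no
#' R HDF5 interface is available in the package's dependency set.
#'
#' @param path directory containing the `.hdf5` files of the dataset
#'   (Zenodo accession 10.5281/zenodo.4288677).
#' @param elements allowed heavy-atom numbers.
#' @param max_heavy maximum heavy-atom count.
#' @param property_keys named character vector: model property name ->
#'   HDF5 dataset key. The 17-property set and its dataset keys are
#'   configuration, not hard-coded.
#' @param python python executable with h5py available.
#' @return a `molinverse_dataset` (all split labels "test"; re-split before
#'   training) with a `subset_size` field.
#' @export
qm7x_load <- function(path, elements = c(6L, 7L, 8L), max_heavy = 7L,
                      property_keys = NULL, python = "python") {
  files <- list.files(path, pattern = "\\.(h5|hdf5)$", full.names = TRUE)
  if (length(files) == 0L)
    stop("no HDF5 files found under '", path,
         "'; download the QM7-X dataset (Zenodo accession ",
         "10.5281/zenodo.4288677) and point to its directory")
  script <- system.file("python", "qm7x_to_json.py", package = "molinverse")
  out <- system2(python, c(script, shQuote(files)), stdout = TRUE,
                 stderr = FALSE)
  records <- jsonlite::fromJSON(paste(out, collapse = ""),
                                simplifyVector = FALSE)

  keep_mols <- list(); keep_props <- list()
  dropped_keys <- 0L
  for (rec in records) {
    if (!isTRUE(rec$equilibrium)) next
    z <- unlist(rec$atNUM)
    heavy <- z != 1L
    zh <- z[heavy]
    if (length(zh) == 0L || length(zh) > max_heavy) next
    if (!all(zh %in% elements)) next
    xyz <- do.call(rbind, lapply(rec$atXYZ, unlist))[heavy, , drop = FALSE]
    if (!is.null(property_keys)) {
      if (!all(property_keys %in% names(rec$properties))) {
        dropped_keys <- dropped_keys + 1L
        next
      }
      pv <- unlist(rec$properties[property_keys])
      names(pv) <- names(property_keys)
    } else {
      pv <- unlist(rec$properties)
    }
    keep_mols[[length(keep_mols) + 1L]] <- molecule(zh, xyz)
    keep_props[[length(keep_props) + 1L]] <- pv
  }
  if (dropped_keys > 0L)
    message(dropped_keys, " records dropped for missing property keys")
  if (length(keep_mols) == 0L)
    stop("no records passed the equilibrium/composition filter")
  props <- do.call(rbind, keep_props)
  layout <- layout_from_molecules(keep_mols, elements)
  padded <- lapply(keep_mols, padded_coulomb_matrix, layout = layout)
  cm <- t(vapply(padded, cm_vector,
                 numeric(layout$size * (layout$size + 1) / 2)))
  structure(list(molecules = keep_mols, properties = props, cm = cm,
                 padded = padded, layout = layout,
                 split = factor(rep("test", length(keep_mols)),
                                levels = c("train", "val", "test")),
                 spec = NULL, subset_size = length(keep_mols)),
            class = "molinverse_dataset")
}

#' Re-split a dataset into train/validation/test
#'
#' Applies the standard 70/5/25 proportions (or custom fractions) with a
#' seeded random permutation.
#'
#' @param dataset a `molinverse_dataset`.
#' @param fractions train and validation fractions (test takes the rest).
#' @param seed RNG seed.
#' @return the dataset with a new `split` factor.
#' @export
resplit_dataset <- function(dataset, fractions = c(0.70, 0.05), seed = 1L) {
  n <- length(dataset$molecules)
  set.seed(seed)
  ord <- sample.int(n)
  n_tr <- floor(fractions[1] * n)
  n_va <- floor(fractions[2] * n)
  split <- character(n)
  split[ord[seq_len(n_tr)]] <- "train"
  split[ord[n_tr + seq_len(n_va)]] <- "val"
  split[split == ""] <- "test"
  dataset$split <- factor(split, levels = c("train", "val", "test"))
  dataset
}
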