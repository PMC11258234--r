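# Coulomb-matrix construction, padding/canonicalisation, and exact inversion.

test_that("Coulomb matrix entries follow the diagonal and off-diagonal rules", {
  # frozen high-precision value of 0.5 * 6^2.4
  m1 <- coulomb_matrix(molecule(6L, c(0, 0, 0)))
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(m1[1, 1], 36.8581051994259473, tolerance = 1e-14)

  m2 <- coulomb_matrix(molecule(c(1L, 1L), rbind(c(0, 0, 0), c(1, 0, 0))))
  expect_equal(m2[1, 2], 1)
  expect_equal(m2, t(m2))

  # a C-C pair at 1.54 Angstrom
  m3 <- coulomb_matrix(molecule(c(6L, 6L), rbind(c(0, 0, 0), c(1.54, 0, 0))))
  expect_equal(m3[1, 2], 36 / 1.54, tolerance = 1e-12)
})

test_that("Coulomb matrix is invariant under rigid motions", {
  set.seed(31)
  for (i in 1:5) {
    mol <- random_molecule(6L)
    r <- random_rotation()
    shifted <- molecule(mol$species,
                        sweep(mol$coords %*% r, 2, rnorm(3, 0, 5), `+`))
    expect_equal(coulomb_matrix(shifted), coulomb_matrix(mol),
                 tolerance = 1e-10)
  }
})

test_that("coincident atoms are rejected as degenerate geometry", {
  expect_error(molecule(c(6L, 6L), rbind(c(0, 0, 0), c(0, 0, 0))),
               "degenerate")
})

test_that("canonicalisation is permutation-invariant and idempotent", {
  set.seed(32)
  layout <- cm_layout(c(7L, 7L, 7L))
  for (i in 1:5) {
    mol <- random_molecule(7L)
    p1 <- padded_coulomb_matrix(mol, layout)
    perm <- sample(length(mol$species))
    mol2 <- molecule(mol$species[perm], mol$coords[perm, ])
    p2 <- padded_coulomb_matrix(mol2, layout)
    expect_identical(p1$matrix, p2$matrix)
    # idempotence: re-canonicalising the occupied block changes nothing
    occ <- p1$occupied
    p3 <- canonicalize_and_pad(p1$matrix[occ, occ],
                               layout$slot_species[occ], layout)
    expect_identical(p3$matrix, p1$matrix)
  }
})

test_that("within a species block the larger row norm takes the earlier slot", {
  # two carbons: one close to a heavy neighbour (large row norm), one far
  mol <- molecule(c(6L, 6L, 8L),
                  rbind(c(0, 0, 0), c(3.0, 0, 0), c(1.2, 0, 0)))
  cm <- coulomb_matrix(mol)
  rn <- sqrt(rowSums(cm^2))
  expect_gt(rn[1], rn[2])  # brute-force check of the intended ordering
  p <- padded_coulomb_matrix(mol, cm_layout(c(2L, 0L, 1L)))
  expect_equal(p$matrix[1, 1], cm[1, 1])
  expect_equal(p$matrix[1, 3], cm[1, 3])  # slot 1 is the close carbon
  # the alternative ordering would place the far carbon first; verify it
  # produces a different matrix (so the sort is doing real work)
  swapped <- canonicalize_and_pad(cm[c(2, 1, 3), c(2, 1, 3)],
                                  c(6L, 6L, 8L), cm_layout(c(2L, 0L, 1L)))
  expect_identical(swapped$matrix, p$matrix)
})

test_that("layout capacity violations error", {
  mol <- molecule(c(6L, 6L), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_error(padded_coulomb_matrix(mol, cm_layout(c(1L, 1L, 1L))),
               "capacity")
})

test_that("composition inference assigns the nearest allowed element", {
  layout <- cm_layout(c(2L, 1L, 1L))
  m <- matrix(0, 4, 4)
  diag(m) <- c(36.8581051994259473, 0, 0, 40)  # frozen: (80)^(1/2.4) = 6.208
  p <- structure(list(matrix = m, layout = layout, occupied = NULL),
                 class = "padded_cm")
  comp <- infer_composition(p)
  expect_equal(comp$species, c(6L, 6L))
  expect_equal(comp$slots, c(1L, 4L))
  # negative / tiny diagonals decode to empty
  diag(m) <- c(-3, 1e-4, 0, 0)
  p$matrix <- m
  expect_length(infer_composition(p)$species, 0L)
})

test_that("distance recovery inverts the off-diagonal rule", {
  mol <- molecule(c(6L, 6L), rbind(c(0, 0, 0), c(1.54, 0, 0)))
  p <- padded_coulomb_matrix(mol, cm_layout(c(2L, 0L, 0L)))
  d <- cm_to_distances(p)
  expect_equal(d[1, 2], 1.54, tolerance = 1e-12)
  set.seed(33)
  mol <- random_molecule(6L)
  p <- padded_coulomb_matrix(mol, cm_layout(c(7L, 7L, 7L)))
  d <- cm_to_distances(p)
  ref <- as.matrix(dist(mol$coords))
  expect_equal(sort(d[upper.tri(d)]), sort(ref[upper.tri(ref)]),
               tolerance = 1e-10)
})

test_that("classical MDS reproduces embeddable distance matrices", {
  set.seed(34)
  for (i in 1:5) {
    x <- matrix(rnorm(15), 5)
    edm <- as.matrix(dist(x))
    y <- cmds_embed(edm)
    expect_equal(as.matrix(dist(y)), edm, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # cross-check against the stats implementation of classical scaling
    y2 <- cmdscale(edm, k = 3)
    expect_equal(as.matrix(dist(y2)), edm, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # collinear points: effectively 1D, third eigenvalue ~ 0
  edm <- as.matrix(dist(cbind(c(0, 1, 2), 0, 0)))
  y <- cmds_embed(edm)
  expect_equal(as.matrix(dist(y)), edm, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(y[, 2:3])), 1e-6)
  # two points at distance 2
  y <- cmds_embed(matrix(c(0, 2, 2, 0), 2))
  expect_equal(sqrt(sum((y[1, ] - y[2, ])^2)), 2, tolerance = 1e-12)
  expect_error(cmds_embed(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
})

test_that("mildly perturbed distance matrices embed with bounded error", {
  set.seed(35)
  for (i in 1:3) {
    x <- matrix(rnorm(12), 4)
    edm <- as.matrix(dist(x))
    noise <- matrix(rnorm(16, 0, 0.01), 4)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    pert <- pmax(edm + noise, 0)
    pert <- (pert + t(pert)) / 2
    y <- cmds_embed(pert)
    err_cmds <- max(abs(as.matrix(dist(y)) - edm))
    # brute-force coordinate-fitting oracle on the same perturbed input
    obj <- function(par) {
      z <- matrix(par, 4)
      sum((as.matrix(dist(z)) - pert)^2)
    }
    fit <- optim(as.numeric(x), obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    z <- matrix(fit$par, 4)
    err_oracle <- max(abs(as.matrix(dist(z)) - edm))
    # both must degrade gracefully with the perturbation scale
    expect_lt(err_cmds, 0.15)
    expect_lt(abs(err_cmds - err_oracle), 0.15)
  }
})

test_that("build -> pad -> reconstruct is an exact inverse up to chirality", {
  set.seed(36)
  layout <- cm_layout(c(7L, 7L, 7L))
  for (i in 1:10) {
    mol <- random_molecule(sample(1:7, 1))
    rec <- reconstruct_molecule(padded_coulomb_matrix(mol, layout))
    expect_identical(sort(rec$species), sort(mol$species))
    cm_rec <- coulomb_matrix(rec)
    p <- padded_coulomb_matrix(mol, layout)
    expect_equal(cm_rec, p$matrix[p$occupied, p$occupied],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(reconstruct_molecule(cm_from_vector(numeric(21 * 22 / 2),
                                                   cm_layout(c(7L, 7L, 7L)))),
               "empty")
})

test_that("composition survives moderate additive noise on the matrix", {
  set.seed(37)
  layout <- cm_layout(c(5L, 5L, 5L))
  for (i in 1:5) {
    mol <- random_molecule(5L)
    p <- padded_coulomb_matrix(mol, layout)
    noise <- matrix(rnorm(15 * 15, 0, 0.1), 15)
    noisy <- p
    noisy$matrix <- p$matrix + (noise + t(noise)) / 2
    comp <- infer_composition(noisy)
    # brute-force margin check: every occupied diagonal stays nearest to its
    # own element, every empty slot nearest to zero
    zt <- (2 * pmax(diag(noisy$matrix), 0))^(1 / 2.4)
    for (s in seq_len(15)) {
      truth <- if (s %in% p$occupied)
        layout$slot_species[s] else 0L
      cand <- c(0L, 6L, 7L, 8L)
      expect_equal(cand[which.min(abs(zt[s] - cand))], truth)
    }
    expect_identical(sort(comp$species), sort(mol$species))
  }
})

test_that("relative Coulomb-matrix error behaves as a norm ratio", {
  v <- c(1, 2, 3)
  expect_equal(relative_cm_error(v, v), 0)
  expect_equal(relative_cm_error(v, 2 * v), 100)
  expect_equal(relative_cm_error(v, 0 * v), 100)
  expect_error(relative_cm_error(c(0, 0), c(1, 1)), "zero norm")
})
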