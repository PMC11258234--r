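# The joint model: encoders, losses, masking, training, inference.

test_that("encoders are deterministic with positive sigma and respond
           continuously to their inputs", {
  set.seed(81)
  model <- inverse_model(10L, 4L, latent = 3L, enc_hidden = 8L, dec_hidden = 8L,
                     prop_hidden = 6L)
  x <- rnorm(10)
  g1 <- encode_structure(model, x)
  g2 <- encode_structure(model, x)
  expect_identical(g1, g2)
  expect_true(all(g1$sigma > 0))
  # zeroed final layer pins the mean at the bias for any input
  m0 <- model
  m0$enc$W[[length(m0$enc$W)]][] <- 0
  m0$enc$b[[length(m0$enc$b)]][] <- 0
  expect_equal(encode_structure(m0, rnorm(10))$mu, matrix(0, 1, 3))
  # finite-difference Jacobian of the mean head matches forward-mode autodiff
  h <- 1e-5
  for (enc in c("structure", "property")) {
    f <- if (enc == "structure") encode_structure else encode_properties
    d_in <- if (enc == "structure") 10L else 4L
    v <- rnorm(d_in)
    net <- if (enc == "structure") model$enc else model$prop
    jac <- mlp_jvp(net, v)$jvp[, 1:3, drop = FALSE]
    for (j in seq_len(d_in)) {
      e <- numeric(d_in); e[j] <- h
      fd <- (f(model, v + e)$mu - f(model, v - e)$mu) / (2 * h)
      expect_equal(jac[j, ], as.numeric(fd), tolerance = 1e-5)
    }
  }
  expect_error(encode_structure(model, c(NA, rnorm(9))), "non-finite")
})

test_that("KL divergence matches the closed form and a Monte-Carlo oracle", {
  expect_equal(kl_divergence(0, 1), 0)
  expect_equal(kl_divergence(1, 1), 0.5)  # 0.5 * (mu^2 + 1 - 1 - 0)
  expect_error(kl_divergence(0, -1), "positive")
  set.seed(82)
  mu <- c(0.4, -1.2); sigma <- c(0.7, 1.5)
  z <- cbind(rnorm(1e6, mu[1], sigma[1]), rnorm(1e6, mu[2], sigma[2]))
  lr <- (dnorm(z[, 1], mu[1], sigma[1], log = TRUE) +
           dnorm(z[, 2], mu[2], sigma[2], log = TRUE)) -
        (dnorm(z[, 1], log = TRUE) + dnorm(z[, 2], log = TRUE))
  expect_lt(abs(mean(lr) - kl_divergence(mu, sigma)), 3 * sd(lr) / sqrt(1e6))
})

test_that("joint loss with tau = 0, beta = 1 is exactly the ELBO", {
  set.seed(83)
  model <- inverse_model(12L, 5L, latent = 4L, enc_hidden = 8L, dec_hidden = 8L,
                     prop_hidden = 6L, beta = 1, tau = 0)
  x <- matrix(rnorm(36), 3); y <- matrix(rnorm(15), 3)
  eps <- matrix(rnorm(12), 3)
  jl <- joint_loss(model, x, y, eps = eps)
  # independent scalar ELBO: KL + unit-variance Gaussian reconstruction NLL
  g <- encode_structure(model, x)
  z <- g$mu + g$sigma * eps
  xhat <- mlp_forward(model$dec, z)$out
  elbo <- 0
  for (i in 1:3) {
    kl_i <- 0
    for (j in 1:4)
      kl_i <- kl_i + 0.5 * (g$mu[i, j]^2 + g$sigma[i, j]^2 - 1 -
                              log(g$sigma[i, j]^2))
    rec_i <- 0
    for (j in 1:12)
      rec_i <- rec_i + 0.5 * (x[i, j] / model$scalers$cm_scale -
                                xhat[i, j])^2 + 0.5 * log(2 * pi)
    elbo <- elbo + (kl_i + rec_i) / 3
  }
  expect_equal(jl$kl + jl$recon, elbo, tolerance = 1e-10)
  expect_equal(jl$total, elbo, tolerance = 1e-10)
  # encoder forced to the prior: KL component vanishes
  m0 <- model
  m0$enc$W[[length(m0$enc$W)]][] <- 0
  m0$enc$b[[length(m0$enc$b)]][] <- 0
  expect_equal(joint_loss(m0, x, y, eps = eps)$kl, 0, tolerance = 1e-12)
})

test_that("joint loss on a frozen 2-molecule batch matches hand arithmetic
           for all three components", {
  set.seed(84)
  model <- inverse_model(6L, 3L, latent = 2L, enc_hidden = 5L, dec_hidden = 5L,
                     prop_hidden = 4L, beta = 0.3, tau = 0.7)
  x <- matrix(rnorm(12), 2); y <- matrix(rnorm(6), 2)
  eps <- matrix(rnorm(4), 2)
  jl <- joint_loss(model, x, y, eps = eps)
  ge <- encode_structure(model, x)
  gp <- encode_properties(model, y)
  z <- ge$mu + ge$sigma * eps
  xhat <- mlp_forward(model$dec, z)$out
  kl <- recon <- pnll <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      kl <- kl + 0.25 * (ge$mu[i, j]^2 + ge$sigma[i, j]^2 - 1 -
                           2 * log(ge$sigma[i, j]))
      pnll <- pnll + 0.25 * ((z[i, j] - gp$mu[i, j])^2 + log(2 * pi))
    }
    for (j in 1:6)
      recon <- recon + 0.5 * ((x[i, j] - xhat[i, j])^2 + log(2 * pi)) / 2
  }
  expect_equal(jl$kl, kl, tolerance = 1e-12)
  expect_equal(jl$recon, recon, tolerance = 1e-12)
  expect_equal(jl$prop_nll, pnll, tolerance = 1e-12)
  expect_equal(jl$total, 0.3 * kl + recon + 0.7 * pnll, tolerance = 1e-12)
})

test_that("reparameterized samples have the encoder's moments", {
  set.seed(85)
  model <- inverse_model(8L, 3L, latent = 2L, enc_hidden = 6L, dec_hidden = 6L,
                     prop_hidden = 4L)
  g <- encode_structure(model, rnorm(8))
  n <- 1e5
  eps <- matrix(rnorm(n * 2), n)
  z <- sweep(sweep(eps, 2, as.numeric(g$sigma), `*`), 2, as.numeric(g$mu), `+`)
  for (j in 1:2) {
    se_mean <- g$sigma[1, j] / sqrt(n)
    expect_lt(abs(mean(z[, j]) - g$mu[1, j]), 3 * se_mean)
    se_var <- g$sigma[1, j]^2 * sqrt(2 / (n - 1))
    expect_lt(abs(var(z[, j]) - g$sigma[1, j]^2), 3 * se_var)
  }
})

test_that("masks have the stated expectations and leak on padding", {
  set.seed(86)
  L <- 8L
  n <- 1e5
  b <- matrix(rbinom(n * L, 1L, 0.5), n)
  diag_mean <- mean(2 * b[, 3]^2)
  off_mean <- mean(2 * b[, 2] * b[, 5])
  expect_lt(abs(diag_mean - 1.0), 0.01)
  expect_lt(abs(off_mean - 0.5), 0.01)
  # the same law as make_mask: spot-check one draw against outer()
  set.seed(87)
  m <- make_mask(L)
  set.seed(87)
  b1 <- rbinom(L, 1L, 0.5)
  expect_identical(m, 2 * outer(b1, b1))
  # padding entries are exactly the leak value wherever the target is zero
  target <- matrix(0, L, L)
  target[1:3, 1:3] <- 1
  mm <- make_mask(L, target = target)
  expect_true(all(mm[target == 0] == 0.1))
})

test_that("masked reconstruction loss reduces correctly at the mask limits", {
  set.seed(88)
  model <- inverse_model(6L, 3L, latent = 2L, enc_hidden = 5L, dec_hidden = 5L,
                     prop_hidden = 4L)
  model$layout <- cm_layout(c(1L, 1L, 1L))  # L = 3, vector length 6
  x <- matrix(rnorm(12), 2); y <- matrix(rnorm(6), 2)
  eps <- matrix(rnorm(4), 2)
  ones <- list(matrix(1, 3, 3), matrix(1, 3, 3))
  jl_plain <- joint_loss(model, x, y, eps = eps)
  jl_ones <- joint_loss(model, x, y, eps = eps,
                        mask_w = mask_to_weights(ones))
  expect_equal(jl_ones$recon, jl_plain$recon, tolerance = 1e-10)
  z <- with(encode_structure(model, x), mu + sigma * eps)
  expect_equal(masked_reconstruction_loss(model, x, z,
                                          list(matrix(0, 3, 3),
                                               matrix(0, 3, 3))), 0)
  # checkerboard on a 2x2 toy: only the selected entries contribute
  m2 <- inverse_model(3L, 2L, latent = 2L, enc_hidden = 4L, dec_hidden = 4L,
                  prop_hidden = 4L)
  x2 <- matrix(rnorm(3), 1)
  z2 <- matrix(rnorm(2), 1)
  cb <- matrix(c(1, 0, 0, 1), 2)  # selects both diagonal entries
  got <- masked_reconstruction_loss(m2, x2, z2, list(cb))
  xhat <- mlp_forward(m2$dec, z2)$out
  want <- 0.5 * (x2[1] - xhat[1])^2 + 0.5 * log(2 * pi) +
    0.5 * (x2[3] - xhat[3])^2 + 0.5 * log(2 * pi)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("training is deterministic, reduces the loss, and leaves the
           property encoder untouched when tau = 0", {
  ds <- make_dataset(synthetic_spec(n = 200, seed = 91))
  m1 <- fit_inverse_model(ds, epochs = 30L, batch = 64L, seed = 9,
                  enc_hidden = c(32L, 32L), dec_hidden = c(32L, 32L),
                  prop_hidden = c(16L, 16L), latent = 8L)
  m2 <- fit_inverse_model(ds, epochs = 30L, batch = 64L, seed = 9,
                  enc_hidden = c(32L, 32L), dec_hidden = c(32L, 32L),
                  prop_hidden = c(16L, 16L), latent = 8L)
  expect_identical(m1$history, m2$history)
  expect_lt(m1$history$val_total[30], m1$history$val_total[1])
  m3 <- fit_inverse_model(ds, epochs = 5L, batch = 64L, seed = 9, tau = 0,
                  enc_hidden = c(16L,16L), dec_hidden = c(16L, 16L),
                  prop_hidden = c(16L, 16L), latent = 4L)
  set.seed(9)
  init <- inverse_model(ncol(ds$cm), 17L, latent = 4L,
                    enc_hidden = c(16L, 16L), dec_hidden = c(16L, 16L),
                    prop_hidden = c(16L, 16L))
  # same seed -> same init; zero gradient -> no update (dimnames aside)
  expect_equal(m3$prop$W, init$prop$W, ignore_attr = TRUE,
               tolerance = 1e-15)
})

test_that("property-to-structure inference is deterministic and emits a
           valid padded matrix even from an untrained model", {
  fix <- trained_fixture()
  y <- fix$dataset$properties[3, ]
  r1 <- property_to_structure(fix$model, y)
  r2 <- property_to_structure(fix$model, y)
  expect_identical(r1$molecule, r2$molecule)
  # untrained model: the decoded object still satisfies the container
  # contract (symmetric, right size) even though its content is garbage
  set.seed(92)
  raw <- inverse_model(ncol(fix$dataset$cm), 17L, layout = fix$dataset$layout,
                   prop_set = colnames(fix$dataset$properties))
  dec <- property_to_structure(raw, y, invert = FALSE)
  expect_s3_class(dec$padded, "padded_cm")
  expect_identical(dec$padded$matrix, t(dec$padded$matrix))
  expect_equal(dim(dec$padded$matrix),
               rep(fix$dataset$layout$size, 2L))
})

test_that("self-consistency is zero for a perfect inverse and nonnegative
           in general", {
  # identity decoder + identity structure-encoder mean: z_tilde == z
  model <- inverse_model(2L, 2L, latent = 2L, enc_hidden = 4L, dec_hidden = 4L,
                     prop_hidden = 4L)
  model$dec <- mlp_new(c(2L, 2L)); model$dec$W[[1]] <- diag(2)
  model$dec$b[[1]] <- numeric(2)
  model$enc <- mlp_new(c(2L, 4L)); model$enc$W[[1]] <- cbind(diag(2), 0, 0)
  model$enc$b[[1]] <- numeric(4)
  expect_equal(self_consistency_delta(model, c(0.3, -0.8)), 0,
               tolerance = 1e-12)
  fix <- trained_fixture()
  dz <- vapply(1:20, function(i)
    self_consistency_delta(fix$model, fix$dataset$properties[i, ]),
    numeric(1))
  expect_true(all(dz >= 0))
})
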