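# Shared fixtures: random molecules, tiny trained models, linear model stubs.

# a random well-separated molecule with n atoms from the CNO set
random_molecule <- function(n = 5L, elements = c(6L, 7L, 8L)) {
  spec <- synthetic_spec(n = 1L, max_atoms = n, elements = elements)
  repeat {
    m <- sample_molecule(spec)
    if (length(m$species) == n) return(m)
  }
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# replace a model's networks by bias-free single linear layers with known
# weights: the property->structure path becomes exactly x = y W_mu W_dec
linearized_model <- function(d_x = 5L, d_y = 3L, latent = 2L,
                             w_mu = NULL, w_dec = NULL) {
  model <- inverse_model(d_x, d_y, latent = latent, enc_hidden = 4L,
                     dec_hidden = 4L, prop_hidden = 4L)
  if (is.null(w_mu)) w_mu <- matrix(seq_len(d_y * latent) / 10, d_y, latent)
  if (is.null(w_dec)) w_dec <- matrix(sin(seq_len(latent * d_x)), latent, d_x)
  model$prop <- mlp_new(c(d_y, 2L * latent))
  model$prop$W[[1]] <- cbind(w_mu, matrix(0, d_y, latent))
  model$prop$b[[1]] <- numeric(2L * latent)
  model$dec <- mlp_new(c(latent, d_x))
  model$dec$W[[1]] <- w_dec
  model$dec$b[[1]] <- numeric(d_x)
  model$w_mu <- w_mu
  model$w_dec <- w_dec
  model
}

# small trained model + dataset, cached per test session (used by several
# files; sizes chosen so training takes a few seconds)
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- make_dataset(synthetic_spec(n = 500L, seed = 101L))
      model <- fit_inverse_model(ds, epochs = 250L, lr = 2e-3, batch = 64L,
                         seed = 5L)
      cache <<- list(dataset = ds, model = model)
    }
    cache
  }
})
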