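# small dimensions throughout: correctness of the machinery, not capacity
.tiny_cfg <- function(...) {
  model_config(embedding_dim = 3L, latent_dim = 2L, hidden_dim = 4L,
               recurrent_dropout = 0, learning_rate = 1e-2, epochs = 5L,
               batch_size = 2L, seed = 7L, ...)
}

.tiny_weights <- function(V = 6L, cfg = .tiny_cfg()) {
  set.seed(cfg$seed)
  rxnvae:::vae_init(V, cfg)
}

test_that("model_config validates its fields", {
  expect_identical(model_config()$embedding_dim, 500L)
  expect_identical(model_config()$latent_dim, 350L)
  expect_identical(model_config()$hidden_dim, 500L)
  expect_equal(model_config()$recurrent_dropout, 0.2)
  expect_equal(model_config()$kl_weight, 0.1)
  expect_equal(model_config()$learning_rate, 1e-5)
  expect_identical(model_config()$epochs, 500L)
  expect_identical(model_config()$batch_size, 25L)
  expect_error(model_config(latent_dim = 0), class = "rxnvae_config_error")
  expect_error(model_config(recurrent_dropout = 1), class = "rxnvae_config_error")
  expect_error(model_config(kl_weight = -0.1), class = "rxnvae_config_error")
})

test_that("closed-form loss identities hold exactly", {
  cfg <- .tiny_cfg()
  V <- 6L
  W <- .tiny_weights(V, cfg)
  # force the latent heads to produce mu = 0, logvar = 0 for any input
  W0 <- W
  W0$W_mu[] <- 0; W0$b_mu[] <- 0; W0$W_lv[] <- 0; W0$b_lv[] <- 0
  x <- matrix(c(1L, 2L, 3L, 0L), 1, 4)
  r <- vae_loss(W0, x, kl_weight = 1)
  expect_identical(r$kl, 0)
  expect_identical(r$total, r$reconstruction)

  # one latent dimension at mu = 1, logvar = 0 contributes exactly 0.5
  W1 <- W0
  W1$b_mu[1, 1] <- 1
  expect_equal(vae_loss(W1, x, kl_weight = 1)$kl, 0.5, tolerance = 1e-12)

  # a reconstruction that puts probability ~1 on every correct symbol has
  # cross-entropy ~0: drive the output projection to near-one-hot via the bias
  Wp <- W0
  Wp$Wx_d[] <- 0; Wp$Wh_d[] <- 0; Wp$b_d[] <- -50  # freeze decoder state
  Wp$W_out[] <- 0
  const <- matrix(1L, 1, 4)  # constant sequence of code 1
  Wp$b_out[] <- -1000; Wp$b_out[1, 2] <- 1000      # all mass on code 1
  r2 <- vae_loss(Wp, const, kl_weight = 1)
  expect_equal(r2$reconstruction, 0, tolerance = 1e-9)
})

test_that("analytic gradients match finite differences", {
  cfg <- .tiny_cfg()
  V <- 5L
  W <- .tiny_weights(V, cfg)
  set.seed(11)
  B <- 3L; T <- 4L
  X <- matrix(sample(0:(V - 1L), B * T, replace = TRUE), B, T)
  eps <- matrix(rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
  masks <- replicate(3, matrix(sample(c(0, 1.25), B * cfg$hidden_dim,
                                      replace = TRUE),
                               B, cfg$hidden_dim), simplify = FALSE)
  r <- rxnvae:::cpp_vae_loss_grad(W, X, eps, 0.3, masks[[1]], masks[[2]],
                                  masks[[3]], TRUE)
  h <- 1e-6
  loss_at <- function(Wmod) {
    rxnvae:::cpp_vae_loss_grad(Wmod, X, eps, 0.3, masks[[1]], masks[[2]],
                               masks[[3]], FALSE)$total
  }
  for (nm in names(r$grads)) {
    g <- r$grads[[nm]]
    for (k in sample(length(g), min(5L, length(g)))) {
      Wp <- W; Wp[[nm]][k] <- Wp[[nm]][k] + h
      Wm <- W; Wm[[nm]][k] <- Wm[[nm]][k] - h
      num <- (loss_at(Wp) - loss_at(Wm)) / (2 * h)
      expect_equal(g[k], num, tolerance = 5e-4,
                   label = sprintf("d(loss)/d(%s[%d])", nm, k))
    }
  }
})

test_that("encode/decode are deterministic pure functions with contract shapes", {
  cfg <- .tiny_cfg()
  V <- 6L
  W <- .tiny_weights(V, cfg)
  x <- matrix(c(1L, 4L, 2L, 0L, 0L), 1, 5)
  e1 <- vae_encode(W, x)
  e2 <- vae_encode(W, x)
  expect_identical(e1, e2)
  expect_identical(dim(e1$mean), c(1L, cfg$latent_dim))
  expect_identical(dim(e1$log_variance), c(1L, cfg$latent_dim))
  expect_true(all(is.finite(e1$mean)), all(is.finite(e1$log_variance)))

  z <- matrix(rnorm(2 * cfg$latent_dim, sd = 2), 2)
  d1 <- vae_decode(W, z, n_max = 7, probs = TRUE)
  d2 <- vae_decode(W, z, n_max = 7, probs = TRUE)
  expect_identical(d1, d2)
  expect_identical(dim(d1$codes), c(2L, 7L))
  expect_true(all(d1$codes >= 0 & d1$codes < V))
  # each position's distribution sums to 1
  sums <- apply(d1$probs, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # argmax of probs equals the greedy codes
  am <- apply(d1$probs, c(1, 3), which.max) - 1L
  expect_identical(t(am), matrix(d1$codes, 2L, 7L))
})

test_that("reparameterization has the right moments and limits", {
  mu <- matrix(1, 1, 4)
  lv <- matrix(0, 1, 4)
  latent <- list(mean = mu, log_variance = lv)
  expect_identical(reparameterize(latent, eps = matrix(0, 1, 4)), mu)
  # logvar -> -Inf limit collapses to the mean
  collapsed <- reparameterize(list(mean = mu, log_variance = mu * 0 - 1e6),
                              seed = 4)
  expect_equal(collapsed, mu, tolerance = 1e-12)
  set.seed(13)
  draws <- replicate(2e4, reparameterize(latent,
                                         eps = matrix(rnorm(4), 1, 4))[1, 1])
  expect_equal(mean(draws), 1, tolerance = 0.03)
  expect_equal(var(draws), 1, tolerance = 0.05)
})

test_that("a single example is memorized with kl_weight 0", {
  s <- "O=C=O + 2[H][H] >> C=O + O"
  vocab <- build_vocabulary(s)
  cfg <- model_config(embedding_dim = 16L, latent_dim = 8L, hidden_dim = 16L,
                      kl_weight = 0, learning_rate = 2e-2, epochs = 600L,
                      batch_size = 1L, recurrent_dropout = 0, seed = 3L)
  m <- vae_train(s, vocab, cfg)
  expect_identical(reconstruction_accuracy(m, s), 1)
  expect_true(all(is.finite(m$metrics$total)))
  # loss is (noisily) decreasing: final well below initial
  expect_lt(tail(m$metrics$total, 1), 0.2 * m$metrics$total[1])
})

test_that("reconstruction_accuracy equals an external string comparison", {
  corpus <- generate_corpus(generator_config(n_equations = 20, seed = 14))$lines
  vocab <- build_vocabulary(corpus)
  cfg <- model_config(embedding_dim = 8L, latent_dim = 4L, hidden_dim = 8L,
                      recurrent_dropout = 0, epochs = 1L, batch_size = 10L,
                      learning_rate = 1e-3, seed = 5L)
  m <- vae_train(corpus, vocab, cfg)
  enc <- vae_encode(m$weights, encode_corpus(corpus, vocab))
  dec <- vae_decode(m$weights, enc$mean, vocab$n_max)
  manual <- mean(vapply(seq_along(corpus), function(i) {
    decode_sequence(dec$codes[i, ], vocab) == corpus[i]
  }, TRUE))
  expect_identical(reconstruction_accuracy(m, corpus), manual)
  # an untrained model on a ~15-symbol alphabet reconstructs ~nothing
  expect_lt(manual, 0.2)
})

test_that("checkpoints round-trip weights, vocabulary and config", {
  corpus <- generate_corpus(generator_config(n_equations = 15, seed = 2))$lines
  vocab <- build_vocabulary(corpus)
  cfg <- model_config(embedding_dim = 6L, latent_dim = 3L, hidden_dim = 6L,
                      epochs = 1L, batch_size = 5L, recurrent_dropout = 0,
                      learning_rate = 1e-3, seed = 9L)
  m <- vae_train(corpus, vocab, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_identical(m2$vocab$chars, m$vocab$chars)
  expect_identical(m2$vocab$n_max, m$vocab$n_max)
  expect_identical(m2$config$latent_dim, cfg$latent_dim)
  # identical encodes through the reloaded model
  X <- encode_corpus(corpus[1:3], vocab)
  expect_equal(vae_encode(m2$weights, X), vae_encode(m$weights, X),
               tolerance = 1e-12)
  expect_error(load_checkpoint(withr::local_tempfile()), class = "rxnvae_config_error")
})

test_that("training is reproducible under a fixed master seed", {
  corpus <- generate_corpus(generator_config(n_equations = 20, seed = 6))$lines
  vocab <- build_vocabulary(corpus)
  cfg <- model_config(embedding_dim = 6L, latent_dim = 3L, hidden_dim = 6L,
                      epochs = 3L, batch_size = 5L, learning_rate = 1e-3,
                      seed = 17L)
  m1 <- vae_train(corpus, vocab, cfg)
  m2 <- vae_train(corpus, vocab, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$metrics, m2$metrics)
})
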