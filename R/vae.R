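# R-facing surface of the sequence VAE. The numerics live in src/vae.cpp; this
# file owns configuration, initialization, the Adam training loop, inference
# wrappers, and the self-describing checkpoint archive (weights + vocabulary +
# config + seed travel together so generation can never run against a
# mismatched alphabet).

stop_model <- function(msg) stop_rxnvae(msg, "rxnvae_model_error")

.PARAM_NAMES <- c("Emb", "Wx_f", "Wh_f", "b_f", "Wx_b", "Wh_b", "b_b",
                  "W_mu", "b_mu", "W_lv", "b_lv",
                  "Wx_d", "Wh_d", "b_d", "W_out", "b_out")

#' Model configuration
#'
#' Defaults are the published training setup of the method this package
#' implements: embedding dimension 500, latent dimension 350, recurrent
#' dropout 0.2, KL weight 0.1, Adam with learning rate 1e-5, 500 epochs,
#' batch size 25. `hidden_dim` (the LSTM state size) is not stated in the
#' source and defaults to `embedding_dim`.
#'
#' @param embedding_dim character embedding dimension.
#' @param latent_dim latent space dimension.
#' @param hidden_dim LSTM hidden state size (default = `embedding_dim`).
#' @param recurrent_dropout recurrent (variational) dropout fraction in \[0,1).
#' @param kl_weight weight of the KL term in the loss.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param grad_clip global gradient-norm clip (0 disables); standard guard
#'   that lets recurrent nets train at practical learning rates.
#' @param lr_decay_at epochs at which the learning rate is multiplied by
#'   `lr_decay_factor` (step schedule; empty = constant rate).
#' @param lr_decay_factor multiplier applied at each epoch in `lr_decay_at`.
#' @param kl_anneal_epochs linearly ramp the KL weight from 0 to `kl_weight`
#'   over this many initial epochs (0 = constant weight). Standard sequence-VAE
#'   practice to avoid early posterior collapse; the final weight is always
#'   `kl_weight`.
#' @param seed master seed for initialization, shuffling, dropout and
#'   reparameterization noise.
#' @return a `rxnvae_config` list.
#' @export
model_config <- function(embedding_dim = 500L, latent_dim = 350L,
                         hidden_dim = embedding_dim,
                         recurrent_dropout = 0.2, kl_weight = 0.1,
                         learning_rate = 1e-5, epochs = 500L, batch_size = 25L,
                         grad_clip = 5, lr_decay_at = integer(0),
                         lr_decay_factor = 0.3, kl_anneal_epochs = 0L,
                         seed = 1L) {
  cfg <- list(
    embedding_dim = as.integer(embedding_dim),
    latent_dim = as.integer(latent_dim),
    hidden_dim = as.integer(hidden_dim),
    recurrent_dropout = recurrent_dropout,
    kl_weight = kl_weight,
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    grad_clip = grad_clip,
    lr_decay_at = as.integer(lr_decay_at),
    lr_decay_factor = lr_decay_factor,
    kl_anneal_epochs = as.integer(kl_anneal_epochs),
    seed = as.integer(seed)
  )
  if (any(c(cfg$embedding_dim, cfg$latent_dim, cfg$hidden_dim) < 1L)) {
    stop_config("all dimensions must be >= 1")
  }
  if (cfg$recurrent_dropout < 0 || cfg$recurrent_dropout >= 1) {
    stop_config("recurrent_dropout must be in [0, 1)")
  }
  if (cfg$kl_weight < 0) stop_config("kl_weight must be >= 0")
  structure(cfg, class = "rxnvae_config")
}

# Glorot-uniform input weights, orthogonal recurrent weights (per gate), and
# forget-gate bias 1 — standard LSTM initialization practice
vae_init <- function(vocab_size, config) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  ortho <- function(n) {
    qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  }
  E <- config$embedding_dim; H <- config$hidden_dim; L <- config$latent_dim
  V <- vocab_size
  lstm_Wh <- function() do.call(cbind, lapply(1:4, function(i) ortho(H)))
  lstm_b <- function() {
    b <- matrix(0, 1, 4 * H)
    b[1, (H + 1):(2 * H)] <- 1
    b
  }
  W <- list(
    Emb = glorot(V, E),
    Wx_f = glorot(E, 4 * H), Wh_f = lstm_Wh(), b_f = lstm_b(),
    Wx_b = glorot(E, 4 * H), Wh_b = lstm_Wh(), b_b = lstm_b(),
    W_mu = glorot(2 * H, L), b_mu = matrix(0, 1, L),
    W_lv = glorot(2 * H, L), b_lv = matrix(0, 1, L),
    Wx_d = glorot(L, 4 * H), Wh_d = lstm_Wh(), b_d = lstm_b(),
    W_out = glorot(H, V), b_out = matrix(0, 1, V)
  )
  W[.PARAM_NAMES]
}

.dropout_mask <- function(n, h, p) {
  if (p <= 0) return(matrix(1, n, h))
  matrix(ifelse(stats::runif(n * h) < p, 0, 1 / (1 - p)), n, h)
}

#' Loss of the VAE on a batch
#'
#' `reconstruction` is the per-sequence sum of per-position categorical
#' cross-entropies (mean over the batch, pads included); `kl` is the closed
#' form KL(N(mu, sigma^2) || N(0, 1)) summed over latent dimensions (mean over
#' batch); `total = reconstruction + kl_weight * kl`.
#'
#' @param weights parameter list (see [vae_init()] / [load_checkpoint()]).
#' @param x integer code matrix (rows = sequences) with 0 = pad.
#' @param eps reparameterization noise matrix (defaults to zero: decode the
#'   mean).
#' @param kl_weight KL weight.
#' @return list `total`, `reconstruction`, `kl`.
#' @export
vae_loss <- function(weights, x, eps = NULL, kl_weight = 0.1) {
  x <- .as_code_matrix(x)
  L <- ncol(weights$W_mu)
  H <- nrow(weights$Wh_f)
  if (is.null(eps)) eps <- matrix(0, nrow(x), L)
  ones <- matrix(1, nrow(x), H)
  r <- cpp_vae_loss_grad(weights, x, eps, kl_weight, ones, ones, ones, FALSE)
  list(total = r$total, reconstruction = r$recon, kl = r$kl)
}

.as_code_matrix <- function(x) {
  if (is.vector(x)) x <- matrix(as.integer(x), nrow = 1)
  storage.mode(x) <- "integer"
  x
}

#' Encode sequences to their latent distributions
#'
#' Deterministic at inference: dropout is off, so identical inputs give
#' identical distributions.
#'
#' @param weights parameter list.
#' @param x integer code matrix or vector.
#' @return list of matrices `mean` and `log_variance` (rows = inputs).
#' @export
vae_encode <- function(weights, x) {
  x <- .as_code_matrix(x)
  if (ncol(weights$Emb) != nrow(weights$Wx_f)) stop_model("corrupt weights")
  cpp_vae_encode(weights, x)
}

#' Sample a latent point from a latent distribution
#'
#' The reparameterization `z = mean + exp(log_variance / 2) * eps` with
#' standard-normal `eps`.
#'
#' @param latent list with `mean` and `log_variance` matrices.
#' @param seed optional seed for the draw.
#' @param eps optional explicit noise matrix (overrides the draw; `eps = 0`
#'   returns the mean exactly).
#' @return matrix of latent points.
#' @export
reparameterize <- function(latent, seed = NULL, eps = NULL) {
  mu <- latent$mean
  lv <- latent$log_variance
  stopifnot(all(dim(mu) == dim(lv)), all(is.finite(mu)), all(is.finite(lv)))
  if (is.null(eps)) {
    if (!is.null(seed)) set.seed(seed)
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  mu + exp(lv / 2) * eps
}

#' Decode latent points to per-position character distributions
#'
#' The latent vector is repeated for every output position and run through the
#' decoder LSTM; the decoder is non-autoregressive (position t does not see
#' emitted symbols). Greedy per-position argmax is the default decoding rule;
#' `temperature > 0` switches to temperature sampling of each position.
#'
#' @param weights parameter list.
#' @param z latent point matrix (rows = points) or single vector.
#' @param n_max output length.
#' @param probs return the full probability array (`n_max` x alphabet x point).
#' @param temperature 0 = greedy argmax; otherwise softmax temperature for
#'   per-position sampling (requires `probs` computation internally).
#' @return list with `codes` (matrix of 0-based codes incl. pad) and
#'   optionally `probs`.
#' @export
vae_decode <- function(weights, z, n_max, probs = FALSE, temperature = 0) {
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  if (ncol(z) != nrow(weights$Wx_d)) stop_model("latent dimension mismatch")
  want_probs <- probs || temperature > 0
  r <- cpp_vae_decode(weights, z, as.integer(n_max), want_probs)
  if (temperature > 0) {
    P <- r$probs
    codes <- r$codes
    for (b in seq_len(dim(P)[3])) {
      for (s in seq_len(dim(P)[1])) {
        p <- P[s, , b]^(1 / temperature)
        codes[b, s] <- sample.int(length(p), 1, prob = p / sum(p)) - 1L
      }
    }
    r$codes <- codes
  }
  if (!probs) r$probs <- NULL
  r
}

#' Train the VAE
#'
#' Seeded Adam over shuffled minibatches. Reproducible for a fixed seed: the
#' master seed drives initialization, shuffling, dropout masks and
#' reparameterization noise. Training aborts with a diagnostic if the loss
#' stops being finite.
#'
#' @param split a `rxnvae_split` (from [split_dataset()]) or a plain character
#'   vector of training strings.
#' @param vocab `rxnvae_vocab` built on the corpus.
#' @param config `rxnvae_config`.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return object of class `rxnvae_model`: `weights`, `vocab`, `config`,
#'   `metrics` (data.frame epoch/total/reconstruction/kl/val_accuracy).
#' @export
vae_train <- function(split, vocab, config, verbose = 0L) {
  train_strings <- if (inherits(split, "rxnvae_split")) split$train else split
  val_strings <- if (inherits(split, "rxnvae_split")) split$validation else character(0)
  if (length(train_strings) == 0L) stop_config("empty training split")

  X <- encode_corpus(train_strings, vocab)
  Xval <- if (length(val_strings)) encode_corpus(val_strings, vocab) else NULL
  V <- length(vocab$chars) + 1L
  n <- nrow(X)

  set.seed(config$seed)
  W <- vae_init(V, config)
  adam_m <- lapply(W, function(w) array(0, dim(w)))
  adam_v <- lapply(W, function(w) array(0, dim(w)))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0L
  p <- config$recurrent_dropout
  H <- config$hidden_dim
  Ldim <- config$latent_dim

  metrics <- data.frame(epoch = integer(0), total = numeric(0),
                        reconstruction = numeric(0), kl = numeric(0),
                        val_accuracy = numeric(0))

  lr <- config$learning_rate
  for (epoch in seq_len(config$epochs)) {
    if (epoch %in% config$lr_decay_at) lr <- lr * config$lr_decay_factor
    klw <- if (config$kl_anneal_epochs > 0L) {
      config$kl_weight * min(1, epoch / config$kl_anneal_epochs)
    } else config$kl_weight
    perm <- sample.int(n)
    tot_e <- rec_e <- kl_e <- 0
    nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      B <- nrow(xb)
      eps <- matrix(stats::rnorm(B * Ldim), B, Ldim)
      mf <- .dropout_mask(B, H, p)
      mb <- .dropout_mask(B, H, p)
      md <- .dropout_mask(B, H, p)
      r <- cpp_vae_loss_grad(W, xb, eps, klw, mf, mb, md, TRUE)
      if (!is.finite(r$total)) {
        stop_model(sprintf(
          "training diverged at epoch %d (loss %g); lower the learning rate",
          epoch, r$total
        ))
      }
      t_step <- t_step + 1L
      g <- r$grads
      if (config$grad_clip > 0) {
        gnorm <- sqrt(sum(vapply(g, function(x) sum(x^2), 0)))
        if (gnorm > config$grad_clip) {
          g <- lapply(g, function(x) x * (config$grad_clip / gnorm))
        }
      }
      for (nm in .PARAM_NAMES) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - beta1^t_step)
        vhat <- adam_v[[nm]] / (1 - beta2^t_step)
        W[[nm]] <- W[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
      tot_e <- tot_e + r$total; rec_e <- rec_e + r$recon; kl_e <- kl_e + r$kl
      nb <- nb + 1L
    }
    model_now <- list(weights = W, vocab = vocab, config = config)
    val_acc <- if (!is.null(Xval)) {
      .reconstruction_accuracy_codes(model_now, Xval, val_strings)
    } else NA_real_
    metrics <- rbind(metrics, data.frame(
      epoch = epoch, total = tot_e / nb, reconstruction = rec_e / nb,
      kl = kl_e / nb, val_accuracy = val_acc
    ))
    if (verbose > 0L && (epoch %% verbose == 0L || epoch == config$epochs)) {
      message(sprintf("epoch %4d  total %8.4f  recon %8.4f  kl %8.4f  val %s",
                      epoch, tot_e / nb, rec_e / nb, kl_e / nb,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  }
  structure(list(weights = W, vocab = vocab, config = config, metrics = metrics),
            class = "rxnvae_model")
}

#' @export
print.rxnvae_model <- function(x, ...) {
  cat(sprintf(
    "<vae model> alphabet %d+pad, n_max %d, embedding %d, hidden %d, latent %d\n",
    length(x$vocab$chars), x$vocab$n_max, x$config$embedding_dim,
    x$config$hidden_dim, x$config$latent_dim
  ))
  if (nrow(x$metrics)) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  trained %d epochs; final total %.4f (recon %.4f, kl %.4f)\n",
                last$epoch, last$total, last$reconstruction, last$kl))
  }
  invisible(x)
}

.reconstruction_accuracy_codes <- function(model, X, strings) {
  enc <- cpp_vae_encode(model$weights, X)
  dec <- cpp_vae_decode(model$weights, enc$mean, model$vocab$n_max, FALSE)
  out <- vapply(seq_len(nrow(dec$codes)), function(i) {
    decode_sequence(dec$codes[i, ], model$vocab)
  }, "")
  mean(out == strings)
}

#' Exact-reconstruction rate
#'
#' Fraction of strings whose greedy decode of the encoded latent *mean*
#' reproduces the source string exactly — the lossless-compression validation
#' used during training.
#'
#' @param model `rxnvae_model` (or list with `weights` and `vocab`).
#' @param strings character vector of equations to test.
#' @return fraction in \[0, 1\].
#' @export
reconstruction_accuracy <- function(model, strings) {
  X <- encode_corpus(strings, model$vocab)
  .reconstruction_accuracy_codes(model, X, strings)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing JSON archive holding the weights
#' together with the vocabulary, configuration and seed.
#'
#' @param model `rxnvae_model`.
#' @param path checkpoint path (`.json`).
#' @return `path` (save) / `rxnvae_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = "rxnvae-checkpoint-1",
    config = unclass(model$config),
    vocab = list(chars = model$vocab$chars, pad_code = model$vocab$pad_code,
                 n_max = model$vocab$n_max),
    weights = lapply(model$weights, function(w) {
      list(dim = dim(w), data = as.numeric(w))
    }),
    metrics = if (!is.null(model$metrics)) model$metrics else NULL
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_config(paste0("no such checkpoint: ", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "rxnvae-checkpoint-1")) {
    stop_config("not a rxnvae checkpoint")
  }
  weights <- lapply(p$weights, function(w) {
    matrix(w$data, w$dim[1], w$dim[2])
  })[.PARAM_NAMES]
  vocab <- structure(list(chars = p$vocab$chars, pad_code = as.integer(p$vocab$pad_code),
                          n_max = as.integer(p$vocab$n_max)), class = "rxnvae_vocab")
  config <- do.call(model_config, as.list(p$config))
  structure(list(weights = weights, vocab = vocab, config = config,
                 metrics = p$metrics), class = "rxnvae_model")
}
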