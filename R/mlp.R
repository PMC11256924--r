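# Minimal feed-forward network used by the binding-affinity classifier:
# fully-connected layers with rectifier activations and a sigmoid output,
# trained by mini-batch Adam on the cross-entropy loss. Kept deliberately
# small and dependency-free so training is fast and bit-reproducible under
# a single RNG seed.

mlp_init <- function(d_in, hidden) {
  sizes <- c(d_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                 sd = sqrt(2 / sizes[i])),
                    nrow = sizes[i]),
         b = numeric(sizes[i + 1L]))
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers))
  A <- X
  for (i in seq_along(layers)) {
    Z <- sweep(A %*% layers[[i]]$W, 2L, layers[[i]]$b, `+`)
    A <- if (i < length(layers)) pmax(Z, 0) else 1 / (1 + exp(-Z))
    acts[[i]] <- A
  }
  acts
}

mlp_predict <- function(layers, X) {
  as.numeric(mlp_forward(layers, X)[[length(layers)]])
}

# One Adam step on a mini-batch; returns updated layers + optimizer state.
mlp_step <- function(layers, state, X, y, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  L <- length(layers)
  acts <- mlp_forward(layers, X)
  n <- nrow(X)
  # output delta for sigmoid + cross-entropy
  delta <- (acts[[L]] - y) / n
  grads <- vector("list", L)
  for (i in L:1) {
    A_prev <- if (i == 1L) X else acts[[i - 1L]]
    grads[[i]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i - 1L]] > 0)
    }
  }
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_len(L)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (state$m[[i]][[p]] / corr1) /
        (sqrt(state$v[[i]][[p]] / corr2) + eps)
    }
  }
  list(layers = layers, state = state)
}

mlp_train <- function(X, y, hidden = c(64L, 32L), epochs = 12L,
                      batch_size = 256L, lr = 1e-3, seed = 1L) {
  set.seed(as.integer(seed))
  layers <- mlp_init(ncol(X), hidden)
  zeros <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  state <- list(m = zeros, v = zeros, t = 0L)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (off in seq(1L, n, by = batch_size)) {
      idx <- ord[off:min(off + batch_size - 1L, n)]
      upd <- mlp_step(layers, state, X[idx, , drop = FALSE], y[idx], lr)
      layers <- upd$layers
      state <- upd$state
    }
  }
  layers
}
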