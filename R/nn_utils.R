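# Small shared numerics for the hand-rolled neural models.
# Everything is plain dense/sparse matrix algebra on CPU; determinism
# comes from seeding R's RNG before initialization and batching.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# mean binary cross-entropy, clipped away from 0/1 for stability
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

glorot <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

# Adam optimizer over a named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Deterministic derived seeds: mix a base seed with stage indices,
# keeping the result a valid 32-bit R integer.
derive_seed <- function(base, ...) {
  ids <- c(base, ...)
  h <- 0
  for (k in ids) h <- (h * 1103515245 + 12345 + as.numeric(k)) %% 2147483647
  as.integer(h)
}

# Fixed, disjoint minibatch index sets after a seeded shuffle.
make_batches <- function(n, batch_size, seed) {
  set.seed(seed)
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}
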