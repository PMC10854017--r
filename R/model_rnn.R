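# One-layer recurrent sequence classifier over encoded visit vectors.
#
# Sequences (one encoded vector per visit, temporal order) are processed
# by a single gated recurrent (GRU) cell -- or a plain tanh cell -- and
# the final hidden state is mapped through an affine layer and a sigmoid
# to a revisit probability. Variable-length sequences in a batch are
# left-padded and masked, so every sequence ends at the last step and
# padding steps leave the hidden state untouched.

rnn_init_params <- function(input_width, hidden_width, seed,
                            cell = "gru") {
  set.seed(seed)
  p <- if (cell == "gru") {
    list(Wz = glorot(input_width, hidden_width), Uz = glorot(hidden_width, hidden_width),
         bz = numeric(hidden_width),
         Wr = glorot(input_width, hidden_width), Ur = glorot(hidden_width, hidden_width),
         br = numeric(hidden_width),
         Wh = glorot(input_width, hidden_width), Uh = glorot(hidden_width, hidden_width),
         bh = numeric(hidden_width))
  } else {
    list(W = glorot(input_width, hidden_width),
         U = glorot(hidden_width, hidden_width),
         b = numeric(hidden_width))
  }
  p$w_out <- glorot(hidden_width, 1L)[, 1L]
  p$b_out <- 0
  p$cell <- cell
  p
}

# Left-pad a list of (len x d) matrices into per-step input matrices and
# an activity mask. Step t inputs are x[[t]] (B x d); mask[, t] is 1
# where the sequence has started.
pad_sequences <- function(seqs, d) {
  B <- length(seqs)
  lens <- vapply(seqs, nrow, 1L)
  T <- max(lens)
  x <- lapply(seq_len(T), function(t) matrix(0, B, d))
  mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    start <- T - lens[b] + 1L
    mask[b, start:T] <- 1
    for (t in seq_len(lens[b])) {
      x[[start + t - 1L]][b, ] <- seqs[[b]][t, ]
    }
  }
  list(x = x, mask = mask, T = T, B = B)
}

rnn_step_gru <- function(xt, h, params) {
  z <- sigmoid(sweep(xt %*% params$Wz + h %*% params$Uz, 2L, params$bz, "+"))
  r <- sigmoid(sweep(xt %*% params$Wr + h %*% params$Ur, 2L, params$br, "+"))
  hhat <- tanh(sweep(xt %*% params$Wh + (r * h) %*% params$Uh, 2L,
                     params$bh, "+"))
  list(h = (1 - z) * h + z * hhat, z = z, r = r, hhat = hhat)
}

rnn_step_tanh <- function(xt, h, params) {
  list(h = tanh(sweep(xt %*% params$W + h %*% params$U, 2L, params$b, "+")))
}

#' Forward pass of the one-layer recurrent sequence classifier
#'
#' Consumes encoded visit vectors in temporal order through a single
#' gated (GRU) or tanh recurrent cell; the final hidden state feeds an
#' affine map and sigmoid. With all-zero weights the output is 0.5. The
#' output is order-sensitive: reversing a non-palindromic sequence
#' changes the hidden state.
#'
#' @param sequences A single numeric matrix (one sequence, one encoded
#'   visit per row) or a list of such matrices.
#' @param params Parameter list from a fitted predictor (`$params`), or
#'   built by hand; must contain the cell weights, `w_out`, `b_out` and
#'   `cell` (`"gru"` or `"tanh"`).
#' @return Numeric vector of probabilities, one per sequence.
#' @export
rnn_forward <- function(sequences, params) {
  if (is.matrix(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0L || any(vapply(sequences, nrow, 1L) == 0L)) {
    stop("empty sequence", call. = FALSE)
  }
  d <- nrow(if (params$cell == "gru") params$Wz else params$W)
  if (ncol(sequences[[1L]]) != d) {
    stop("sequence width does not match parameters", call. = FALSE)
  }
  pad <- pad_sequences(sequences, d)
  h <- matrix(0, pad$B, length(params$w_out))
  for (t in seq_len(pad$T)) {
    st <- if (params$cell == "gru") rnn_step_gru(pad$x[[t]], h, params)
    else rnn_step_tanh(pad$x[[t]], h, params)
    m <- pad$mask[, t]
    h <- m * st$h + (1 - m) * h
  }
  as.numeric(sigmoid(h %*% params$w_out + params$b_out))
}

# Forward with caches + analytic backward (BPTT) for one padded batch.
rnn_grad <- function(pad, y, params) {
  B <- pad$B; T <- pad$T
  hw <- length(params$w_out)
  gru <- params$cell == "gru"
  h <- matrix(0, B, hw)
  cache <- vector("list", T)
  for (t in seq_len(T)) {
    st <- if (gru) rnn_step_gru(pad$x[[t]], h, params)
    else rnn_step_tanh(pad$x[[t]], h, params)
    m <- pad$mask[, t]
    cache[[t]] <- c(st, list(h_prev = h, m = m))
    h <- m * st$h + (1 - m) * h
  }
  p <- as.numeric(sigmoid(h %*% params$w_out + params$b_out))
  dlog <- (p - y) / B
  grads <- lapply(params[setdiff(names(params), "cell")], function(q) q * 0)
  grads$w_out <- as.numeric(crossprod(h, dlog))
  grads$b_out <- sum(dlog)
  dh <- outer(dlog, params$w_out)
  for (t in rev(seq_len(T))) {
    cc <- cache[[t]]
    m <- cc$m
    dnew <- dh * m          # gradient into this step's cell output
    dcarry <- dh * (1 - m)  # rows where the step was padding
    if (gru) {
      dz <- dnew * (cc$hhat - cc$h_prev)
      dhhat <- dnew * cc$z
      dh_prev <- dnew * (1 - cc$z)
      da_h <- dhhat * (1 - cc$hhat^2)
      grads$Wh <- grads$Wh + crossprod(pad$x[[t]], da_h)
      grads$Uh <- grads$Uh + crossprod(cc$r * cc$h_prev, da_h)
      grads$bh <- grads$bh + colSums(da_h)
      dru <- da_h %*% t(params$Uh)
      dr <- dru * cc$h_prev
      dh_prev <- dh_prev + dru * cc$r
      da_z <- dz * cc$z * (1 - cc$z)
      grads$Wz <- grads$Wz + crossprod(pad$x[[t]], da_z)
      grads$Uz <- grads$Uz + crossprod(cc$h_prev, da_z)
      grads$bz <- grads$bz + colSums(da_z)
      dh_prev <- dh_prev + da_z %*% t(params$Uz)
      da_r <- dr * cc$r * (1 - cc$r)
      grads$Wr <- grads$Wr + crossprod(pad$x[[t]], da_r)
      grads$Ur <- grads$Ur + crossprod(cc$h_prev, da_r)
      grads$br <- grads$br + colSums(da_r)
      dh_prev <- dh_prev + da_r %*% t(params$Ur)
    } else {
      da <- dnew * (1 - cc$h^2)
      grads$W <- grads$W + crossprod(pad$x[[t]], da)
      grads$U <- grads$U + crossprod(cc$h_prev, da)
      grads$b <- grads$b + colSums(da)
      dh_prev <- da %*% t(params$U)
    }
    dh <- dh_prev + dcarry
  }
  list(loss = bce_loss(p, y), grads = grads)
}

fit_rnn <- function(sequences, labels, cfg) {
  d <- ncol(sequences[[1L]])
  params <- rnn_init_params(d, cfg$hidden_width,
                            derive_seed(cfg$seed, 201L), cfg$rnn_cell)
  opt_names <- setdiff(names(params), "cell")
  state <- adam_init(params[opt_names])
  batches <- make_batches(length(sequences), cfg$batch_size,
                          derive_seed(cfg$seed, 202L))
  prepared <- lapply(batches, function(idx)
    list(pad = pad_sequences(sequences[idx], d), y = labels[idx]))
  loss_trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ep_loss <- 0
    for (b in prepared) {
      g <- rnn_grad(b$pad, b$y, params)
      upd <- adam_step(params[opt_names], g$grads, state, cfg$learning_rate)
      params[opt_names] <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + g$loss * length(b$y)
    }
    loss_trace[ep] <- ep_loss / length(sequences)
  }
  params$loss_trace <- loss_trace
  params
}
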