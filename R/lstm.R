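# A small LSTM language model over SMILES tokens, implemented with plain
# matrix algebra (batched over sequences) and trained with Adam. Scaled
# for desk-size corpora; layer sizes, depth and sequence length are all
# configurable.

new_lstm_params <- function(vocab_size, embedding_size, hidden_size,
                            n_layers, seed) {
  set.seed(seed)
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -0.08, 0.08), nr, nc)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    in_size <- if (l == 1) embedding_size else hidden_size
    b <- numeric(4 * hidden_size)
    # forget-gate bias starts positive (standard stabilization)
    b[(hidden_size + 1):(2 * hidden_size)] <- 1
    layers[[l]] <- list(W = u(4 * hidden_size, in_size + hidden_size), b = b)
  }
  list(E = u(vocab_size, embedding_size),
       layers = layers,
       Wo = u(vocab_size, hidden_size),
       bo = numeric(vocab_size))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One forward step through all layers. states: list per layer of
# list(h, c) matrices (hidden x batch). Returns logits and new states
# (plus per-layer caches when requested).
lstm_step <- function(params, x, states, keep_cache = FALSE) {
  H <- nrow(states[[1]]$h)
  caches <- if (keep_cache) vector("list", length(params$layers)) else NULL
  inp <- x
  for (l in seq_along(params$layers)) {
    W <- params$layers[[l]]$W
    b <- params$layers[[l]]$b
    h_prev <- states[[l]]$h
    c_prev <- states[[l]]$c
    xh <- rbind(inp, h_prev)
    z <- W %*% xh + b
    i <- sigmoid(z[1:H, , drop = FALSE])
    f <- sigmoid(z[(H + 1):(2 * H), , drop = FALSE])
    g <- tanh(z[(2 * H + 1):(3 * H), , drop = FALSE])
    o <- sigmoid(z[(3 * H + 1):(4 * H), , drop = FALSE])
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (keep_cache)
      caches[[l]] <- list(xh = xh, i = i, f = f, g = g, o = o,
                          c_prev = c_prev, tc = tc)
    states[[l]] <- list(h = h, c = cc)
    inp <- h
  }
  logits <- params$Wo %*% inp + params$bo
  list(logits = logits, states = states, caches = caches)
}

zero_states <- function(n_layers, hidden_size, batch) {
  rep(list(list(h = matrix(0, hidden_size, batch),
                c = matrix(0, hidden_size, batch))), n_layers)
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Forward + backward over one padded batch (seq matrix T x B of token
# ids). Returns loss (mean NLL per unmasked target token) and gradients.
lstm_batch_grad <- function(params, seqs, pad_id) {
  Tn <- nrow(seqs); B <- ncol(seqs)
  H <- nrow(params$layers[[1]]$W) / 4
  L <- length(params$layers)
  V <- nrow(params$E)
  states <- zero_states(L, H, B)
  cache_t <- vector("list", Tn - 1)
  probs_t <- vector("list", Tn - 1)
  mask_t <- vector("list", Tn - 1)
  n_tok <- 0
  loss <- 0
  for (t in seq_len(Tn - 1)) {
    ids <- seqs[t, ]
    x <- t(params$E[ids, , drop = FALSE])
    st <- lstm_step(params, x, states, keep_cache = TRUE)
    states <- st$states
    p <- softmax_cols(st$logits)
    target <- seqs[t + 1, ]
    mask <- target != pad_id
    n_tok <- n_tok + sum(mask)
    idx <- cbind(target[mask], which(mask))
    loss <- loss - sum(log(pmax(p[idx], 1e-12)))
    cache_t[[t]] <- list(ids = ids, caches = st$caches,
                         h_top = states[[L]]$h)
    probs_t[[t]] <- p
    mask_t[[t]] <- mask
  }

  grads <- list(E = matrix(0, V, ncol(params$E)),
                layers = lapply(params$layers, function(ly) {
                  list(W = matrix(0, nrow(ly$W), ncol(ly$W)),
                       b = numeric(length(ly$b)))
                }),
                Wo = matrix(0, V, H), bo = numeric(V))
  dh_next <- rep(list(matrix(0, H, B)), L)
  dc_next <- rep(list(matrix(0, H, B)), L)
  for (t in rev(seq_len(Tn - 1))) {
    p <- probs_t[[t]]
    target <- seqs[t + 1, ]
    mask <- mask_t[[t]]
    dlogits <- p
    idx <- cbind(target[mask], which(mask))
    dlogits[idx] <- dlogits[idx] - 1
    dlogits[, !mask] <- 0
    h_top <- cache_t[[t]]$h_top
    grads$Wo <- grads$Wo + dlogits %*% t(h_top)
    grads$bo <- grads$bo + rowSums(dlogits)
    dinp <- t(params$Wo) %*% dlogits
    for (l in rev(seq_len(L))) {
      ch <- cache_t[[t]]$caches[[l]]
      dh <- dinp + dh_next[[l]]
      dcc <- dc_next[[l]] + dh * ch$o * (1 - ch$tc^2)
      do_ <- dh * ch$tc
      di <- dcc * ch$g
      df <- dcc * ch$c_prev
      dg <- dcc * ch$i
      dz <- rbind(di * ch$i * (1 - ch$i),
                  df * ch$f * (1 - ch$f),
                  dg * (1 - ch$g^2),
                  do_ * ch$o * (1 - ch$o))
      grads$layers[[l]]$W <- grads$layers[[l]]$W + dz %*% t(ch$xh)
      grads$layers[[l]]$b <- grads$layers[[l]]$b + rowSums(dz)
      dxh <- t(params$layers[[l]]$W) %*% dz
      in_size <- nrow(ch$xh) - H
      dinp <- dxh[seq_len(in_size), , drop = FALSE]
      dh_next[[l]] <- dxh[(in_size + 1):(in_size + H), , drop = FALSE]
      dc_next[[l]] <- dcc * ch$f
    }
    # dinp is now the embedding gradient for the inputs at time t
    add <- rowsum(t(dinp), cache_t[[t]]$ids)
    rows <- as.integer(rownames(add))
    grads$E[rows, ] <- grads$E[rows, ] + add
  }
  scale <- max(n_tok, 1)
  grads <- rapply(grads, function(g) g / scale, how = "replace")
  list(loss = loss / scale, grads = grads, n_tokens = n_tok)
}

# Held-out mean NLL per token (forward only).
lstm_batch_loss <- function(params, seqs, pad_id) {
  Tn <- nrow(seqs); B <- ncol(seqs)
  H <- nrow(params$layers[[1]]$W) / 4
  L <- length(params$layers)
  states <- zero_states(L, H, B)
  loss <- 0; n_tok <- 0
  for (t in seq_len(Tn - 1)) {
    x <- t(params$E[seqs[t, ], , drop = FALSE])
    st <- lstm_step(params, x, states)
    states <- st$states
    p <- softmax_cols(st$logits)
    target <- seqs[t + 1, ]
    mask <- target != pad_id
    if (!any(mask)) break
    idx <- cbind(target[mask], which(mask))
    loss <- loss - sum(log(pmax(p[idx], 1e-12)))
    n_tok <- n_tok + sum(mask)
  }
  loss / max(n_tok, 1)
}

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "replace")
}

# Flat walk over the nested parameter list; f(param, grad, state) ->
# list(param, state).
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        clip = 5) {
  gnorm <- sqrt(sum(unlist(rapply(grads, function(g) sum(g^2),
                                  how = "unlist"))))
  scale <- if (gnorm > clip) clip / gnorm else 1
  upd <- function(p, g, s) {
    g <- g * scale
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  r1 <- upd(params$E, grads$E, state$E)
  params$E <- r1$p; state$E <- r1$s
  for (l in seq_along(params$layers)) {
    rW <- upd(params$layers[[l]]$W, grads$layers[[l]]$W, state$layers[[l]]$W)
    params$layers[[l]]$W <- rW$p; state$layers[[l]]$W <- rW$s
    rb <- upd(params$layers[[l]]$b, grads$layers[[l]]$b, state$layers[[l]]$b)
    params$layers[[l]]$b <- rb$p; state$layers[[l]]$b <- rb$s
  }
  r2 <- upd(params$Wo, grads$Wo, state$Wo)
  params$Wo <- r2$p; state$Wo <- r2$s
  r3 <- upd(params$bo, grads$bo, state$bo)
  params$bo <- r3$p; state$bo <- r3$s
  list(params = params, state = state)
}

pad_batch <- function(encoded, pad_id) {
  Tn <- max(lengths(encoded))
  m <- matrix(pad_id, Tn, length(encoded))
  for (j in seq_along(encoded)) m[seq_along(encoded[[j]]), j] <- encoded[[j]]
  m
}

# Length-bucketed minibatches: sequences of similar length share a batch
# (minimizing padding waste); batch order and near-ties are shuffled.
bucket_batches <- function(encoded, batch_size, pad_id) {
  ord <- order(lengths(encoded) + stats::runif(length(encoded)))
  starts <- seq(1, length(encoded), by = batch_size)
  batches <- lapply(starts, function(s) {
    idx <- ord[s:min(s + batch_size - 1L, length(encoded))]
    pad_batch(encoded[idx], pad_id)
  })
  batches[sample.int(length(batches))]
}

# Sample `n` token sequences from the model. Temperature 0 means argmax.
lstm_sample <- function(params, vocab, n, max_length, temperature = 1) {
  H <- nrow(params$layers[[1]]$W) / 4
  L <- length(params$layers)
  states <- zero_states(L, H, n)
  current <- rep(vocab$start, n)
  finished <- rep(FALSE, n)
  out <- vector("list", n)
  for (step in seq_len(max_length)) {
    x <- t(params$E[current, , drop = FALSE])
    st <- lstm_step(params, x, states)
    states <- st$states
    if (temperature <= 0) {
      nxt <- apply(st$logits, 2, which.max)
    } else {
      p <- softmax_cols(st$logits / temperature)
      u <- stats::runif(n)
      cum <- apply(p, 2, cumsum)
      nxt <- vapply(seq_len(n), function(j) {
        which(cum[, j] >= u[j])[1]
      }, integer(1))
    }
    nxt[finished] <- vocab$pad
    newly_done <- nxt == vocab$end
    for (j in which(!finished & !newly_done & nxt > 3L)) {
      out[[j]] <- c(out[[j]], nxt[j])
    }
    finished <- finished | newly_done
    if (all(finished)) break
    current <- nxt
    current[finished] <- vocab$pad
  }
  vapply(out, function(ids) {
    if (is.null(ids)) "" else decode_smiles(ids, vocab)
  }, character(1))
}
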