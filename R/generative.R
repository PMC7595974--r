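# Generative SMILES model with transfer learning.
#
# A recurrent (LSTM) language model is pre-trained on a background
# corpus (the "prior") and then fine-tuned on the existing analogs of
# one series. After each fine-tuning epoch a fixed number of SMILES is
# sampled and scored: valid strings, unique structures, structures
# containing the series core, and reproduced existing analogs. The
# default configuration is desk-scale; the full-size architecture
# (embedding 512, three LSTM layers of 512, sequence length 256, 50
# epochs with 1024 samples) remains selectable through the same fields.

#' Generative model configuration
#'
#' @param embedding_size,hidden_size,n_layers Network dimensions.
#' @param max_sequence_length Maximum token sequence length (must be at
#'   least the longest training string + 2).
#' @param epochs Pre-training epochs.
#' @param tl_epochs Transfer-learning (fine-tuning) epochs.
#' @param sample_per_epoch SMILES sampled after each fine-tuning epoch.
#' @param batch_size Minibatch size.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay,patience Exponential learning-rate decay factor,
#'   applied when the held-out loss has not improved for `patience`
#'   epochs.
#' @param temperature Sampling temperature.
#' @param augmentation Randomize SMILES atom order during fine-tuning
#'   (data augmentation).
#' @param holdout_fraction Held-out fraction monitoring convergence.
#' @param seed Integer seed.
#' @return A `generative_config`.
#' @export
generative_config <- function(embedding_size = 64L, hidden_size = 128L,
                              n_layers = 2L, max_sequence_length = 128L,
                              epochs = 50L, tl_epochs = 15L,
                              sample_per_epoch = 256L, batch_size = 64L,
                              learning_rate = 0.005, lr_decay = 0.9,
                              patience = 3L, temperature = 1,
                              augmentation = TRUE,
                              holdout_fraction = 0.1, seed = 1L) {
  stopifnot(embedding_size > 0, hidden_size > 0, n_layers > 0,
            max_sequence_length > 2, epochs >= 1, tl_epochs >= 1,
            sample_per_epoch >= 1)
  structure(as.list(environment()), class = "generative_config")
}

#' Pre-train the prior SMILES language model
#'
#' Trains the LSTM on a background corpus with next-token cross-entropy;
#' a held-out split monitors convergence, and the learning rate decays
#' exponentially when the held-out loss stalls. A warning is emitted if
#' the held-out loss fails to decrease over the run.
#'
#' @param corpus Character vector of valid SMILES (>= 100 strings for a
#'   meaningful prior; desk scale is ~500).
#' @param config A [generative_config()].
#' @return A `smiles_lm` with the fitted parameters, vocabulary and
#'   per-epoch loss history.
#' @export
pretrain <- function(corpus, config = generative_config()) {
  stopifnot(inherits(config, "generative_config"))
  vocab <- build_vocabulary(corpus)
  corpus <- corpus[is_valid_smiles(corpus)]
  enc <- encode_smiles(corpus, vocab)
  too_long <- lengths(enc) > config$max_sequence_length
  if (any(too_long))
    stop("corpus string(s) exceed max_sequence_length: ",
         sum(too_long), " strings")
  set.seed(config$seed)
  n <- length(enc)
  n_hold <- max(1L, round(config$holdout_fraction * n))
  hold_idx <- sample.int(n, n_hold)
  hold <- pad_batch(enc[hold_idx], vocab$pad)
  train <- enc[-hold_idx]

  params <- new_lstm_params(vocab$size, config$embedding_size,
                            config$hidden_size, config$n_layers,
                            seed = config$seed)
  opt <- adam_init(params)
  lr <- config$learning_rate
  best_hold <- Inf; stall <- 0L; step <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        holdout_loss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ep_loss <- 0; ep_tok <- 0
    for (batch in bucket_batches(train, config$batch_size, vocab$pad)) {
      bg <- lstm_batch_grad(params, batch, vocab$pad)
      step <- step + 1L
      res <- adam_update(params, bg$grads, opt, lr, step)
      params <- res$params; opt <- res$state
      ep_loss <- ep_loss + bg$loss * bg$n_tokens
      ep_tok <- ep_tok + bg$n_tokens
    }
    hold_loss <- lstm_batch_loss(params, hold, vocab$pad)
    if (hold_loss < best_hold - 1e-4) {
      best_hold <- hold_loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) {
        lr <- lr * config$lr_decay
        stall <- 0L
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_tok,
      holdout_loss = hold_loss, lr = lr))
  }
  if (history$holdout_loss[nrow(history)] >= history$holdout_loss[1])
    warning("held-out loss did not decrease over pre-training")
  structure(list(params = params, vocab = vocab, config = config,
                 history = history),
            class = "smiles_lm")
}

#' @export
print.smiles_lm <- function(x, ...) {
  h <- x$history
  cat("<smiles_lm> vocab ", x$vocab$size, ", ",
      x$config$n_layers, " x ", x$config$hidden_size, " LSTM, ",
      nrow(h), " epochs (held-out loss ",
      sprintf("%.3f -> %.3f", h$holdout_loss[1], h$holdout_loss[nrow(h)]),
      ")\n", sep = "")
  invisible(x)
}

#' Sample SMILES strings from a model
#'
#' @param model A `smiles_lm`.
#' @param n Number of strings.
#' @param temperature Sampling temperature (0 = greedy argmax).
#' @param seed Optional seed.
#' @return Character vector of sampled strings (not validity-filtered).
#' @export
sample_smiles <- function(model, n, temperature = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(temperature)) temperature <- model$config$temperature
  lstm_sample(model$params, model$vocab, n,
              model$config$max_sequence_length, temperature)
}

# Randomized (non-canonical) SMILES via random atom reordering; used as
# data augmentation during fine-tuning.
random_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- mol_from_smiles(s)
    n <- length(mol$elements)
    perm <- sample.int(n)
    inv <- match(seq_len(n), perm)
    m2 <- molgraph(mol$elements[perm], mol$charges[perm],
                   cbind(a = inv[mol$bonds[, "a"]],
                         b = inv[mol$bonds[, "b"]],
                         order = mol$bonds[, "order"]))
    out <- mol_to_smiles(m2, canonical = FALSE)
    if (is.na(out)) s else out
  }, character(1), USE.NAMES = FALSE)
}

# SMARTS pattern testing for containment of a series core: attachment
# points are dropped, so substitution sites are unconstrained (H or any
# substituent).
core_substructure_pattern <- function(core) {
  mol <- core$mol
  keep <- which(mol$elements != "*")
  bare <- mol_subgraph(mol, keep)
  mol_to_smiles(bare)
}

#' Fine-tune a prior model on the existing analogs of a series
#'
#' Runs `tl_epochs` epochs of continued training on the EA SMILES
#' (optionally augmented with randomized SMILES each epoch). After every
#' epoch `sample_per_epoch` strings are sampled and scored into epoch
#' metrics: sampled, valid, unique, core-containing, and reproduced-EA
#' counts.
#'
#' @param prior A `smiles_lm` from [pretrain()].
#' @param series An `analog_series` (or character vector of EA SMILES
#'   plus a `core` argument).
#' @param config Optional `generative_config`; defaults to the prior's
#'   with its transfer-learning fields.
#' @param core Optional `core_scaffold` when `series` is a SMILES vector.
#' @return List: `model` (fine-tuned `smiles_lm`), `metrics` (one row
#'   per epoch), `samples` (per-epoch canonical SMILES of valid
#'   samples).
#' @export
transfer_learn <- function(prior, series, config = NULL, core = NULL) {
  stopifnot(inherits(prior, "smiles_lm"))
  if (inherits(series, "analog_series")) {
    eas <- series$analogs$smiles
    core <- series$core
  } else {
    eas <- as.character(series)
    if (is.null(core)) stop("core required when series is a SMILES vector")
  }
  if (is.null(config)) config <- prior$config
  vocab <- prior$vocab
  enc0 <- encode_smiles(eas, vocab)  # errors on out-of-vocabulary tokens
  if (any(lengths(enc0) > config$max_sequence_length))
    stop("EA string(s) exceed max_sequence_length")
  core_pat <- core_substructure_pattern(core)
  ea_canon <- canonical_smiles(eas)

  params <- prior$params
  opt <- adam_init(params)
  lr <- config$learning_rate
  set.seed(config$seed)
  step <- 0L
  metrics <- list()
  samples <- vector("list", config$tl_epochs)
  best_loss <- Inf; stall <- 0L
  for (epoch in seq_len(config$tl_epochs)) {
    strings <- if (config$augmentation) random_smiles(eas) else eas
    enc <- tryCatch(encode_smiles(strings, vocab),
                    error = function(e) enc0)
    ep_loss <- 0; ep_tok <- 0
    for (batch in bucket_batches(enc, config$batch_size, vocab$pad)) {
      bg <- lstm_batch_grad(params, batch, vocab$pad)
      step <- step + 1L
      res <- adam_update(params, bg$grads, opt, lr, step)
      params <- res$params; opt <- res$state
      ep_loss <- ep_loss + bg$loss * bg$n_tokens
      ep_tok <- ep_tok + bg$n_tokens
    }
    ep_loss <- ep_loss / ep_tok
    if (ep_loss < best_loss - 1e-4) { best_loss <- ep_loss; stall <- 0L }
    else {
      stall <- stall + 1L
      if (stall >= config$patience) { lr <- lr * config$lr_decay; stall <- 0L }
    }
    raw <- lstm_sample(params, vocab, config$sample_per_epoch,
                       config$max_sequence_length, config$temperature)
    vs <- valid_sampled_smiles(raw, vocab)
    valid <- vs$valid
    can_valid <- vs$canonical[valid]
    uniq <- unique(can_valid)
    with_core <- if (length(uniq)) {
      uniq[smarts_count(uniq, core_pat) >= 1L]
    } else character(0)
    metrics[[epoch]] <- data.frame(
      epoch = epoch,
      n_sampled = length(raw),
      n_valid = sum(valid),
      n_unique = length(uniq),
      n_with_core = length(with_core),
      n_reproduced_eas = length(intersect(uniq, ea_canon)),
      train_loss = ep_loss)
    samples[[epoch]] <- can_valid
  }
  model <- structure(list(params = params, vocab = vocab, config = config,
                          history = prior$history),
                     class = "smiles_lm")
  list(model = model, metrics = do.call(rbind, metrics), samples = samples)
}

#' Collect the unique sampled virtual-analog population
#'
#' Deduplicates all per-epoch samples by canonical SMILES and counts,
#' for every structure, the number of distinct epochs in which it was
#' sampled (repeats within one epoch count once). Reproduced EAs are
#' flagged.
#'
#' @param samples Per-epoch list of canonical SMILES (from
#'   [transfer_learn()]).
#' @param series The `analog_series` (or character vector of EA SMILES).
#' @return data.frame: `smiles`, `epoch_frequency`, `is_ea`.
#' @export
collect_sampled_vas <- function(samples, series) {
  ea_canon <- if (inherits(series, "analog_series"))
    series$analogs$smiles else canonical_smiles(as.character(series))
  per_epoch <- lapply(samples, unique)
  all_smiles <- unlist(per_epoch, use.names = FALSE)
  if (length(all_smiles) == 0L)
    return(data.frame(smiles = character(0), epoch_frequency = integer(0),
                      is_ea = logical(0)))
  freq <- table(all_smiles)
  out <- data.frame(smiles = names(freq),
                    epoch_frequency = as.integer(freq),
                    stringsAsFactors = FALSE)
  out$is_ea <- out$smiles %in% ea_canon
  out <- out[order(-out$epoch_frequency, out$smiles, method = "radix"), ]
  rownames(out) <- NULL
  out
}
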