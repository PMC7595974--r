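# Tokenization, the prior language model, and transfer learning.

test_that("tokenization keeps multi-character tokens intact and round-trips", {
  expect_length(tokenize_smiles("c1ccccc1"), 8L)
  expect_equal(tokenize_smiles("CCl"), c("C", "Cl"))
  expect_equal(tokenize_smiles("CBr"), c("C", "Br"))
  expect_equal(tokenize_smiles("C[nH]1ccc1"),
               c("C", "[nH]", "1", "c", "c", "c", "1"))
  for (s in c("CC(=O)Nc1ccc(F)cc1", "FC(F)(F)c1ccncc1", "C%12CC%12")) {
    expect_equal(paste(tokenize_smiles(s), collapse = ""), s)
  }
})

test_that("vocabulary construction rejects invalid corpus strings and flags OOV", {
  expect_warning(v <- build_vocabulary(c("CCO", "C1CC", "CCC")), "invalid")
  expect_true(all(c("<pad>", "<start>", "<end>", "C", "O") %in% v$tokens))
  enc <- encode_smiles("CCO", v)[[1]]
  expect_equal(enc[1], v$start)
  expect_equal(enc[length(enc)], v$end)
  expect_equal(decode_smiles(enc, v), "CCO")
  expect_error(encode_smiles("CBr", v), "out-of-vocabulary token 'Br'")
})

test_that("the grammar check catches malformed strings the parser repairs", {
  expect_true(all(smiles_grammar_ok(c("CCO", "c1ccccc1", "CC(=O)N",
                                      "C(C)(C)C"))))
  expect_false(any(smiles_grammar_ok(c("C(C(n", "C1CC", "(CCO)", "CC(",
                                       "CC()", "C=", "", "1CC"))))
})

test_that("the pre-trained prior converges and samples mostly valid SMILES", {
  prior <- get_test_prior()
  h <- prior$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_lt(h$holdout_loss[nrow(h)], h$holdout_loss[1])

  set.seed(2)
  s <- sample_smiles(prior, 512)
  v <- comodiag:::valid_sampled_smiles(s, prior$vocab)
  expect_gte(mean(v$valid), 0.5)

  # greedy (temperature -> 0) sampling is deterministic
  g1 <- sample_smiles(prior, 8, temperature = 0)
  g2 <- sample_smiles(prior, 8, temperature = 0)
  expect_identical(g1, g2)
  expect_length(unique(g1), 1L)
})

test_that("randomized SMILES keep the molecule identity", {
  set.seed(3)
  smis <- c("CCOc1ccccc1C(=O)NC", "FC(F)(F)c1ccncc1")
  r <- comodiag:::random_smiles(smis)
  expect_equal(canonical_smiles(r), canonical_smiles(smis))
})

test_that("fine-tuning focuses sampling on the series core", {
  tl <- get_test_tl()
  m <- tl$metrics
  expect_equal(nrow(m), 15L)
  # chain inequalities hold at every epoch
  expect_true(all(m$n_with_core <= m$n_valid))
  expect_true(all(m$n_valid <= m$n_sampled))
  expect_true(all(m$n_unique <= m$n_valid))
  expect_true(all(m$n_reproduced_eas <= nrow(get_tl_series()$analogs)))
  # focusing: the core-containing fraction rises
  expect_gt(m$n_with_core[15] / m$n_valid[15],
            m$n_with_core[1] / m$n_valid[1])
  # no validity collapse between consecutive epochs
  frac_valid <- m$n_valid / m$n_sampled
  expect_true(all(diff(frac_valid) > -0.2))
  # trend is monotone in rank correlation
  expect_gt(cor(m$epoch, m$n_with_core, method = "spearman"), 0)
})

test_that("an unfocused prior almost never emits the series core", {
  prior <- get_test_prior()
  ser <- get_tl_series()
  set.seed(5)
  s <- sample_smiles(prior, 256)
  v <- comodiag:::valid_sampled_smiles(s, prior$vocab)
  uniq <- unique(v$canonical[v$valid])
  pat <- comodiag:::core_substructure_pattern(ser$core)
  frac <- sum(comodiag:::smarts_count(uniq, pat) >= 1) / length(uniq)
  expect_lt(frac, 0.1)
})

test_that("sampled-population collection counts epochs, not repeats", {
  samples <- list(c("CCO", "CCO", "CCC"), c("CCO"), character(0),
                  c("CCC", "CCN"))
  pop <- collect_sampled_vas(samples, c("CCN"))
  expect_equal(nrow(pop), 3L)
  expect_equal(pop$epoch_frequency[pop$smiles == "CCO"], 2L)
  expect_equal(pop$epoch_frequency[pop$smiles == "CCC"], 2L)
  expect_equal(pop$epoch_frequency[pop$smiles == "CCN"], 1L)
  expect_true(pop$is_ea[pop$smiles == "CCN"])
  expect_equal(sum(table(pop$epoch_frequency)), nrow(pop))

  # six distinct epochs -> frequency 6
  samples6 <- rep(list(character(0)), 50)
  for (e in c(8, 16, 26, 40, 41, 48)) samples6[[e]] <- "CCOC"
  pop6 <- collect_sampled_vas(samples6, character(0))
  expect_equal(pop6$epoch_frequency, 6L)

  tl <- get_test_tl()
  pop_tl <- collect_sampled_vas(tl$samples, get_tl_series())
  expect_gt(nrow(pop_tl), 100)
  expect_gt(sum(pop_tl$is_ea), 0)
  expect_true(all(pop_tl$epoch_frequency >= 1 &
                    pop_tl$epoch_frequency <= 15))
})

test_that("transfer learning rejects out-of-vocabulary analogs by token", {
  tiny <- suppressWarnings(pretrain(
    c("CCO", "CCC", "CCN", "CCCC", "COC", "CNC", "CCCN", "CCOC"),
    generative_config(embedding_size = 8, hidden_size = 12, n_layers = 1,
                      epochs = 2, max_sequence_length = 16, seed = 1)))
  core1 <- core_scaffold("*NC(=O)c1ccc(OC)cc1")
  expect_error(
    transfer_learn(tiny, c("CCBr"), core = core1),
    "out-of-vocabulary token 'Br'")
})
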