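# Fingerprints, Tanimoto kernel and global potency models.

test_that("fingerprints are 2048-bit, non-empty and canonicalization-invariant", {
  fp <- ecfp4_fingerprints(c("CCOc1ccccc1", "c1ccccc1OCC", "CCO"))
  expect_equal(ncol(fp), 2048L)
  expect_true(all(rowSums(fp) > 0))
  expect_equal(fp[1, ], fp[2, ])
  expect_false(all(fp[1, ] == fp[3, ]))
})

test_that("Tanimoto kernel has its analytic values and is PSD", {
  a <- c(1, 1, 0, 0); b <- c(0, 0, 1, 1)
  expect_equal(tanimoto_kernel(a, a), 1)
  expect_equal(tanimoto_kernel(a, b), 0)
  expect_equal(tanimoto_kernel(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_warning(z <- tanimoto_kernel(c(0, 0), c(0, 0)), "empty")
  expect_equal(z, 0)

  set.seed(21)
  M <- matrix(rbinom(100 * 64, 1, 0.2), 100, 64)
  M[rowSums(M) == 0, 1] <- 1
  K <- tanimoto_kernel_matrix(M)
  expect_true(isSymmetric(K))
  expect_equal(diag(K), rep(1, 100))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # matrix form agrees with the pairwise function
  expect_equal(K[3, 7], tanimoto_kernel(M[3, ], M[7, ]))
})

test_that("evaluation metrics follow their definitions", {
  m <- structure(list(), class = "potency_model")
  expect_equal(comodiag:::r_squared(c(5, 6, 7), c(5, 6, 8)), 0.5)
  expect_equal(comodiag:::r_squared(c(5, 6, 7), c(5, 6, 7)), 1)
  expect_equal(comodiag:::r_squared(c(5, 6, 7), rep(6, 3)), 0)
})

test_that("double-CV models learn additive synthetic SAR and not permuted labels", {
  ser <- cache_get("potency_series", function() {
    generate_series(series_generator_spec(n_sites = 3,
                                          substituents_per_site = 5,
                                          n_eas = 80, noise_sd = 0.1,
                                          seed = 5))
  })
  m <- cache_get("svr_model", function() {
    train_global_model(ser$analogs$smiles, ser$analogs$potency,
                       method = "svr", seed = 2)
  })
  expect_gt(mean(m$outer_cv$r_squared), 0.7)
  expect_lt(mean(m$outer_cv$mae), 0.3)

  m2 <- train_global_model(ser$analogs$smiles, ser$analogs$potency,
                           method = "svr", seed = 2)
  expect_equal(m2$outer_cv, m$outer_cv)  # determinism

  mr <- train_global_model(ser$analogs$smiles, ser$analogs$potency,
                           method = "ridge", seed = 2)
  expect_gt(mean(mr$outer_cv$r_squared), 0.7)

  set.seed(9)
  mp <- train_global_model(ser$analogs$smiles,
                           sample(ser$analogs$potency),
                           method = "svr", seed = 2)
  expect_lt(mean(mp$outer_cv$r_squared), 0.2)

  expect_error(train_global_model(ser$analogs$smiles[1:31],
                                  rep(5, 31), seed = 1),
               "constant potency")
})

test_that("held-out evaluation and population ranking are coherent", {
  ser <- cache_get("potency_series", function() {
    generate_series(series_generator_spec(n_sites = 3,
                                          substituents_per_site = 5,
                                          n_eas = 80, noise_sd = 0.1,
                                          seed = 5))
  })
  m <- cache_get("svr_model", function() {
    train_global_model(ser$analogs$smiles, ser$analogs$potency,
                       method = "svr", seed = 2)
  })
  sp <- split_series(ser, fraction = 0.5, seed = 3)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(ser$analogs))
  expect_lt(abs(nrow(sp$train) - nrow(sp$test)), 4)
  # both halves span the potency range (stratified split)
  expect_lt(abs(median(sp$train$potency) - median(sp$test$potency)), 1)

  ev <- evaluate_model(m, sp$test$smiles, sp$test$potency)
  expect_gt(ev$r_squared, 0.5)
  expect_equal(ev$n_test, nrow(sp$test))

  # near-duplicates of training data predict near training potency
  tr_pred <- evaluate_model(m, ser$analogs$smiles, ser$analogs$potency)
  expect_lt(tr_pred$mae, 0.25)

  vas <- ser$analogs[1:10, c("id", "smiles")]
  vas$origin <- "close_in_VA"
  ranked <- predict_population(m, vas)
  expect_equal(ranked$rank, 1:10)
  expect_true(all(diff(ranked$predicted) <= 0))
  q <- attr(ranked, "quantiles")
  expect_equal(unname(q["close_in_VA", ]),
               unname(quantile(ranked$predicted, c(0, 0.25, 0.5, 0.75, 1))))

  empty <- predict_population(m, ser$analogs[0, c("id", "smiles")])
  expect_equal(nrow(empty), 0L)
})
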