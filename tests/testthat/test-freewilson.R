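# Matched molecular pairs, quartets and Free-Wilson additivity.

test_that("MMPs are exactly the single-site exchanges", {
  # one-site series of k analogs: complete graph
  core <- core_scaffold("*NC(=O)c1ccc(OC)cc1")
  k <- 5
  eas <- data.frame(id = paste0("e", 1:k),
                    sub_1 = c("*C", "*CC", "*CCC", "*C(C)C", "*CCO"),
                    potency = 5:9, stringsAsFactors = FALSE)
  ser1 <- analog_series(core, eas)
  expect_equal(nrow(compute_mmps(ser1)), k * (k - 1) / 2)

  # two-site differences are not MMPs
  ser2 <- mk_series(c("*C", "*F"), c("*OC", "*CC"), c(6, 7))
  expect_equal(nrow(compute_mmps(ser2)), 0L)

  # random series vs exhaustive pairwise-difference oracle
  ser <- get_ref_series()
  mmps <- compute_mmps(ser)
  m <- as.matrix(ser$analogs[, paste0("sub_", 1:3)])
  rownames(m) <- ser$analogs$id
  oracle <- 0L
  for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    if (sum(m[i, ] != m[j, ]) == 1L) oracle <- oracle + 1L
  }
  expect_equal(nrow(mmps), oracle)
  expect_true(all(vapply(seq_len(nrow(mmps)), function(r) {
    sum(m[mmps$analog_a[r], ] != m[mmps$analog_b[r], ]) == 1L
  }, logical(1))))
  g <- mmp_network(ser)
  expect_equal(igraph::ecount(g), oracle)
  expect_equal(igraph::vcount(g), nrow(ser$analogs))
})

test_that("quartet enumeration handles the canonical rectangle cases", {
  full <- mk_series(c("*C", "*F", "*C", "*F"), c("*OC", "*OC", "*CC", "*CC"),
                    c(5, 6, 5.5, 6.5), ids = c("p11", "p21", "p12", "p22"))
  q <- find_quartets(full)
  expect_equal(nrow(q), 4L)
  expect_true(all(q$target_status == "FW_EA"))
  expect_setequal(q$target_id, c("p11", "p21", "p12", "p22"))

  three <- mk_series(c("*C", "*F", "*C"), c("*OC", "*OC", "*CC"),
                     c(5, 6, 5.5), ids = c("p11", "p21", "p12"))
  q3 <- find_quartets(three)
  expect_equal(nrow(q3), 1L)
  expect_equal(q3$target_status, "FW_VA")
  expect_true(is.na(q3$target_id))

  core1 <- core_scaffold("*NC(=O)c1ccc(OC)cc1")
  one_site <- analog_series(core1, data.frame(
    id = c("a", "b", "c"), sub_1 = c("*C", "*CC", "*F"),
    potency = c(5, 6, 7), stringsAsFactors = FALSE))
  expect_equal(nrow(find_quartets(one_site)), 0L)
})

test_that("quartet enumeration matches the brute-force triple oracle", {
  ser <- get_ref_series()
  expect_identical(quartet_signatures(find_quartets(ser)),
                   oracle_quartets(ser))
  small <- generate_series(series_generator_spec(n_sites = 2,
                                                 substituents_per_site = 4,
                                                 n_eas = 10, seed = 13))
  expect_identical(quartet_signatures(find_quartets(small)),
                   oracle_quartets(small))
})

test_that("Free-Wilson prediction is additive and aggregates correctly", {
  three <- mk_series(c("*C", "*F", "*C"), c("*OC", "*OC", "*CC"),
                     c(5, 6, 5.5), ids = c("p11", "p21", "p12"))
  q <- find_quartets(three)
  pots <- stats::setNames(three$analogs$potency, three$analogs$id)
  expect_equal(fw_predict(q[1, ], pots), 6.5)
  expect_equal(fw_predict(q[1, ], c(p11 = 3, p21 = 3, p12 = 3)), 3)
  expect_error(fw_predict(q[1, ], pots[-1]), "missing potency")

  agg <- fw_predict_aggregate(three)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$mean_pred, 6.5)
  expect_equal(agg$sd_pred, 0)
  expect_equal(agg$n_quartets, 1L)

  vas <- generate_fw_vas(three)
  expect_equal(nrow(vas), 1L)
  expect_equal(vas$smiles, assemble_analog(three$core, c("*F", "*CC")))
  expect_equal(vas$origin, "FW_VA")

  # saturated combinatorial series leaves nothing to design
  full <- mk_series(c("*C", "*F", "*C", "*F"), c("*OC", "*OC", "*CC", "*CC"),
                    c(5, 6, 5.5, 6.5))
  expect_equal(nrow(generate_fw_vas(full)), 0L)
})

test_that("noiseless additive series give exact Free-Wilson predictions", {
  ser <- get_ref_series()  # noise_sd = 0, interaction_sd = 0
  agg <- fw_predict_aggregate(ser)
  expect_gt(nrow(agg), 0)
  for (i in seq_len(nrow(agg))) {
    subs <- strsplit(agg$target_key[i], "|", fixed = TRUE)[[1]]
    expect_equal(agg$mean_pred[i], true_potency(ser, subs),
                 tolerance = 1e-10)
  }
  expect_equal(max(agg$sd_pred), 0, tolerance = 1e-10)
})

test_that("per-quartet error under noise matches the closed form", {
  # each quartet error is eps_x + eps_y - eps_ref ~ N(0, 3 sigma^2),
  # so E|error| = sigma * sqrt(3) * sqrt(2/pi)
  sigma <- 0.2
  errs <- unlist(lapply(1:6, function(sd) {
    ser <- generate_series(series_generator_spec(
      n_sites = 3, substituents_per_site = 5, n_eas = 60,
      noise_sd = sigma, seed = sd))
    q <- find_quartets(ser)
    q <- q[q$target_status == "FW_VA", ]
    pots <- stats::setNames(ser$analogs$potency, ser$analogs$id)
    vapply(seq_len(nrow(q)), function(i) {
      subs <- strsplit(q$target_key[i], "|", fixed = TRUE)[[1]]
      abs(fw_predict(q[i, ], pots) - true_potency(ser, subs))
    }, numeric(1))
  }))
  # quartet errors sharing EA noise terms are correlated, so per-run means
  # scatter more than independent sampling would suggest
  expected <- sigma * sqrt(3) * sqrt(2 / pi)
  expect_equal(mean(errs), expected, tolerance = 0.2)
})

test_that("prediction error grows with the interaction (non-additivity) term", {
  maes <- vapply(c(0, 0.5, 2), function(int_sd) {
    ser <- generate_series(series_generator_spec(
      n_sites = 3, substituents_per_site = 5, n_eas = 60,
      noise_sd = 0, interaction_sd = int_sd, seed = 77))
    agg <- fw_predict_aggregate(ser)
    errs <- vapply(seq_len(nrow(agg)), function(i) {
      subs <- strsplit(agg$target_key[i], "|", fixed = TRUE)[[1]]
      abs(agg$mean_pred[i] - true_potency(ser, subs))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(maes) > 0))
})

test_that("Free-Wilson EA participation is counted in any quartet role", {
  three <- mk_series(c("*C", "*F", "*C"), c("*OC", "*OC", "*CC"),
                     c(5, 6, 5.5))
  f <- fw_ea_fraction(three)
  expect_equal(f$count, 3L)
  expect_equal(f$fraction, 1)

  core1 <- core_scaffold("*NC(=O)c1ccc(OC)cc1")
  no_q <- analog_series(core1, data.frame(
    id = c("a", "b"), sub_1 = c("*C", "*CC"), potency = c(5, 6),
    stringsAsFactors = FALSE))
  f0 <- fw_ea_fraction(no_q)
  expect_equal(f0$count, 0L)
  expect_equal(f0$fraction, 0)
})
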