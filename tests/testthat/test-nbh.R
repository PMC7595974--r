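# Neighborhood assignment and the C/D/S/P diagnostic scores.

identity_space <- function(d) {
  structure(list(center = rep(0, d), scale = rep(1, d)),
            class = "chem_space")
}

test_that("closed-ball membership matches the geometry", {
  sp <- identity_space(2)
  eas <- matrix(0, 1, 2, dimnames = list("e1", NULL))
  vas <- matrix(c(0.5, 0, 1.5, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("v1", "v2"), NULL))
  a <- assign_neighborhoods(eas, vas, radius = 1, space = sp)
  expect_equal(a$membership$e1, "v1")
  expect_equal(unname(a$multiplicity), c(1, 0))

  a0 <- assign_neighborhoods(eas, vas, radius = 0, space = sp)
  expect_length(a0$membership$e1, 0L)
  # boundary is inclusive
  ab <- assign_neighborhoods(eas, vas, radius = 0.5, space = sp)
  expect_equal(ab$membership$e1, "v1")
  expect_error(assign_neighborhoods(eas[0, , drop = FALSE], vas, 1, sp),
               "empty EA")
})

test_that("assignment equals the exhaustive pairwise-distance oracle", {
  set.seed(7)
  sp <- identity_space(3)
  E <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(paste0("e", 1:20), NULL))
  V <- matrix(rnorm(200 * 3), 200, 3,
              dimnames = list(paste0("v", 1:200), NULL))
  r <- 0.8
  a <- assign_neighborhoods(E, V, r, sp)
  for (i in seq_len(20)) {
    d <- sqrt(colSums((t(V) - E[i, ])^2))
    expect_equal(sort(a$membership[[i]]), sort(rownames(V)[d <= r]))
  }
  expect_equal(unname(a$multiplicity),
               unname(colSums(sapply(seq_len(200), function(j) {
                 sqrt(rowSums(sweep(E, 2, V[j, ])^2)) <= r
               }))[]))
})

test_that("coverage score counts covered VAs", {
  sp <- identity_space(1)
  E <- matrix(0, 1, 1, dimnames = list("e1", NULL))
  V <- matrix(c(0.1, 0.2, 0.3, 0.4, 5, 6, 7, 8, 9, 10), 10, 1,
              dimnames = list(paste0("v", 1:10), NULL))
  a <- assign_neighborhoods(E, V, 1, sp)
  expect_equal(coverage_score(a), 0.4)
  expect_equal(coverage_score(assign_neighborhoods(E, V, 100, sp)), 1)
  expect_equal(coverage_score(assign_neighborhoods(E, V, 0.01, sp)), 0)
})

test_that("density score is the mean-multiplicity overlap measure", {
  # construct multiplicities {1, 2, 3}: d_mean = 2, D = 0.5
  sp <- identity_space(1)
  E <- matrix(c(0, 0.3, 0.6), 3, 1, dimnames = list(c("e1", "e2", "e3"), NULL))
  V <- matrix(c(-0.4, -0.1, 0.3), 3, 1,
              dimnames = list(c("v1", "v2", "v3"), NULL))
  a <- assign_neighborhoods(E, V, 0.4, sp)
  expect_equal(unname(sort(a$multiplicity)), c(1, 2, 3))
  expect_equal(density_score(a), 0.5)

  # all covered VAs in exactly one NBH -> D = 0
  a1 <- assign_neighborhoods(E[1, , drop = FALSE], V, 0.4, sp)
  expect_equal(density_score(a1), 0)
  # nothing covered -> defined as 0
  a2 <- assign_neighborhoods(E, V + 100, 0.4, sp)
  expect_equal(density_score(a2), 0)
})

test_that("saturation score is the harmonic mean with its bounds", {
  expect_equal(round(saturation_score(0.43, 0.90), 2), 0.58)
  expect_equal(round(saturation_score(0.18, 0.73), 2), 0.29)
  for (x in c(0.2, 0.5, 0.9)) expect_equal(saturation_score(x, x), x)
  expect_equal(saturation_score(0, 0.7), 0)
  expect_equal(saturation_score(0, 0), 0)
  set.seed(5)
  for (i in 1:25) {
    C <- runif(1); D <- runif(1)
    S <- saturation_score(C, D)
    expect_gte(S, min(C, D) - 1e-12)
    expect_lte(S, max(C, D) + 1e-12)
    expect_lte(S, sqrt(C * D) + 1e-12)  # harmonic <= geometric
  }
})

test_that("progression score averages pairwise potency ranges", {
  sp <- identity_space(1)
  # one VA in two NBHs (pots 5, 7), another VA with m = 1
  E <- matrix(c(0, 0.4, 10), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  V <- matrix(c(0.2, 10.1), 2, 1, dimnames = list(c("v1", "v2"), NULL))
  a <- assign_neighborhoods(E, V, 0.3, sp)
  expect_equal(progression_score(a, c(a = 5, b = 7, c = 1)), 2.0)
  # all potencies equal -> 0
  expect_equal(progression_score(a, c(a = 4, b = 4, c = 4)), 0)

  # one VA inside three NBHs with pots 5, 6, 9 -> mean pair gap 8/3
  E3 <- matrix(c(0, 0.1, 0.2), 3, 1,
               dimnames = list(c("a", "b", "c"), NULL))
  V3 <- matrix(0.1, 1, 1, dimnames = list("v", NULL))
  a3 <- assign_neighborhoods(E3, V3, 0.5, sp)
  expect_equal(progression_score(a3, c(a = 5, b = 6, c = 9)), 8 / 3)

  # shift invariance and linear scaling
  pots <- c(a = 5, b = 6, c = 9)
  base <- progression_score(a3, pots)
  expect_equal(progression_score(a3, pots + 3.7), base)
  expect_equal(progression_score(a3, pots * 2.5), base * 2.5)

  expect_error(progression_score(a3, c(a = 5, b = 6)), "missing potency.*c")
})

test_that("radius calibration matches the sorted-distance oracle", {
  set.seed(8)
  sp <- identity_space(2)
  E <- matrix(rnorm(10 * 2), 10, 2)
  V <- matrix(rnorm(50 * 2), 50, 2)
  all_d <- as.vector(sqrt(outer(rowSums(E^2), rowSums(V^2), "+") -
                            2 * E %*% t(V)))
  for (q in c(0.05, 0.3, 0.9)) {
    expect_equal(calibrate_radius(E, V, sp, q),
                 unname(quantile(all_d, q)))
  }
  # monotone in the quantile; high quantile covers everything
  r_small <- calibrate_radius(E, V, sp, 0.01)
  r_big <- calibrate_radius(E, V, sp, 0.99)
  expect_lt(r_small, r_big)
  a <- assign_neighborhoods(E, V, max(all_d), sp)
  expect_equal(coverage_score(a), 1)
})

test_that("C and D are monotone in EAs and radius", {
  set.seed(9)
  sp <- identity_space(3)
  V <- matrix(rnorm(150 * 3), 150, 3)
  E_all <- matrix(rnorm(12 * 3), 12, 3)
  for (r in c(0.5, 1)) {
    c_small <- coverage_score(
      assign_neighborhoods(E_all[1:6, ], V, r, sp))
    c_big <- coverage_score(assign_neighborhoods(E_all, V, r, sp))
    expect_gte(c_big, c_small)
  }
  radii <- c(0.3, 0.6, 1.2, 2.4)
  cs <- numeric(0); ds <- numeric(0)
  for (r in radii) {
    a <- assign_neighborhoods(E_all, V, r, sp)
    cs <- c(cs, coverage_score(a)); ds <- c(ds, density_score(a))
  }
  expect_true(all(diff(cs) >= 0))
  expect_true(all(diff(ds) >= -1e-12))
})

test_that("resampled scoring is seeded, deterministic and degenerate-safe", {
  ser <- mk_series(c("*C", "*CC", "*F", "*OC", "*CCC"),
                   c("*OC", "*C", "*C", "*CC", "*F"),
                   c(6, 7, 8, 6.5, 7.2))
  pool <- suppressWarnings(
    generate_va_pool(ser, n = 60, strategy = "close_in", seed = 3))
  cfg <- run_config(auto_radius_quantile = 0.1, n_resamples = 4,
                    sample_size = 15, seed = 11)
  r1 <- suppressWarnings(score_with_resampling(ser, pool, cfg))
  r2 <- suppressWarnings(score_with_resampling(ser, pool, cfg))
  expect_identical(r1$scores, r2$scores)
  expect_equal(r1$scores["S", "mean"],
               mean(apply(r1$per_resample, 1, function(x) {
                 saturation_score(x["C"], x["D"])
               })))
  # sampling the whole pool every time -> zero variance across resamples
  n_pool <- length(setdiff(unique(pool$smiles), ser$analogs$smiles))
  cfg_all <- run_config(auto_radius_quantile = 0.1, n_resamples = 3,
                        sample_size = n_pool, seed = 2)
  r3 <- suppressWarnings(score_with_resampling(ser, pool, cfg_all))
  expect_equal(unname(r3$scores$sd), rep(0, 4))
  expect_error(
    score_with_resampling(ser, pool,
                          run_config(sample_size = 10000, seed = 1)),
    "smaller than")
})
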