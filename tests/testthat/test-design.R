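# Scaffold-based virtual-analog enumeration and population overlap.

test_that("enumeration is seeded-deterministic, core-containing and size-bounded", {
  ser <- get_ref_series()
  pool <- build_pool(ser)
  spec <- enumeration_spec(ser, pool, n_target = 40, seed = 5)
  v1 <- enumerate_vas(spec)
  v2 <- enumerate_vas(spec)
  expect_identical(v1$smiles, v2$smiles)
  expect_equal(v1$origin[1], "close_in_VA")
  expect_false(any(v1$smiles %in% ser$analogs$smiles))
  expect_false(anyDuplicated(v1$smiles) > 0)

  core_pat <- comodiag:::core_substructure_pattern(ser$core)
  expect_true(all(comodiag:::smarts_count(v1$smiles, core_pat) >= 1))

  heavy <- vapply(ser$analogs$smiles, function(s) {
    comodiag:::n_heavy_atoms(comodiag:::fragment_mol(s))
  }, numeric(1))
  va_heavy <- vapply(v1$smiles, function(s) {
    comodiag:::n_heavy_atoms(comodiag:::fragment_mol(s))
  }, numeric(1))
  expect_true(all(va_heavy >= min(heavy) & va_heavy <= max(heavy)))
})

test_that("all-H probabilities collapse enumeration to the bare core", {
  ser <- mk_series(c("*C", "*CC"), c("*OC", "*OC"), c(6, 7))
  pool <- build_pool(ser)
  bare <- assemble_analog(ser$core, c("H", "H"))
  spec <- enumeration_spec(ser, pool, n_target = 5,
                           h_probabilities = c(1, 1),
                           size_range = c(1, 100), seed = 2)
  expect_warning(vas <- enumerate_vas(spec), "shortfall")
  expect_equal(vas$smiles, bare)
})

test_that("one-site enumeration equals the exhaustive analog space", {
  core <- core_scaffold("*NC(=O)c1ccc(OC)cc1")
  frags <- canonical_smiles(c("*C", "*CC", "*CCC", "*C(C)C", "*CCO",
                              "*COC", "*C(C)(C)C"))
  eas <- data.frame(id = c("e1", "e2"), sub_1 = c("*C", "*CC"),
                    potency = c(6, 7), stringsAsFactors = FALSE)
  ser <- analog_series(core, eas)
  pool <- build_pool(frags)
  spec <- enumeration_spec(ser, pool, n_target = 10,
                           h_probabilities = 0, size_range = c(1, 100),
                           seed = 9)
  expect_warning(vas <- enumerate_vas(spec), "shortfall")
  oracle <- setdiff(vapply(frags, function(f) assemble_analog(core, f),
                           character(1)),
                    ser$analogs$smiles)
  expect_setequal(vas$smiles, oracle)
})

test_that("population overlap counts canonical intersections symmetrically", {
  a <- c("CCO", "CCC", "c1ccccc1")
  b <- c("OCC", "CCCC")            # OCC == CCO after canonicalization
  m <- population_overlap(list(A = a, B = b, C = "CO"))
  expect_equal(m["A", "A"], 3L)
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["A", "C"], 0L)
  expect_true(isSymmetric(m))

  set.seed(12)
  uni <- comodiag:::synthetic_fragments()$smiles
  core <- core_scaffold("*c1ccccc1")
  mols <- canonical_smiles(vapply(uni, function(f) {
    assemble_analog(core, f)
  }, character(1)))
  p1 <- sample(mols, 15); p2 <- sample(mols, 15)
  m2 <- population_overlap(list(x = p1, y = p2))
  expect_equal(m2["x", "y"], length(intersect(unique(p1), unique(p2))))
})

test_that("Free-Wilson VAs are a subset of the close-in enumerable space", {
  ser3 <- mk_series(c("*C", "*F", "*C"), c("*OC", "*OC", "*CC"),
                    c(5, 6, 5.5))
  fw <- generate_fw_vas(ser3)
  pool <- build_pool(ser3)
  combos <- expand.grid(s1 = pool$fragments, s2 = pool$fragments,
                        stringsAsFactors = FALSE)
  close_in_space <- vapply(seq_len(nrow(combos)), function(i) {
    assemble_analog(ser3$core, c(combos$s1[i], combos$s2[i]))
  }, character(1))
  expect_true(all(fw$smiles %in% close_in_space))
})
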