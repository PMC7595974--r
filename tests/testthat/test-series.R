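# Series representation, extraction and substituent pools.

test_that("a one-substituent family extracts as a single series", {
  core <- core_scaffold("*NC(=O)c1ccc(OC)cc1")
  subs <- c("*C", "*CC", "*CCC", "*C(C)C", "*CCO")
  cpds <- data.frame(
    id = paste0("m", 1:5),
    smiles = vapply(subs, function(s) assemble_analog(core, s), character(1)),
    potency = c(5, 6, 7, 8, 9), stringsAsFactors = FALSE)
  sl <- extract_series(cpds, min_size = 3, max_sites = 2)
  expect_length(sl, 1L)
  expect_equal(sl[[1]]$core$n_sites, 1L)
  expect_setequal(sl[[1]]$analogs$id, cpds$id)
})

test_that("unrelated scaffolds split into separate series", {
  core_a <- core_scaffold("*NC(=O)c1ccc(OC)cc1")
  core_b <- core_scaffold("*NS(=O)(=O)c1ccc(cc1)C1CCCC1")
  subs <- c("*C", "*CC", "*CCC")
  cpds <- data.frame(
    id = paste0("m", 1:6),
    smiles = c(vapply(subs, function(s) assemble_analog(core_a, s),
                      character(1)),
               vapply(subs, function(s) assemble_analog(core_b, s),
                      character(1))),
    potency = 5:10, stringsAsFactors = FALSE)
  sl <- extract_series(cpds, min_size = 3, max_sites = 2)
  expect_length(sl, 2L)
  ids <- lapply(sl, function(s) sort(s$analogs$id))
  expect_setequal(unlist(ids), cpds$id)
  expect_true(all(lengths(ids) == 3))
})

test_that("extraction recovers generator ground truth including H analogs", {
  ser <- generate_series(series_generator_spec(n_sites = 2,
                                               substituents_per_site = 5,
                                               n_eas = 12, seed = 7))
  # add an H-substituted analog on the same core
  extra <- data.frame(id = "h_case",
                      smiles = assemble_analog(ser$core, c("H", "*CC")),
                      potency = 6.1, stringsAsFactors = FALSE)
  cpds <- rbind(ser$analogs[, c("id", "smiles", "potency")], extra)
  sl <- extract_series(cpds, min_size = 3, max_sites = 2)
  expect_length(sl, 1L)
  expect_equal(sl[[1]]$core$smiles, ser$core$smiles)
  expect_setequal(sl[[1]]$analogs$id, cpds$id)
  h_row <- sl[[1]]$analogs[sl[[1]]$analogs$id == "h_case", ]
  expect_true("H" %in% unlist(h_row[, c("sub_1", "sub_2")]))

  # permutation invariance of the input order
  sl2 <- extract_series(cpds[rev(seq_len(nrow(cpds))), ],
                        min_size = 3, max_sites = 2)
  expect_equal(sl2[[1]]$core$smiles, sl[[1]]$core$smiles)
  expect_setequal(sl2[[1]]$analogs$id, sl[[1]]$analogs$id)
})

test_that("series constructor validates reassembly and uniqueness", {
  ser <- mk_series(c("*C", "*F"), c("*OC", "*OC"), c(6, 7))
  expect_equal(ser$core$n_sites, 2L)
  expect_equal(ser$analogs$smiles,
               c(assemble_analog(ser$core, c("*C", "*OC")),
                 assemble_analog(ser$core, c("*F", "*OC"))))
  bad <- data.frame(id = c("a", "b"), sub_1 = c("*C", "*F"),
                    sub_2 = c("*OC", "*OC"), potency = c(6, 7),
                    smiles = c("CCO", "CCC"))
  expect_error(analog_series(TEST_CORE, bad), "do not reassemble")
})

test_that("substituent pools deduplicate, validate and filter by size", {
  ser <- mk_series(c("*C", "*C", "*F"), c("*OC", "*CC", "*OC"), c(6, 7, 8))
  pool <- build_pool(ser)
  expect_s3_class(pool, "substituent_pool")
  expect_setequal(pool$fragments, canonical_smiles(c("*C", "*F", "*OC", "*CC")))
  expect_equal(pool$provenance, "series")

  # idempotence
  pool2 <- build_pool(pool$fragments)
  expect_setequal(pool2$fragments, pool$fragments)

  # 14 heavy atoms filtered at the max-13 boundary, 13 kept
  frag13 <- paste0("*", paste(rep("C", 13), collapse = ""))
  frag14 <- paste0("*", paste(rep("C", 14), collapse = ""))
  p <- build_pool(c(frag13, frag14), max_heavy_atoms = 13)
  expect_length(p$fragments, 1L)
  expect_error(build_pool(frag14, max_heavy_atoms = 13), "empty pool")
  expect_error(build_pool("*C*"), "exactly one attachment")
  expect_error(build_pool("CC"), "exactly one attachment")
})
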