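# Molecule primitives: canonicalization, fingerprints, similarity, MCS,
# diversity picking.

test_that("canonicalization yields canonical nonisomeric molecules", {
  benzene <- canonicalize("c1ccccc1")
  expect_equal(benzene$heavy_atom_count, 6L)
  expect_identical(canonicalize("C1=CC=CC=C1")$smiles, benzene$smiles)

  # stereo tags are erased on ingest
  expect_identical(canonicalize("C[C@H](N)C(=O)O")$smiles,
                   canonicalize("CC(N)C(=O)O")$smiles)

  # 3-fluoro-4-methylaniline: C7 + N + F = 9 heavy atoms
  expect_equal(canonicalize("Cc1ccc(N)cc1F")$heavy_atom_count, 9L)

  expect_error(canonicalize("notasmiles"), class = "aa_parse_error")
  expect_error(canonicalize(""), class = "aa_parse_error")
})

test_that("canonicalization is idempotent and graphs round-trip", {
  for (s in panel_smiles) {
    m <- canonicalize(s)
    expect_identical(canonicalize(m$smiles)$smiles, m$smiles, label = s)
    # heavy atom count matches the parsed structure
    expect_equal(m$heavy_atom_count, m$graph$n, label = s)
    # writer round-trip: serialize the parsed graph and re-canonicalize
    rewritten <- aascore:::write_smiles_graph(m$graph)
    expect_identical(canonicalize(rewritten)$smiles, m$smiles, label = s)
  }
})

test_that("tanimoto matches the symbolic environment-enumeration oracle", {
  benzene <- mol("c1ccccc1"); toluene <- mol("Cc1ccccc1")
  # hand enumeration: benzene has 3 distinct environments (one per radius),
  # toluene 12, of which benzene's 3 are shared (the para CH environment is
  # indistinguishable from benzene's at radius <= 2), giving 3/12
  expect_equal(length(oracle_env_features(benzene)), 3L)
  expect_equal(length(oracle_env_features(toluene)), 12L)
  expect_equal(oracle_tanimoto(benzene, toluene), 0.25)
  expect_equal(tanimoto(benzene, toluene), 0.25)

  for (pair in list(c("CC(=O)O", "CCC(=O)O"), c("Nc1ccccc1", "Nc1ccc(C)cc1"),
                    c("CCO", "CCCO"))) {
    a <- mol(pair[[1]]); b <- mol(pair[[2]])
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b), label = paste(pair, collapse = "/"))
  }
})

test_that("tanimoto is an identity-1, symmetric, bounded similarity", {
  mols <- lapply(panel_smiles[1:8], mol)
  for (m in mols) expect_equal(tanimoto(m, m), 1)
  expect_equal(tanimoto(mol("C"),
                        mol("FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")), 0)
  for (i in 1:4) for (j in 1:4) {
    tij <- tanimoto(mols[[i]], mols[[j]])
    expect_identical(tij, tanimoto(mols[[j]], mols[[i]]))
    expect_gte(tij, 0); expect_lte(tij, 1)
  }
})

test_that("tanimoto refuses mismatched fingerprint parameters", {
  a <- aascore:::with_fp(mol("CCO"), list(radius = 2L, nbits = 2048L))
  b <- aascore:::with_fp(mol("CCCO"), list(radius = 1L, nbits = 1024L))
  expect_error(tanimoto(a, b), class = "aa_config_error")
})

test_that("MCS ratio matches exhaustive subgraph enumeration", {
  toluene <- mol("Cc1ccccc1"); benzene <- mol("c1ccccc1")
  expect_equal(oracle_mcs_size(toluene, benzene), 6L)
  expect_equal(mcs_heavy_atom_ratio(toluene, benzene), 6 / 7)
  # largest common connected subgraph of benzene and methane is one carbon
  expect_equal(oracle_mcs_size(benzene, mol("C")), 1L)
  expect_equal(mcs_heavy_atom_ratio(benzene, mol("C")), 1 / 6)
  # self-MCS is the whole molecule
  for (s in c("CC(=O)Nc1ccccc1", "c1cc[nH]c1")) {
    expect_equal(mcs_heavy_atom_ratio(mol(s), mol(s)), 1)
  }
  # a slightly larger pair, still checked against the exhaustive oracle
  a <- mol("CC(=O)Nc1ccccc1"); b <- mol("CCC(=O)Nc1ccccc1")
  expect_equal(mcs_heavy_atom_ratio(a, b) * a$heavy_atom_count,
               oracle_mcs_size(a, b))
})

test_that("MCS ratio is 1 exactly when the common subgraph covers the input", {
  pairs <- list(c("c1ccccc1", "Cc1ccccc1"), c("Cc1ccccc1", "c1ccccc1"),
                c("CCO", "CCOC"), c("CC(=O)O", "CC(=O)Nc1ccccc1"))
  for (p in pairs) {
    a <- mol(p[[1]]); b <- mol(p[[2]])
    ratio <- mcs_heavy_atom_ratio(a, b)
    size <- ratio * a$heavy_atom_count
    expect_lte(ratio, min(a$heavy_atom_count, b$heavy_atom_count) / a$heavy_atom_count)
    expect_identical(ratio == 1, abs(size - a$heavy_atom_count) < 1e-9,
                     label = paste(p, collapse = "/"))
  }
})

test_that("MCS respects its time budget", {
  a <- mol("c1ccc2ccccc2c1"); b <- mol("c1ccc2cc3ccccc3cc2c1")
  expect_error(aascore:::mcs_size(a, b, time_budget = 0), class = "aa_mcs_timeout")
})

test_that("maxmin_pick follows the greedy recurrence and is deterministic", {
  pool <- lapply(c("CCO", "CCCCCCCC", "c1ccccc1", "CC(=O)O"), mol)
  got <- vapply(maxmin_pick(pool, 4L, seed = 11L), function(m) m$smiles, character(1))
  expect_identical(got, oracle_maxmin(pool, 4L, seed = 11L))
  # all members picked when k = |pool| (a permutation)
  expect_setequal(got, vapply(pool, function(m) m$smiles, character(1)))
  # singleton pool
  expect_identical(maxmin_pick(pool[1], 1L, seed = 3L)[[1]]$smiles, pool[[1]]$smiles)
  # determinism for identical pool + seed
  for (seed in c(1L, 7L)) {
    a <- vapply(maxmin_pick(pool, 3L, seed), function(m) m$smiles, character(1))
    b <- vapply(maxmin_pick(pool, 3L, seed), function(m) m$smiles, character(1))
    expect_identical(a, b)
    expect_identical(a, oracle_maxmin(pool, 3L, seed))
  }
  expect_error(maxmin_pick(pool, 5L, seed = 1L), class = "aa_argument_error")
})
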