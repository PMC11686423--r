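# Atom mapping, leaving-group completion, center extraction and matching.

test_that("template steps carry maps; unmapped external steps are discarded", {
  step <- amide_step_for("CC(=O)Nc1ccccc1")
  expect_identical(map_reaction(step)$template_name, "amide_coupling")

  # pre-mapped external reaction SMILES: maps parsed and preserved verbatim
  mapped <- mapped_reactants_smiles(step)
  ext <- aascore:::step_from_mapped_smiles(mapped, step$product, rank = 1L)
  expect_identical(ext$template_name, "external")
  got <- map_reaction(ext)
  expect_false(is.null(got))
  expect_setequal(unlist(got$raw$maps)[!is.na(unlist(got$raw$maps))],
                  unlist(step$raw$maps)[!is.na(unlist(step$raw$maps))])

  # external proposal with no labels at all -> discarded
  plain <- paste(vapply(step$reactants, function(m) m$smiles, character(1)),
                 collapse = ".")
  ext2 <- aascore:::step_from_mapped_smiles(plain, step$product, rank = 1L)
  expect_null(map_reaction(ext2))
})

test_that("leaving groups complete the map and conserve heavy atoms", {
  # amide coupling: the acid hydroxyl oxygen leaves as the water by-product
  step <- complete_leaving_groups(amide_step_for("CC(=O)Nc1ccccc1"))
  expect_length(step$aug$byproducts, 1L)
  expect_identical(step$aug$byproducts[[1]]$atoms$elem, "O")
  expect_false(anyNA(unlist(step$aug$maps)))
  expect_identical(step_reactant_elements(step), step_product_side_elements(step))

  # N-alkylation: bromide is the leaving fragment
  steps <- propose_retro(mol("CNCc1ccccc1"))
  alk <- Filter(function(s) s$template_name == "n_alkylation", steps)[[1]]
  alk <- complete_leaving_groups(alk)
  expect_true(any(vapply(alk$aug$byproducts,
                         function(g) identical(g$atoms$elem, "Br"), logical(1))))
  expect_identical(step_reactant_elements(alk), step_product_side_elements(alk))

  # urea formation has no leaving group: completion is a no-op
  ure <- Filter(function(s) s$template_name == "urea",
                propose_retro(mol("O=C(Nc1ccccc1)NC1CCCCC1")))[[1]]
  ure <- complete_leaving_groups(ure)
  expect_length(ure$aug$byproducts, 0L)
  expect_identical(step_reactant_elements(ure), step_product_side_elements(ure))
})

test_that("aniline center is the amine nitrogen plus its radius-2 shell", {
  step <- complete_leaving_groups(amide_step_for("CC(=O)Nc1ccccc1"))
  smi <- vapply(step$reactants, function(m) m$smiles, character(1))
  ai <- which(smi == mol("Nc1ccccc1")$smiles)
  ctr <- extract_center(step, ai, radius = 2L)

  g <- step$raw$graphs[[ai]]
  n_atom <- which(g$atoms$elem == "N")
  expect_identical(ctr$core_atoms, n_atom)
  # extended: N + ipso carbon + the two ortho carbons
  expect_length(ctr$extended_atoms, 4L)
  expect_true(all(n_atom %in% ctr$extended_atoms))

  # radius 0: extended == core
  ctr0 <- extract_center(step, ai, radius = 0L)
  expect_identical(ctr0$extended_atoms, ctr0$core_atoms)

  # monotone nesting in the radius
  prev <- integer(0)
  for (r in 0:3) {
    ext <- extract_center(step, ai, radius = r)$extended_atoms
    expect_true(all(prev %in% ext), label = sprintf("radius %d", r))
    prev <- ext
  }

  # determinism: identical step + radius -> identical query string
  expect_identical(extract_center(step, ai, 2L)$smarts,
                   extract_center(step, ai, 2L)$smarts)
})

test_that("a one-heavy-atom reactant is wholly covered by its center", {
  # methylamine from N-methylbenzamide: the replaced reactant is tiny and the
  # extended center spans the entire molecule
  steps <- propose_retro(mol("CNC(=O)c1ccccc1"))
  amide <- Filter(function(s) s$template_name == "amide_coupling", steps)[[1]]
  amide <- complete_leaving_groups(amide)
  ridx <- select_replaced_reactant(amide)
  expect_identical(amide$reactants[[ridx]]$smiles, mol("CN")$smiles)
  ctr <- extract_center(amide, ridx, radius = 2L)
  expect_identical(sort(ctr$extended_atoms),
                   seq_len(amide$reactants[[ridx]]$heavy_atom_count))
})

test_that("centers self-match and discriminate aromatic from aliphatic amines", {
  step <- complete_leaving_groups(amide_step_for("CC(=O)Nc1ccccc1"))
  smi <- vapply(step$reactants, function(m) m$smiles, character(1))
  for (r in seq_along(step$reactants)) {
    ctr <- extract_center(step, r, radius = 2L)
    expect_true(center_matches(step$reactants[[r]], ctr),
                label = paste("self-match", smi[[r]]))
  }
  ai <- which(smi == mol("Nc1ccccc1")$smiles)
  ctr <- extract_center(step, ai, radius = 2L)
  expect_false(center_matches(mol("NC1CCCCC1"), ctr))  # aliphatic environment
  expect_true(center_matches(mol("Cc1ccc(N)cc1F"), ctr))  # substituted aniline
  expect_false(center_matches(mol("Oc1ccccc1"), ctr))
})
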