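# Retrosynthesis proposals, forward prediction, round-trip validation,
# curation, backend substitutability.

test_that("benzene admits no multi-reactant disconnection", {
  expect_length(propose_retro(mol("c1ccccc1")), 0L)
})

test_that("acetanilide disconnects into aniline + acetic acid", {
  steps <- propose_retro(mol("CC(=O)Nc1ccccc1"))
  expect_length(steps, 1L)
  expect_identical(steps[[1]]$template_name, "amide_coupling")
  expect_setequal(vapply(steps[[1]]$reactants, function(m) m$smiles, character(1)),
                  c(mol("Nc1ccccc1")$smiles, mol("CC(=O)O")$smiles))
})

test_that("multiple match sites yield distinct steps; symmetric sites collapse", {
  # asymmetric diamide: one disconnection per amide bond
  steps <- propose_retro(mol("O=C(Nc1ccccc1)c1ccc(C(=O)NC)cc1"))
  amide <- Filter(function(s) s$template_name == "amide_coupling", steps)
  expect_length(amide, 2L)
  keys <- vapply(amide, aascore:::step_reactant_key, character(1))
  expect_length(unique(keys), 2L)

  # symmetric diamide: both sites give the same reactant multiset -> one step
  steps_sym <- propose_retro(mol("O=C(Nc1ccccc1)c1ccc(C(=O)Nc2ccccc2)cc1"))
  amide_sym <- Filter(function(s) s$template_name == "amide_coupling", steps_sym)
  expect_length(amide_sym, 1L)
})

test_that("forward prediction applies the top-priority matching template", {
  expect_identical(predict_forward(c("Nc1ccccc1", "CC(=O)O"))$smiles,
                   mol("CC(=O)Nc1ccccc1")$smiles)
  expect_identical(predict_forward(c("Nc1ccc(C)cc1", "CC(=O)O"))$smiles,
                   mol("CC(=O)Nc1ccc(C)cc1")$smiles)
  # no applicable template
  expect_null(predict_forward(c("c1ccccc1")))
  expect_null(predict_forward(c("c1ccccc1", "C1CCCCC1")))
})

test_that("every shipped template round-trips on a matching fixture molecule", {
  fixtures <- c(
    amide_coupling = "CC(=O)Nc1ccccc1",
    sulfonamide = "CS(=O)(=O)Nc1ccccc1",
    ester = "COC(=O)c1ccccc1",
    urea = "O=C(Nc1ccccc1)NC1CCCCC1",
    n_alkylation = "CNCc1ccccc1",
    williamson_ether = "CCOCC1CCCCC1",
    suzuki_biaryl = "Cc1ccc(-c2ccccc2)cc1")
  for (tname in names(fixtures)) {
    input <- mol(fixtures[[tname]])
    steps <- Filter(function(s) s$template_name == tname, propose_retro(input))
    expect_gt(length(steps), 0, label = tname)
    rt <- vapply(steps, round_trip_validate, logical(1), input_mol = input)
    expect_true(any(rt), label = paste("round trip", tname))
  }
})

test_that("round-trip validation rejects corrupted or dead steps", {
  input <- mol("CC(=O)Nc1ccccc1")
  step <- propose_retro(input)[[1]]
  expect_true(round_trip_validate(step, input_mol = input))

  # swap a reactant for its homolog: recombines to a different product
  corrupted <- step
  acid_idx <- which(vapply(step$reactants, function(m) m$smiles == mol("CC(=O)O")$smiles,
                           logical(1)))
  corrupted$reactants[[acid_idx]] <- mol("CCC(=O)O")
  expect_false(round_trip_validate(corrupted, input_mol = input))

  # forward prediction returning nothing counts as failure
  dead <- step
  dead$reactants <- list(mol("c1ccccc1"), mol("C1CCCCC1"))
  expect_false(round_trip_validate(dead, input_mol = input))
})

test_that("curation applies its rules in order and preserves ranking", {
  input <- mol("CC(=O)Nc1ccccc1")
  good <- propose_retro(input)[[1]]
  # a step that fails round-trip (reactants recombine elsewhere)
  bad_rt <- good
  bad_rt$reactants <- list(mol("CCC(=O)O"), mol("Nc1ccccc1"))
  single <- good
  single$reactants <- list(mol("CC(=O)O"))
  ident <- good
  ident$reactants <- list(input, mol("O"))
  dup <- good

  steps <- list(good, bad_rt, single, ident, dup)
  for (i in seq_along(steps)) steps[[i]]$rank <- i
  out <- curate_reactant_sets(steps, input, k_keep = 7L)
  expect_length(out, 1L)
  expect_identical(out[[1]]$rank, 1L)
  drops <- attr(out, "drops")
  expect_equal(drops[["round_trip"]], 1L)
  expect_equal(drops[["multi_reactant"]], 1L)
  expect_equal(drops[["product_identity"]], 1L)
  expect_equal(drops[["dedup"]], 1L)

  # rank order is a subsequence of the input ranks; k_keep truncates
  many <- rep(list(good), 10L)
  for (i in seq_along(many)) {
    many[[i]]$rank <- i
    # make reactant sets distinct so dedup keeps them
    many[[i]]$reactants[[1]] <- mol(paste0("C", strrep("C", i), "C(=O)O"))
  }
  kept <- curate_reactant_sets(many, input, k_keep = 3L,
                               rules = c("parseable", "multi_reactant",
                                         "product_identity", "dedup"))
  expect_length(kept, 3L)
  expect_identical(vapply(kept, function(s) s$rank, integer(1)), 1:3)

  # everything failing round-trip yields an empty curated list
  all_bad <- curate_reactant_sets(list(bad_rt), input, k_keep = 7L)
  expect_length(all_bad, 0L)
})

test_that("a text backend with mapped output reproduces template-backend scores", {
  db <- aniline_db()
  input <- "O=C(Nc1ccccc1)c1ccccc1"

  ref <- score_compound(input, db)

  tpl_be <- template_backend()
  mock <- text_backend(
    retro = function(smiles, n) {
      steps <- propose_retro(canonicalize(smiles), tpl_be, n)
      vapply(steps, mapped_reactants_smiles, character(1))
    },
    forward = function(reactants) {
      p <- predict_forward(reactants, tpl_be)
      if (is.null(p)) NA_character_ else p$smiles
    })
  got <- score_compound(input, db, backends = list(retro = mock, forward = mock))

  expect_identical(got$score, ref$score)
  expect_setequal(got$analogs, ref$analogs)
  expect_gt(ref$score, 0L)
})
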