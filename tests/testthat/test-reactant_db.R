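# Database preparation profiles, replaced-reactant selection and the
# two-criterion candidate search.

test_that("prepare_db deduplicates and drops unparseable records", {
  db <- prepare_db(c("CCO", "OCC", "c1ccccc1", "C1=CC=CC=C1", "CCN"),
                   profile = "custom")
  expect_equal(nrow(db$entries), 3L)  # 5 records, 2 SMILES duplicates
  expect_equal(db$provenance$counts$input, 5L)

  db2 <- prepare_db(c("CCO", "not_a_smiles", "CCN"), profile = "custom")
  expect_equal(db2$provenance$counts$parsed, 2L)
  expect_equal(nrow(db2$entries), 2L)
})

test_that("size filters follow the database profile", {
  big45 <- paste0("C", strrep("C", 44))            # 45 heavy atoms
  mw300 <- "CCCCCCCCCCCCCCCCCCCCC(=O)O"            # C21 acid, MW ~ 326
  small <- "CC(=O)O"
  zinc <- prepare_db(c(big45, mw300, small), profile = "zinc_style")
  expect_false(any(zinc$entries$heavy > 40))
  expect_true(mol(mw300)$smiles %in% zinc$entries$smiles)   # <= 40 heavy: kept
  expect_false(mol(big45)$smiles %in% zinc$entries$smiles)

  emol <- prepare_db(c(mw300, small), profile = "emolecules_style")
  expect_false(mol(mw300)$smiles %in% emol$entries$smiles)  # MW > 250: dropped
  expect_true(mol(small)$smiles %in% emol$entries$smiles)
})

test_that("the smallest reactant is replaced; ties break lexicographically", {
  step <- amide_step_for("CC(=O)Nc1ccccc1")     # aniline(7) vs acetic acid(4)
  expect_identical(step$reactants[[select_replaced_reactant(step)]]$smiles,
                   mol("CC(=O)O")$smiles)

  step2 <- amide_step_for("O=C(Nc1ccccc1)c1ccccc1")  # aniline(7) vs benzoic(9)
  expect_identical(step2$reactants[[select_replaced_reactant(step2)]]$smiles,
                   mol("Nc1ccccc1")$smiles)

  # equal heavy-atom counts: lexicographically smaller canonical SMILES wins
  tie <- step
  tie$reactants <- list(mol("CCCO"), mol("CCCN"))
  smi <- vapply(tie$reactants, function(m) m$smiles, character(1))
  expect_identical(tie$reactants[[select_replaced_reactant(tie)]]$smiles,
                   sort(smi)[[1]])
})

aniline_center <- function() {
  step <- complete_leaving_groups(amide_step_for("CC(=O)Nc1ccccc1"))
  smi <- vapply(step$reactants, function(m) m$smiles, character(1))
  ai <- which(smi == mol("Nc1ccccc1")$smiles)
  list(center = extract_center(step, ai, 2L), replaced = step$reactants[[ai]])
}

test_that("candidate search enforces both qualification criteria", {
  ac <- aniline_center()
  replaced <- aascore:::with_fp(ac$replaced)

  expect_equal(nrow(search_candidates(
    prepare_db("CCCCCCCC", profile = "custom"), replaced, ac$center)), 0L)

  db <- toy_amine_db()
  got <- search_candidates(db, replaced, ac$center, sim_threshold = 0.4)
  # cyclohexylamine and phenol excluded by center mismatch; the anilines
  # qualify iff their similarity reaches the threshold
  expect_false(mol("NC1CCCCC1")$smiles %in% got$smiles)
  expect_false(mol("Oc1ccccc1")$smiles %in% got$smiles)
  for (s in c("Nc1ccc(C)cc1", "Nc1cccc(Cl)c1")) {
    should <- tanimoto(mol(s), replaced) >= 0.4
    expect_identical(mol(s)$smiles %in% got$smiles, should, label = s)
  }
  # exclusion soundness: every returned candidate passes both predicates
  for (i in seq_len(nrow(got))) {
    cand <- mol(got$smiles[[i]])
    expect_true(center_matches(cand, ac$center))
    expect_gte(tanimoto(cand, replaced), 0.4)
    expect_gte(got$similarity[[i]], 0.4)
  }
  expect_false(anyDuplicated(got$smiles) > 0)
  # similarity-descending order
  expect_true(all(diff(got$similarity) <= 0))
})

test_that("the replaced reactant itself is excluded from candidates", {
  ac <- aniline_center()
  db <- aniline_db(extra = "Nc1ccccc1 SELF")
  got <- search_candidates(db, aascore:::with_fp(ac$replaced), ac$center, 0.4)
  expect_false(mol("Nc1ccccc1")$smiles %in% got$smiles)
})

test_that("qualified sets shrink monotonically with the similarity threshold", {
  ac <- aniline_center()
  replaced <- aascore:::with_fp(ac$replaced)
  db <- aniline_db()
  sizes <- vapply(c(0, 0.2, 0.4, 0.6), function(t) {
    nrow(search_candidates(db, replaced, ac$center, sim_threshold = t))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # and every higher-threshold set is a subset of the lower-threshold set
  lo <- search_candidates(db, replaced, ac$center, 0.2)$smiles
  hi <- search_candidates(db, replaced, ac$center, 0.6)$smiles
  expect_true(all(hi %in% lo))
})

test_that("adding database entries never removes a qualified candidate", {
  ac <- aniline_center()
  replaced <- aascore:::with_fp(ac$replaced)
  base <- aniline_db()
  grown <- aniline_db(extra = c("Nc1ccc(CC)cc1 X01", "Nc1cc(F)ccc1C X02",
                                "CCCCO X03"))
  got_base <- search_candidates(base, replaced, ac$center, 0.4)$smiles
  got_grown <- search_candidates(grown, replaced, ac$center, 0.4)$smiles
  expect_true(all(got_base %in% got_grown))
})

test_that("the candidate cap truncates the similarity-ranked list", {
  ac <- aniline_center()
  replaced <- aascore:::with_fp(ac$replaced)
  db <- aniline_db()
  full <- search_candidates(db, replaced, ac$center, 0)
  capped <- search_candidates(db, replaced, ac$center, 0, cap = 2L)
  expect_equal(nrow(capped), 2L)
  expect_identical(capped$smiles, full$smiles[1:2])
})
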