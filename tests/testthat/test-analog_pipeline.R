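# End-to-end scoring: oracle equivalence, invariants, monotonicity,
# route validity, determinism.

test_that("benzene scores 0 with empty routes", {
  res <- score_compound("c1ccccc1", aniline_db())
  expect_equal(res$score, 0L)
  expect_length(res$routes, 0L)
  expect_length(res$analogs, 0L)
})

test_that("an empty database yields score 0 but curated steps > 0", {
  empty <- prepare_db("CCCCCCCCCC", profile = "custom")  # one decoy, no match
  res <- score_compound("O=C(Nc1ccccc1)c1ccccc1", empty)
  expect_equal(res$score, 0L)
  expect_gt(res$funnel$curated_steps, 0L)
  expect_equal(res$funnel$candidates, 0L)
})

test_that("score equals the exhaustive enumeration oracle on fixtures", {
  db <- toy_amine_db()
  for (s in c("CC(=O)Nc1ccccc1", "O=C(Nc1ccccc1)c1ccccc1")) {
    expect_equal(score_compound(s, db)$score, brute_force_score(s, db),
                 label = s)
  }
})

test_that("score counts unique analogs and every route replays forward", {
  res <- score_compound("O=C(Nc1ccccc1)c1ccccc1", aniline_db())
  expect_gt(res$score, 0L)
  expect_equal(res$score, length(res$analogs))
  expect_false(anyDuplicated(res$analogs) > 0)
  expect_false(res$input %in% res$analogs)
  route_analogs <- vapply(res$routes, function(r) r$analog$smiles, character(1))
  expect_setequal(unique(route_analogs), res$analogs)
  for (r in res$routes) {
    combo <- r$reaction_step$reactants
    combo[[r$replaced_idx]] <- canonicalize(r$candidate$smiles)
    replay <- predict_forward(combo)
    expect_identical(replay$smiles, r$analog$smiles)
    expect_gte(r$mcs_ratio, 2 / 3)
    expect_gte(r$candidate$similarity, 0.4)
  }
  # funnel counts never increase through record-removing stages
  fn <- res$funnel
  expect_lte(fn$curated_steps, fn$retro_proposals)
  expect_lte(fn$curated_products, fn$raw_products)
  expect_lte(fn$eligible_analogs, fn$curated_products)
  expect_lte(fn$unique_analogs, fn$eligible_analogs)
})

test_that("the MCS scaffold filter keeps and drops by the ratio rule", {
  toluene <- mol("Cc1ccccc1")
  routes <- lapply(c("c1ccccc1", "C"), function(s) list(analog = mol(s)))
  kept <- filter_products(routes, toluene, mcs_threshold = 2 / 3)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$analog$smiles, mol("c1ccccc1")$smiles)
  expect_equal(kept[[1]]$mcs_ratio, 6 / 7)

  benzene <- mol("c1ccccc1")
  expect_length(filter_products(list(list(analog = mol("C"))), benzene, 2 / 3), 0L)
})

test_that("score is monotone in database content and in both thresholds", {
  input <- "O=C(Nc1ccccc1)c1ccccc1"
  small <- aniline_db()
  grown <- aniline_db(extra = c("Nc1ccc(Br)cc1 X01", "Nc1ccc(N)cc1 X02"))
  expect_lte(score_compound(input, small)$score,
             score_compound(input, grown)$score)

  scores_sim <- vapply(c(0, 0.2, 0.4, 0.6), function(t) {
    score_compound(input, small, cfg = aa_config(sim_threshold = t))$score
  }, integer(1))
  expect_true(all(diff(scores_sim) <= 0))

  scores_mcs <- vapply(c(1 / 3, 1 / 2, 2 / 3, 5 / 6), function(t) {
    score_compound(input, small, cfg = aa_config(mcs_threshold = t))$score
  }, integer(1))
  expect_true(all(diff(scores_mcs) <= 0))
})

test_that("batch scoring aggregates and isolates failures", {
  db <- aniline_db()
  inputs <- c("O=C(Nc1ccccc1)c1ccccc1", "c1ccccc1")
  batch <- score_batch(inputs, db)
  scores <- vapply(batch$results, function(r) r$score, integer(1))
  expect_equal(batch$summary$mean_score, mean(scores))
  expect_equal(batch$summary$median_score, median(scores))

  # single-input batch equals the single result
  one <- score_batch(inputs[[1]], db)
  expect_equal(one$summary$mean_score, scores[[1]])

  # a bad SMILES does not abort the batch
  mixed <- score_batch(c("not_a_smiles", inputs), db)
  expect_equal(mixed$summary$n_scored, 2L)
  expect_true(is.na(mixed$results[[1]]$score))

  expect_error(score_batch(character(0), db), class = "aa_argument_error")
})

test_that("identical runs produce identical results", {
  db <- aniline_db()
  r1 <- score_compound("O=C(Nc1ccccc1)c1ccccc1", db)
  r2 <- score_compound("O=C(Nc1ccccc1)c1ccccc1", db)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$analogs, r2$analogs)
  expect_identical(r1$funnel, r2$funnel)
})
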