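# Exhaustive reference enumerator. Unlike the pipeline it takes no shortcuts:
# every template is applied at every match site, every database entry is
# tested against both qualification predicates directly, every candidate
# combination is re-assembled by forward prediction and every product is
# filtered explicitly. Intended for small fixture databases (<= a few dozen
# entries) where its cost is irrelevant; used by the `selftest` subcommand
# and the equivalence tests.

#' Brute-force analog count for a compound
#'
#' Exhaustively enumerates every (validated disconnection x database entry)
#' combination and counts unique eligible analogs. Must equal
#' [score_compound()]'s score on any input where both run with the same
#' configuration and template set.
#'
#' @param input_smiles input compound SMILES.
#' @param db `aa_reactant_db`.
#' @param templates template set (default: shipped).
#' @param cfg pipeline configuration.
#' @return integer analog count.
#' @export
brute_force_score <- function(input_smiles, db, templates = default_templates(),
                              cfg = aa_config()) {
  cfg <- validate_config(cfg)
  input_mol <- canonicalize(input_smiles)
  be <- template_backend(templates)

  # every validated, curated disconnection (same contract as the pipeline:
  # ranked template order, duplicates collapsed, top k_keep round-trip
  # survivors)
  steps <- list()
  seen <- character(0)
  for (tpl in templates) {
    for (app in apply_transform(tpl$retro, list(input_mol))) {
      st <- step_from_retro_application(tpl, app, input_mol)
      if (is.null(st)) next
      key <- step_reactant_key(st)
      if (key %in% seen) next
      seen <- c(seen, key)
      steps[[length(steps) + 1L]] <- st
    }
  }
  steps <- head(steps, cfg$n_retro)
  steps <- Filter(function(st) length(st$reactants) >= 2L, steps)
  steps <- Filter(function(st) {
    !any(vapply(st$reactants, function(m) mol_equal(m, input_mol), logical(1)))
  }, steps)
  steps <- Filter(function(st) {
    prod <- predict_forward(st$reactants, be)
    !is.null(prod) && mol_equal(prod, input_mol)
  }, steps)
  steps <- head(steps, cfg$k_keep)

  analogs <- character(0)
  for (st in steps) {
    st <- complete_leaving_groups(st)
    ridx <- select_replaced_reactant(st)
    center <- extract_center(st, ridx, cfg$center_radius, cfg$center_strictness)
    replaced <- with_fp(st$reactants[[ridx]], cfg$fp_params)
    for (e in seq_len(db_size(db))) {
      cand <- db$mols[[e]]
      if (cand$smiles == replaced$smiles) next
      if (!center_matches(cand, center)) next
      if (tanimoto_bits(mol_fp(cand, cfg$fp_params), mol_fp(replaced, cfg$fp_params)) <
          cfg$sim_threshold) next
      combo <- st$reactants
      combo[[ridx]] <- cand
      prod <- predict_forward(combo, be)
      if (is.null(prod)) next
      if (mol_equal(prod, input_mol)) next
      if (any(vapply(combo, function(m) mol_equal(m, prod), logical(1)))) next
      ratio <- tryCatch(
        mcs_heavy_atom_ratio(input_mol, prod, cfg$mcs_time_budget),
        aa_mcs_timeout = function(e) NA_real_)
      if (is.na(ratio) || ratio < cfg$mcs_threshold) next
      analogs <- c(analogs, prod$smiles)
    }
  }
  length(unique(analogs))
}
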