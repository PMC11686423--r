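# End-to-end analog accessibility scoring: retro proposals -> curation ->
# per-step center extraction and candidate search -> forward re-assembly ->
# product curation -> MCS scaffold filter -> unique-analog count.

#' Score a compound by its accessible analogs
#'
#' Runs the full pipeline for one input compound: single-step retrosynthesis
#' proposals are curated (round-trip validation included), the smallest
#' reactant of each surviving step is replaced by qualified database
#' candidates (same extended reaction center, Tanimoto >= threshold), products
#' are rebuilt by forward prediction, curated (unparseable, identical to the
#' input, or identical to a reactant of their own combination are dropped) and
#' filtered by the MCS heavy-atom-ratio scaffold criterion. The score is the
#' number of unique analogs; every analog is reported with its synthesis
#' route(s).
#'
#' @param input_smiles input compound SMILES.
#' @param db `aa_reactant_db` of purchasable reactants.
#' @param backends list with elements `retro` and `forward` (defaults: the
#'   shipped template backend for both).
#' @param cfg pipeline configuration from [aa_config()].
#' @return an `aa_result`: `input`, `score`, `analogs`, `routes`, `funnel`,
#'   `config_snapshot`, `candidate_failures`, `incomplete`.
#' @examples
#' \donttest{
#' db <- generate_fixture_db("anilines", 6, seed = 1)$db
#' res <- score_compound("CC(=O)Nc1ccccc1", db)
#' res$score
#' }
#' @export
score_compound <- function(input_smiles, db, backends = NULL, cfg = aa_config()) {
  backends <- normalize_backends(backends)
  cfg <- validate_config(cfg)
  input_mol <- with_fp(canonicalize(input_smiles), cfg$fp_params)

  funnel <- c(retro_proposals = 0L, curated_steps = 0L, candidates = 0L,
              raw_products = 0L, curated_products = 0L, eligible_analogs = 0L,
              unique_analogs = 0L)
  incomplete <- FALSE
  candidate_failures <- list()
  routes <- list()

  proposals <- propose_retro(input_mol, backends$retro, cfg$n_retro)
  funnel[["retro_proposals"]] <- length(proposals)

  curated <- curate_reactant_sets(proposals, input_mol, backends$forward,
                                  cfg$k_keep, rules = cfg$curation_rules)
  funnel[["curated_steps"]] <- length(curated)
  curation_drops <- attr(curated, "drops")

  for (step in curated) {
    step <- map_reaction(step, mapper = NULL)
    if (is.null(step)) { incomplete <- TRUE; next }
    step <- complete_leaving_groups(step)
    ridx <- select_replaced_reactant(step)
    center <- tryCatch(
      extract_center(step, ridx, cfg$center_radius, cfg$center_strictness),
      aa_center_error = function(e) {
        aa_log("WARN", "center extraction failed: %s", conditionMessage(e))
        NULL
      })
    if (is.null(center)) { incomplete <- TRUE; next }
    replaced <- with_fp(step$reactants[[ridx]], cfg$fp_params)

    cands <- search_candidates(db, replaced, center, cfg$sim_threshold,
                               cfg$candidate_cap)
    if (!nrow(cands)) {
      candidate_failures[[length(candidate_failures) + 1L]] <- list(
        step_rank = step$rank, template = step$template_name,
        replaced = replaced$smiles, center_smarts = center$smarts,
        center_covers_reactant = length(center$extended_atoms) ==
          replaced$heavy_atom_count,
        any_center_match = attr(cands, "diagnosis")$any_center_match,
        any_similar = attr(cands, "diagnosis")$any_similar,
        reason = attr(cands, "failure"))
      next
    }
    funnel[["candidates"]] <- funnel[["candidates"]] + nrow(cands)

    unchanged <- step$reactants[-ridx]
    cand_mols <- attr(cands, "mols")
    for (ci in seq_along(cand_mols)) {
      combo <- append(unchanged, cand_mols[ci], after = ridx - 1L)
      product <- predict_forward(combo, backends$forward)
      if (is.null(product)) next
      funnel[["raw_products"]] <- funnel[["raw_products"]] + 1L
      if (mol_equal(product, input_mol)) next
      if (any(vapply(combo, function(m) mol_equal(m, product), logical(1)))) next
      funnel[["curated_products"]] <- funnel[["curated_products"]] + 1L
      routes[[length(routes) + 1L]] <- list(
        reaction_step = step, candidate = list(
          smiles = cand_mols[[ci]]$smiles, id = cands$id[[ci]],
          similarity = cands$similarity[[ci]]),
        replaced_idx = ridx,
        unchanged_reactants = vapply(unchanged, function(m) m$smiles, character(1)),
        analog = product, mcs_ratio = NA_real_)
    }
  }

  eligible <- filter_products(routes, input_mol, cfg$mcs_threshold,
                              cfg$mcs_time_budget)
  funnel[["eligible_analogs"]] <- length(eligible)
  analog_smiles <- vapply(eligible, function(r) r$analog$smiles, character(1))
  uniq <- !duplicated(analog_smiles)
  analogs <- analog_smiles[uniq]
  funnel[["unique_analogs"]] <- length(analogs)

  structure(list(
    input = input_mol$smiles,
    score = length(analogs),
    analogs = analogs,
    routes = eligible,
    funnel = as.list(funnel),
    curation_drops = as.list(curation_drops),
    candidate_failures = candidate_failures,
    config_snapshot = config_snapshot(cfg),
    incomplete = incomplete
  ), class = "aa_result")
}

#' Apply the MCS scaffold filter to candidate products
#'
#' Keeps routes whose product shares at least `mcs_threshold` of the input's
#' heavy atoms with the input via the maximum common substructure, attaching
#' the computed ratio to each surviving route. An MCS timeout drops the
#' product conservatively (logged).
#'
#' @param routes list of route records carrying an `analog` molecule.
#' @param input_mol the input `aa_mol`.
#' @param mcs_threshold ratio threshold in (0, 1\] (default 2/3).
#' @param time_budget per-pair MCS budget in seconds.
#' @return the surviving routes with `mcs_ratio` filled in.
#' @export
filter_products <- function(routes, input_mol, mcs_threshold = 2 / 3,
                            time_budget = 10) {
  if (mcs_threshold <= 0 || mcs_threshold > 1) {
    stop_argument("mcs_threshold must be in (0,1]")
  }
  ratio_cache <- new.env(parent = emptyenv())
  out <- list()
  for (r in routes) {
    key <- r$analog$smiles
    ratio <- if (!is.null(ratio_cache[[key]])) ratio_cache[[key]] else {
      v <- tryCatch(mcs_heavy_atom_ratio(input_mol, r$analog, time_budget),
                    aa_mcs_timeout = function(e) {
                      aa_log("WARN", "MCS timeout for %s; analog dropped", key)
                      NA_real_
                    })
      ratio_cache[[key]] <- v
      v
    }
    if (!is.na(ratio) && ratio >= mcs_threshold) {
      r$mcs_ratio <- ratio
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

#' Score a batch of compounds
#'
#' Per-compound failures are isolated: a compound whose SMILES does not parse
#' (or whose run errors) is reported with `NA` score and does not abort the
#' batch.
#'
#' @param inputs character vector of SMILES.
#' @param db,backends,cfg as in [score_compound()].
#' @return list with `results` (per compound) and `summary` (mean/median score
#'   over successful runs, funnel totals).
#' @export
score_batch <- function(inputs, db, backends = NULL, cfg = aa_config()) {
  if (!length(inputs)) stop_argument("at least one input required")
  results <- lapply(inputs, function(s) {
    tryCatch(score_compound(s, db, backends, cfg), error = function(e) {
      aa_log("WARN", "scoring failed for '%s': %s", s, conditionMessage(e))
      structure(list(input = s, score = NA_integer_, analogs = character(0),
                     routes = list(), funnel = NULL,
                     error = conditionMessage(e), incomplete = TRUE),
                class = "aa_result")
    })
  })
  scores <- vapply(results, function(r) as.numeric(r$score), numeric(1))
  ok <- !is.na(scores)
  if (!any(ok)) stop_argument("all inputs failed to score")
  funnel_names <- names(results[[which(ok)[1]]]$funnel)
  funnel_totals <- sapply(funnel_names, function(nm) {
    sum(vapply(results[ok], function(r) r$funnel[[nm]], numeric(1)))
  }, simplify = FALSE)
  list(results = results,
       summary = list(n = length(inputs), n_scored = sum(ok),
                      mean_score = mean(scores[ok]),
                      median_score = median(scores[ok]),
                      funnel_totals = funnel_totals))
}

normalize_backends <- function(backends) {
  if (is.null(backends)) {
    be <- template_backend()
    return(list(retro = be, forward = be))
  }
  if (inherits(backends, "aa_backend")) {
    return(list(retro = backends, forward = backends))
  }
  if (is.null(backends$retro) || is.null(backends$forward)) {
    stop_config("backends must provide both 'retro' and 'forward'")
  }
  backends
}

#' @export
print.aa_result <- function(x, ...) {
  cat(sprintf("<AAscore %s: %s>\n", x$input,
              if (is.na(x$score)) "failed" else x$score))
  if (!is.null(x$funnel)) {
    cat(sprintf("  funnel: %s\n",
                paste(sprintf("%s=%d", names(x$funnel), unlist(x$funnel)),
                      collapse = " ")))
  }
  invisible(x)
}
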