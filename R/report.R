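# Machine-readable reports. Reports contain no timestamps or environment
# information, so identical runs produce byte-identical files.

route_record <- function(r) {
  step <- r$reaction_step
  reactant_smiles <- vapply(step$reactants, function(m) m$smiles, character(1))
  new_reactants <- reactant_smiles
  new_reactants[[r$replaced_idx]] <- r$candidate$smiles
  list(
    template = step$template_name,
    step_rank = step$rank,
    original_reactants = as.list(reactant_smiles),
    replaced_reactant = reactant_smiles[[r$replaced_idx]],
    candidate = r$candidate,
    analog = r$analog$smiles,
    mcs_ratio = r$mcs_ratio,
    reaction_smiles = paste0(paste(new_reactants, collapse = "."), ">>",
                             r$analog$smiles))
}

result_report <- function(res, db = NULL) {
  rep <- list(
    input = res$input,
    score = res$score,
    analogs = as.list(res$analogs),
    routes = lapply(res$routes, route_record),
    funnel = res$funnel,
    curation_drops = res$curation_drops,
    candidate_failures = res$candidate_failures,
    config = res$config_snapshot,
    incomplete = res$incomplete)
  if (!is.null(db)) rep$db_provenance <- db$provenance[c("source", "profile", "limits", "counts")]
  rep
}

#' Write a scoring report as JSON
#'
#' @param res an `aa_result` (or batch list from [score_batch()]).
#' @param path output file.
#' @param db optional `aa_reactant_db` whose provenance is embedded.
#' @return `path`, invisibly.
#' @export
write_report <- function(res, path, db = NULL) {
  payload <- if (inherits(res, "aa_result")) {
    result_report(res, db)
  } else {
    list(results = lapply(res$results, result_report),
         summary = res$summary,
         db_provenance = if (!is.null(db)) db$provenance[c("source", "profile", "limits", "counts")])
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Write a one-row-per-input CSV summary
#'
#' @param batch result of [score_batch()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_csv_summary <- function(batch, path) {
  rows <- lapply(batch$results, function(r) {
    fn <- r$funnel
    data.frame(
      smiles = r$input, score = r$score,
      retro_proposals = if (is.null(fn)) NA else fn$retro_proposals,
      curated_steps = if (is.null(fn)) NA else fn$curated_steps,
      candidates = if (is.null(fn)) NA else fn$candidates,
      raw_products = if (is.null(fn)) NA else fn$raw_products,
      curated_products = if (is.null(fn)) NA else fn$curated_products,
      eligible_analogs = if (is.null(fn)) NA else fn$eligible_analogs,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
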