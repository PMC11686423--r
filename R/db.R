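# Purchasable-compound database: ingest, curation profiles, fingerprint
# index and the two-criterion candidate-reactant search.

#' Prepare a reactant database from SMILES or SDF input
#'
#' Drops unparseable records, deduplicates on canonical nonisomeric SMILES and
#' applies the size filter of the chosen profile: `zinc_style` removes
#' molecules with more than 40 heavy atoms; `emolecules_style` removes
#' molecules with molecular weight above 250; `custom` applies the explicit
#' `max_heavy` / `max_mw` arguments. A fingerprint index is built over the
#' survivors and per-stage record counts are kept as provenance.
#'
#' @param raw a character vector of SMILES (optionally "SMILES ID" per
#'   element), or a path to a `.smi`/`.txt` SMILES file or an `.sdf` file.
#' @param profile `"zinc_style"`, `"emolecules_style"` or `"custom"`.
#' @param max_heavy,max_mw explicit limits for the `custom` profile (NA = no
#'   limit).
#' @param fp_params fingerprint settings (radius, nbits).
#' @param source_name free-text provenance label.
#' @return an `aa_reactant_db`: `entries` (data.frame id, smiles, heavy, mw),
#'   `mols` (fingerprinted `aa_mol` list) and `provenance` (filters + counts).
#' @export
prepare_db <- function(raw, profile = c("zinc_style", "emolecules_style", "custom"),
                       max_heavy = NA, max_mw = NA,
                       fp_params = default_fp_params(),
                       source_name = "unspecified") {
  profile <- match.arg(profile)
  records <- read_db_records(raw)
  if (!length(records$smiles)) stop_argument("reactant database input has no records")
  limits <- switch(profile,
    zinc_style = list(max_heavy = 40, max_mw = NA),
    emolecules_style = list(max_heavy = NA, max_mw = 250),
    custom = list(max_heavy = max_heavy, max_mw = max_mw))

  counts <- c(input = length(records$smiles), parsed = 0L, deduplicated = 0L,
              size_filtered = 0L)
  mols <- list(); ids <- character(0); seen <- character(0)
  n_parsed <- 0L
  for (i in seq_along(records$smiles)) {
    m <- tryCatch(canonicalize(records$smiles[[i]]),
                  aa_parse_error = function(e) {
                    aa_log("DEBUG", "dropping unparseable DB record '%s'",
                           records$smiles[[i]])
                    NULL
                  })
    if (is.null(m)) next
    n_parsed <- n_parsed + 1L
    if (m$smiles %in% seen) next
    seen <- c(seen, m$smiles)
    mols[[length(mols) + 1L]] <- m
    ids <- c(ids, records$ids[[i]])
  }
  counts[["parsed"]] <- n_parsed
  counts[["deduplicated"]] <- length(mols)

  keep <- vapply(mols, function(m) {
    ok <- TRUE
    if (!is.na(limits$max_heavy)) ok <- ok && m$heavy_atom_count <= limits$max_heavy
    if (!is.na(limits$max_mw)) ok <- ok && !is.na(m$mw) && m$mw <= limits$max_mw
    ok
  }, logical(1))
  mols <- mols[keep]; ids <- ids[keep]
  counts[["size_filtered"]] <- length(mols)
  if (!length(mols)) aa_log("WARN", "reactant DB is empty after filtering; scores will be 0")

  mols <- lapply(mols, with_fp, fp_params = fp_params)
  entries <- data.frame(
    id = ids,
    smiles = vapply(mols, function(m) m$smiles, character(1)),
    heavy = vapply(mols, function(m) m$heavy_atom_count, integer(1)),
    mw = vapply(mols, function(m) m$mw, numeric(1)),
    stringsAsFactors = FALSE)

  structure(list(entries = entries, mols = mols,
                 provenance = list(source = source_name, profile = profile,
                                   limits = limits, counts = as.list(counts),
                                   fp_params = fp_params)),
            class = "aa_reactant_db")
}

read_db_records <- function(raw) {
  if (length(raw) == 1L && is.character(raw) && file.exists(raw) &&
      !grepl("[[:space:]]", raw)) {
    if (grepl("\\.sdf$", raw, ignore.case = TRUE)) {
      txt <- paste(readLines(raw, warn = FALSE), collapse = "\n")
      out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
      lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      return(list(smiles = vapply(parts, `[`, character(1), 1L),
                  ids = vapply(seq_along(parts), function(i) {
                    p <- parts[[i]]
                    if (length(p) > 1L && nzchar(trimws(p[[2]]))) trimws(p[[2]])
                    else sprintf("SDF%05d", i)
                  }, character(1))))
    }
    raw <- readLines(raw, warn = FALSE)
  }
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  parts <- strsplit(raw, "[[:space:]]+")
  list(smiles = vapply(parts, `[`, character(1), 1L),
       ids = vapply(seq_along(parts), function(i) {
         p <- parts[[i]]
         if (length(p) > 1L) p[[2]] else sprintf("DB%05d", i)
       }, character(1)))
}

#' @export
print.aa_reactant_db <- function(x, ...) {
  cat(sprintf("<ReactantDB %s (%s): %d entries>\n", x$provenance$source,
              x$provenance$profile, nrow(x$entries)))
  cnt <- x$provenance$counts
  cat(sprintf("  funnel: %d input -> %d parsed -> %d unique -> %d size-filtered\n",
              cnt$input, cnt$parsed, cnt$deduplicated, cnt$size_filtered))
  invisible(x)
}

db_size <- function(db) nrow(db$entries)

#' Pick the replaced reactant of a step
#'
#' The smallest reactant by heavy-atom count is the one swapped for database
#' candidates; ties are broken by canonical-SMILES lexicographic order
#' (smallest string wins).
#'
#' @param step an `aa_step` with >= 2 reactants.
#' @return integer index into `step$reactants`.
#' @export
select_replaced_reactant <- function(step) {
  if (length(step$reactants) < 2L) stop_argument("step must have >= 2 reactants")
  heavy <- vapply(step$reactants, function(m) m$heavy_atom_count, integer(1))
  smi <- vapply(step$reactants, function(m) m$smiles, character(1))
  ord <- order(heavy, smi, method = "radix")
  ord[[1L]]
}

#' Search qualified candidate reactants
#'
#' Returns database entries satisfying BOTH qualification criteria: the entry
#' contains the extended reaction center, and its Tanimoto similarity to the
#' replaced reactant is at least `sim_threshold`. The replaced reactant
#' itself, if present in the database, is excluded (it would regenerate the
#' input, not an analog). Results are sorted by similarity descending (ties
#' by canonical SMILES) and truncated at `cap`.
#'
#' @param db `aa_reactant_db`.
#' @param replaced `aa_mol`, the reactant being replaced.
#' @param center `aa_center` extracted from the replaced reactant.
#' @param sim_threshold Tanimoto threshold in \[0, 1\] (default 0.4).
#' @param cap maximum number of candidates (0 = unlimited).
#' @return data.frame (class kept plain) with columns `id`, `smiles`,
#'   `similarity`, `center_matched`, plus the molecule list as attribute
#'   `mols`. The `diagnosis` attribute records `any_center_match`,
#'   `any_similar` and a `reason` string (`"ok"`, `"no_center_match"`,
#'   `"no_similar"`, `"no_center_match_and_no_similar"`, `"empty_db"`) so
#'   no-candidate situations are attributable to the failing criterion.
#' @export
search_candidates <- function(db, replaced, center, sim_threshold = 0.4, cap = 0L) {
  if (sim_threshold < 0 || sim_threshold > 1) stop_argument("sim_threshold must be in [0,1]")
  if (cap < 0L) stop_argument("cap must be >= 0")
  n <- db_size(db)
  if (!n) return(candidate_result(db, integer(0), numeric(0), "empty_db"))

  rfp <- mol_fp(replaced, db$provenance$fp_params)
  not_self <- vapply(db$mols, function(m) m$smiles != replaced$smiles, logical(1))
  center_ok <- logical(n)
  center_ok[not_self] <- vapply(db$mols[not_self], center_matches,
                                logical(1), center = center)
  sims <- rep(NA_real_, n)
  sims[not_self] <- vapply(db$mols[not_self], function(m) {
    tanimoto_bits(mol_fp(m, db$provenance$fp_params), rfp)
  }, numeric(1))
  sim_ok <- !is.na(sims) & sims >= sim_threshold

  qualified <- which(center_ok & sim_ok)
  diagnosis <- list(any_center_match = any(center_ok),
                    any_similar = any(sim_ok, na.rm = TRUE))
  diagnosis$reason <- if (length(qualified)) "ok"
    else if (!diagnosis$any_center_match && !diagnosis$any_similar) "no_center_match_and_no_similar"
    else if (!diagnosis$any_center_match) "no_center_match"
    else "no_similar"
  if (diagnosis$reason != "ok") {
    aa_log("INFO", "no qualified candidates for %s (center %s): %s",
           replaced$smiles, center$smarts, diagnosis$reason)
  }
  ord <- qualified[order(-sims[qualified], db$entries$smiles[qualified],
                         method = "radix")]
  if (cap > 0L && length(ord) > cap) ord <- ord[seq_len(cap)]
  candidate_result(db, ord, sims[ord], diagnosis)
}

candidate_result <- function(db, idx, sims, diagnosis) {
  if (is.character(diagnosis)) {
    diagnosis <- list(any_center_match = FALSE, any_similar = FALSE,
                      reason = diagnosis)
  }
  out <- data.frame(
    id = db$entries$id[idx],
    smiles = db$entries$smiles[idx],
    similarity = as.numeric(sims),
    center_matched = rep(TRUE, length(idx)),
    stringsAsFactors = FALSE)
  attr(out, "mols") <- db$mols[idx]
  attr(out, "failure") <- diagnosis$reason
  attr(out, "diagnosis") <- diagnosis
  out
}
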