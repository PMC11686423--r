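# Molecule: canonical nonisomeric SMILES + parsed graph + lazy fingerprint.

#' Canonicalize a SMILES string into a Molecule
#'
#' Produces the canonical nonisomeric form of the input: stereochemistry is
#' stripped on ingest and the remaining structure is canonicalized by Open
#' Babel. Two molecules are considered identical throughout the package iff
#' their canonical nonisomeric SMILES strings are equal, which is also the
#' identity used for database deduplication and unique-analog counting.
#'
#' @param smiles_in a single SMILES string.
#' @return an object of class `aa_mol` with elements `smiles` (canonical
#'   nonisomeric SMILES), `heavy_atom_count`, `mw` and the parsed graph.
#' @examples
#' m <- canonicalize("C[C@@H](N)C(=O)O")
#' identical(m$smiles, canonicalize("CC(N)C(=O)O")$smiles)
#' @export
canonicalize <- function(smiles_in) {
  if (!is.character(smiles_in) || length(smiles_in) != 1L || !nzchar(trimws(smiles_in))) {
    stop_parse(paste(smiles_in, collapse = ","), "SMILES must be a non-empty string")
  }
  can <- canonical_smiles(smiles_in)
  graph_to_mol(parse_smiles_graph(can), can)
}

# Raw canonical nonisomeric SMILES via Open Babel; parse failure signalled as
# an aa_parse_error condition.
canonical_smiles <- function(smiles_in) {
  s <- trimws(smiles_in)
  # nonisomeric: drop stereo marks before canonicalization
  s <- gsub("@", "", s, fixed = TRUE)
  s <- gsub("/", "", s, fixed = TRUE)
  s <- gsub("\\", "", s, fixed = TRUE)
  if (!nzchar(s)) stop_parse(smiles_in, "empty SMILES")
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s))
  out <- sub("\t.*$", "", sub("\n$", "", out))
  out <- trimws(out)
  if (!nzchar(out)) stop_parse(smiles_in)
  out
}

graph_to_mol <- function(g, can_smiles) {
  structure(
    list(smiles = can_smiles,
         heavy_atom_count = g$n,
         mw = graph_mw(g),
         graph = g),
    class = "aa_mol"
  )
}

# Serialize a working graph back into a canonical Molecule (used after
# reaction edits). Returns NULL if the graph does not round-trip through
# canonicalization (malformed valence etc.).
graph_to_canonical_mol <- function(g) {
  smi <- tryCatch(write_smiles_graph(g), error = function(e) NULL)
  if (is.null(smi)) return(NULL)
  tryCatch(canonicalize(smi), aa_parse_error = function(e) NULL)
}

is_aa_mol <- function(x) inherits(x, "aa_mol")

mol_equal <- function(a, b) identical(a$smiles, b$smiles)

#' @export
print.aa_mol <- function(x, ...) {
  cat(sprintf("<Molecule %s  heavy atoms: %d  MW: %.1f>\n",
              x$smiles, x$heavy_atom_count, x$mw))
  invisible(x)
}

#' @export
format.aa_mol <- function(x, ...) x$smiles

# Fingerprint accessor with memoisation on the molecule object is not possible
# for plain lists passed by value; callers that loop keep their own cache.
mol_fp <- function(m, fp_params = NULL) {
  if (!is.null(m$fp)) return(m$fp)
  if (is.null(fp_params)) fp_params <- default_fp_params()
  ecfp_bits(m, radius = fp_params$radius, nbits = fp_params$nbits)
}

# Attach the fingerprint eagerly (DB entries, pipeline molecules).
with_fp <- function(m, fp_params = NULL) {
  if (is.null(fp_params)) fp_params <- default_fp_params()
  m$fp <- mol_fp(m, fp_params)
  m$fp_params <- fp_params
  m
}

default_fp_params <- function() list(radius = 2L, nbits = 2048L)
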