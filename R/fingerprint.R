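# Circular substructure fingerprints (ECFP4-equivalent at the defaults:
# radius 2, folded to 2048 binary bits). Atom invariants: element, formal
# charge, heavy-atom degree, hydrogen count, ring membership, aromaticity.

.elem_code <- function(e) {
  codes <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
             P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Br = 35, I = 53)
  out <- codes[e]
  out[is.na(out)] <- 99
  unname(out)
}

# Deterministic 31-bit integer hash of an integer vector.
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 131 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Circular fingerprint on-bit indices
#'
#' Computes radius-0..`radius` circular atom-environment identifiers by
#' iterative neighbourhood hashing and folds them into `nbits` binary bits.
#' Returns the sorted vector of on-bit indices (0-based), the set form used by
#' all similarity computations in the package.
#'
#' @param mol an `aa_mol`.
#' @param radius neighbourhood radius (default 2, i.e. ECFP4-equivalent).
#' @param nbits folded length (default 2048).
#' @return sorted integer vector of on-bit indices.
#' @export
ecfp_bits <- function(mol, radius = 2L, nbits = 2048L) {
  g <- mol$graph
  n <- g$n
  nbr <- lapply(seq_len(n), function(i) graph_neighbors(g, i))
  bcode <- function(row) if (row[["arom"]]) 4L else as.integer(row[["order"]])

  inv <- vapply(seq_len(n), function(i) {
    hash_ints(c(.elem_code(g$atoms$elem[[i]]), g$atoms$charge[[i]],
                nrow(nbr[[i]]), g$atoms$h[[i]],
                as.integer(g$atoms$ring[[i]]), as.integer(g$atoms$arom[[i]])))
  }, integer(1))
  feats <- inv

  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(n), function(i) {
      nb <- nbr[[i]]
      if (!nrow(nb)) return(hash_ints(c(inv[[i]], r)))
      pairs <- cbind(vapply(seq_len(nrow(nb)), function(k) bcode(nb[k, ]), integer(1)),
                     inv[nb$nbr])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash_ints(c(inv[[i]], r, t(pairs)))
    }, integer(1))
    inv <- inv_new
    feats <- c(feats, inv)
  }

  sort(unique(as.integer(unique(feats) %% nbits)))
}

#' Tanimoto similarity between two molecules
#'
#' Intersection-over-union of the binary circular-fingerprint feature sets.
#' Both molecules must carry fingerprints computed with identical parameters
#' (the pipeline uses one fingerprint configuration everywhere).
#'
#' @param a,b `aa_mol` objects (fingerprints computed on the fly if absent).
#' @return similarity in \[0, 1\]; 1 for identical molecules.
#' @export
tanimoto <- function(a, b) {
  if (!is.null(a$fp_params) && !is.null(b$fp_params) &&
      !identical(a$fp_params, b$fp_params)) {
    stop_config("fingerprint parameter mismatch between molecules")
  }
  fa <- mol_fp(a, a$fp_params); fb <- mol_fp(b, b$fp_params)
  tanimoto_bits(fa, fb)
}

tanimoto_bits <- function(fa, fb) {
  u <- length(union(fa, fb))
  if (u == 0L) return(1)
  length(intersect(fa, fb)) / u
}
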