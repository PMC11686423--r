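# MaxMin diversity picking on Tanimoto distance.

#' Select k diverse molecules by the MaxMin algorithm
#'
#' Greedy MaxMin on Tanimoto distance (1 - similarity): the first pick is
#' drawn with the seeded random number generator; every subsequent pick
#' maximizes the minimum distance to the already-picked set. Ties on the
#' min-distance criterion are broken by canonical-SMILES lexicographic order,
#' so a given pool and seed always yield the same selection.
#'
#' @param pool list of `aa_mol` objects.
#' @param k number of molecules to select (`k <= length(pool)`).
#' @param seed integer seed for the first pick.
#' @return list of `k` molecules (a subset of `pool`).
#' @export
maxmin_pick <- function(pool, k, seed = 42L) {
  if (!length(pool) || k > length(pool)) {
    stop_argument("k must not exceed the pool size")
  }
  if (k < 1L) stop_argument("k must be >= 1")
  n <- length(pool)
  fps <- lapply(pool, mol_fp)
  smi <- vapply(pool, function(m) m$smiles, character(1))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  picked <- sample.int(n, 1L)

  dist_to_picked <- vapply(seq_len(n), function(i) {
    1 - tanimoto_bits(fps[[i]], fps[[picked[[1L]]]])
  }, numeric(1))
  dist_to_picked[picked] <- -Inf

  while (length(picked) < k) {
    mx <- max(dist_to_picked)
    ties <- which(dist_to_picked == mx)
    nxt <- ties[order(smi[ties])][[1L]]
    picked <- c(picked, nxt)
    upd <- vapply(seq_len(n), function(i) {
      1 - tanimoto_bits(fps[[i]], fps[[nxt]])
    }, numeric(1))
    dist_to_picked <- pmin(dist_to_picked, upd)
    dist_to_picked[picked] <- -Inf
  }
  pool[picked]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
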