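# Molecular graph -> SMILES. Output is not canonical; it is always passed
# through Open Babel canonicalization before leaving the package.

write_smiles_graph <- function(g, with_maps = FALSE) {
  n <- g$n
  if (n == 1L) return(atom_token(g, 1L, with_maps))

  nb <- nrow(g$bonds)
  tree <- logical(nb)
  back <- logical(nb)
  visited <- logical(n)
  child_order <- vector("list", n)  # tree children (bond indices) per atom

  # Pass 1: iterative DFS to classify tree vs back (ring-closure) edges.
  stack <- list(list(atom = 1L, from = NA_integer_))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- top$atom
    if (visited[[i]]) next
    visited[[i]] <- TRUE
    nbrs <- graph_neighbors(g, i)
    for (r in seq_len(nrow(nbrs))) {
      k <- nbrs$bond[[r]]; j <- nbrs$nbr[[r]]
      if (!is.na(top$from) && k == top$from) next
      if (visited[[j]]) {
        if (!tree[[k]] && !back[[k]]) back[[k]] <- TRUE
      }
    }
    for (r in rev(seq_len(nrow(nbrs)))) {
      k <- nbrs$bond[[r]]; j <- nbrs$nbr[[r]]
      if (!visited[[j]] && !tree[[k]]) {
        # may be re-pushed; resolved by the visited check on pop
        stack[[length(stack) + 1L]] <- list(atom = j, from = k)
      }
    }
  }
  # Tree edges: a bond is a tree edge iff it connects an atom to the atom that
  # discovered it. Reconstruct: any non-back bond is a tree edge.
  tree <- !back

  ring_id <- rep(NA_integer_, nb)
  ring_id[back] <- seq_len(sum(back))
  ring_seen <- logical(nb)

  out <- character(0)
  push <- function(x) if (nzchar(x)) out[[length(out) + 1L]] <<- x
  visited2 <- logical(n)

  emit <- function(i, from_bond) {
    visited2[[i]] <<- TRUE
    push(atom_token(g, i, with_maps))
    nbrs <- graph_neighbors(g, i)
    # ring-closure digits at this atom
    for (r in seq_len(nrow(nbrs))) {
      k <- nbrs$bond[[r]]
      if (back[[k]]) {
        if (!ring_seen[[k]]) {
          ring_seen[[k]] <<- TRUE
          push(paste0(bond_token(g, k), ring_digit(ring_id[[k]])))
        } else {
          push(ring_digit(ring_id[[k]]))
        }
      }
    }
    kids <- which(tree[nbrs$bond] & !visited2[nbrs$nbr])
    for (idx in seq_along(kids)) {
      r <- kids[[idx]]
      j <- nbrs$nbr[[r]]; k <- nbrs$bond[[r]]
      if (visited2[[j]]) next
      remaining <- kids[-seq_len(idx)]
      last <- !length(remaining) || all(visited2[nbrs$nbr[remaining]])
      if (!last) push("(")
      push(bond_token(g, k))
      emit(j, k)
      if (!last) push(")")
    }
  }
  emit(1L, NA_integer_)
  paste0(out, collapse = "")
}

ring_digit <- function(id) if (id < 10L) as.character(id) else sprintf("%%%02d", id)

bond_token <- function(g, k) {
  if (g$bonds$arom[[k]]) return("")
  o <- g$bonds$order[[k]]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # explicit single bond between two aromatic atoms (e.g. biphenyl linker)
  if (g$atoms$arom[[g$bonds$a1[[k]]]] && g$atoms$arom[[g$bonds$a2[[k]]]]) "-" else ""
}

atom_token <- function(g, i, with_maps = FALSE) {
  elem <- g$atoms$elem[[i]]
  arom <- g$atoms$arom[[i]]
  chg <- g$atoms$charge[[i]]
  h <- g$atoms$h[[i]]
  mp <- g$atoms$map[[i]]
  sym <- if (arom) tolower(elem) else elem
  plain_ok <- elem %in% .organic_subset && chg == 0L &&
    (is.na(mp) || !with_maps) && h == implicit_h(g, i)
  if (plain_ok) return(sym)
  paste0(
    "[", sym,
    if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
    if (chg > 0L) paste0("+", if (chg > 1L) chg else "") else "",
    if (chg < 0L) paste0("-", if (chg < -1L) -chg else "") else "",
    if (with_maps && !is.na(mp)) paste0(":", mp) else "",
    "]"
  )
}
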