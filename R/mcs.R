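# Connected maximum common (induced) substructure between two molecules.
# Atoms are compared by element; bonds by order class (aromatic bonds are
# their own class) and ring membership. Branch-and-bound: at each node one
# frontier atom of the first molecule is either mapped to a compatible atom
# of the second or permanently excluded, so each common subgraph is visited
# once. A wall-clock budget guards pathological pairs; exceeding it raises an
# aa_mcs_timeout condition so callers can treat the pair conservatively.

mcs_size <- function(a, b, time_budget = 10) {
  ga <- a$graph; gb <- b$graph
  na_ <- ga$n; nb_ <- gb$n
  deadline <- Sys.time() + time_budget

  nbr_a <- lapply(seq_len(na_), function(i) graph_neighbors(ga, i)$nbr)
  bcode <- function(g, k) paste0(bond_code(g, k), if (g$bonds$ring[[k]]) "@" else "")

  best <- 0L
  map_ab <- rep(NA_integer_, na_)
  used_b <- logical(nb_)
  excluded <- logical(na_)
  size <- 0L

  compatible <- function(i, j) {
    if (ga$atoms$elem[[i]] != gb$atoms$elem[[j]]) return(FALSE)
    connected <- size == 0L
    for (p in which(!is.na(map_ab))) {
      q <- map_ab[[p]]
      ka <- bond_between(ga, i, p)
      kb <- bond_between(gb, j, q)
      if (is.na(ka) != is.na(kb)) return(FALSE)
      if (!is.na(ka)) {
        if (bcode(ga, ka) != bcode(gb, kb)) return(FALSE)
        connected <- TRUE
      }
    }
    connected
  }

  rec <- function() {
    if (size > best) best <<- size
    if (Sys.time() > deadline) stop_mcs_timeout(time_budget)
    avail <- !excluded & is.na(map_ab)
    if (size + sum(avail) <= best || size + (nb_ - size) <= best) return(invisible(NULL))
    cand <- if (size == 0L) which(avail) else {
      mapped <- which(!is.na(map_ab))
      frontier <- unique(unlist(nbr_a[mapped]))
      frontier[avail[frontier]]
    }
    if (!length(cand)) return(invisible(NULL))
    i <- cand[[1L]]
    for (j in which(!used_b)) {
      if (!compatible(i, j)) next
      map_ab[[i]] <<- j; used_b[[j]] <<- TRUE; size <<- size + 1L
      rec()
      map_ab[[i]] <<- NA_integer_; used_b[[j]] <<- FALSE; size <<- size - 1L
    }
    excluded[[i]] <<- TRUE
    rec()
    excluded[[i]] <<- FALSE
    invisible(NULL)
  }
  rec()
  best
}

#' Heavy-atom MCS ratio between an input compound and an analog
#'
#' Size (in heavy atoms) of the connected maximum common substructure of the
#' pair, divided by the heavy-atom count of the INPUT compound. The analog
#' scaffold filter keeps analogs with ratio >= the configured threshold
#' (default 2/3).
#'
#' @param input_mol,analog `aa_mol` objects; the denominator is always
#'   `input_mol$heavy_atom_count`.
#' @param time_budget seconds allowed for the MCS search (default 10);
#'   exceeding it signals an `aa_mcs_timeout` condition.
#' @return ratio in \[0, 1\].
#' @examples
#' mcs_heavy_atom_ratio(canonicalize("Cc1ccccc1"), canonicalize("c1ccccc1"))
#' @export
mcs_heavy_atom_ratio <- function(input_mol, analog, time_budget = 10) {
  mcs_size(input_mol, analog, time_budget) / input_mol$heavy_atom_count
}
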