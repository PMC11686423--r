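# Transformation engine: applies a parsed transformation (lhs patterns >>
# rhs patterns) to a list of molecules. Shared by retro proposal (one input
# molecule, >= 2 output fragments) and forward prediction (>= 2 reactants,
# one product plus leaving fragments).
#
# Semantics: atom-map labels link lhs and rhs atoms. Mapped bonds present on
# one side only are deleted/created; order changes follow the rhs. Unmapped
# lhs atoms are detached from the mapped skeleton (they become leaving
# fragments); unmapped rhs atoms are created and attached. Hydrogen counts of
# every touched atom are refilled by standard valence rules.

# All applications of `transform` to `mols` (list of aa_mol), in deterministic
# order: molecule-to-pattern assignment, then match order. Each application:
# list(union = edited graph, comp = component id per union atom,
#      prov = data.frame(mol, atom) per union atom (NA for created atoms),
#      rhs_target = target union atom per rhs pattern/atom,
#      touched = logical per union atom)
apply_transform <- function(transform, mols, max_applications = Inf) {
  lhs <- transform$lhs; rhs <- transform$rhs
  if (length(mols) != length(lhs)) return(list())

  perms <- all_permutations(length(mols))
  out <- list()
  seen_edit_keys <- character(0)

  for (perm in perms) {
    match_sets <- vector("list", length(lhs))
    ok <- TRUE
    for (p in seq_along(lhs)) {
      m <- match_pattern(lhs[[p]], mols[[perm[[p]]]]$graph)
      if (!length(m)) { ok <- FALSE; break }
      match_sets[[p]] <- m
    }
    if (!ok) next
    for (combo in cartesian_index(lengths(match_sets))) {
      app <- apply_one(transform, mols, perm,
                       lapply(seq_along(lhs), function(p) match_sets[[p]][[combo[[p]]]]))
      if (is.null(app)) next
      # collapse symmetry-equivalent matches hitting the same atoms/edits
      key <- app$edit_key
      if (key %in% seen_edit_keys) next
      seen_edit_keys <- c(seen_edit_keys, key)
      out[[length(out) + 1L]] <- app
      if (length(out) >= max_applications) return(out)
    }
  }
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in sub) out[[length(out) + 1L]] <- c(i, rest[s])
  }
  out
}

cartesian_index <- function(lens) {
  if (!length(lens) || any(lens == 0L)) return(list())
  grid <- do.call(expand.grid, rev(lapply(lens, seq_len)))
  grid <- grid[, rev(seq_along(lens)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) as.integer(unlist(grid[r, ])))
}

apply_one <- function(transform, mols, perm, matches) {
  lhs <- transform$lhs; rhs <- transform$rhs

  # union graph: molecule perm[p] (the one matched by lhs pattern p) occupies
  # union indices offs[p]+1 .. offs[p]+n_p
  offs <- integer(length(lhs))
  atoms <- NULL; bonds <- NULL
  for (p in seq_along(lhs)) {
    g <- mols[[perm[[p]]]]$graph
    offs[[p]] <- if (is.null(atoms)) 0L else nrow(atoms)
    a <- g$atoms; a$map <- NA_integer_
    atoms <- rbind(atoms, a)
    if (nrow(g$bonds)) {
      b <- g$bonds; b$a1 <- b$a1 + offs[[p]]; b$a2 <- b$a2 + offs[[p]]
      bonds <- rbind(bonds, b)
    }
  }
  if (is.null(bonds)) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        arom = logical(0), ring = logical(0))
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  U <- list(atoms = atoms, bonds = bonds, n = nrow(atoms))
  prov <- data.frame(
    mol = unlist(lapply(seq_along(mols), function(p) rep(perm[[p]], mols[[perm[[p]]]]$graph$n))),
    atom = unlist(lapply(seq_along(mols), function(p) seq_len(mols[[perm[[p]]]]$graph$n)))
  )

  touched <- logical(U$n)

  # lhs pattern atom -> union atom
  l_target <- vector("list", length(lhs))
  for (p in seq_along(lhs)) l_target[[p]] <- matches[[p]] + offs[[p]]

  # map label -> union atom (lhs side)
  lhs_label_atom <- list()
  for (p in seq_along(lhs)) {
    mp <- lhs[[p]]$atoms$map
    for (a in seq_along(mp)) {
      if (!is.na(mp[[a]])) lhs_label_atom[[as.character(mp[[a]])]] <- l_target[[p]][[a]]
    }
  }

  del_bond <- function(i, j) {
    k <- which((U$bonds$a1 == i & U$bonds$a2 == j) | (U$bonds$a1 == j & U$bonds$a2 == i))
    if (length(k)) U$bonds <<- U$bonds[-k[[1]], , drop = FALSE]
    touched[[i]] <<- TRUE; touched[[j]] <<- TRUE
  }
  add_bond <- function(i, j, order, arom) {
    U$bonds <<- rbind(U$bonds, data.frame(a1 = i, a2 = j, order = order,
                                          arom = arom, ring = FALSE))
    touched[[i]] <<- TRUE; touched[[j]] <<- TRUE
  }

  # 1. detach unmapped lhs atoms from mapped neighbours (pattern bonds only)
  for (p in seq_along(lhs)) {
    pb <- lhs[[p]]$bonds
    mp <- lhs[[p]]$atoms$map
    for (k in seq_len(nrow(pb))) {
      a1 <- pb$a1[[k]]; a2 <- pb$a2[[k]]
      if (is.na(mp[[a1]]) != is.na(mp[[a2]])) {
        del_bond(l_target[[p]][[a1]], l_target[[p]][[a2]])
      }
    }
  }

  # 2. mapped-bond edits driven by the rhs
  rhs_bond_spec <- function(p, k) {
    sym <- rhs[[p]]$bonds$sym[[k]]
    if (is.na(sym)) {
      both_arom <- isTRUE(rhs[[p]]$atoms$arom[[rhs[[p]]$bonds$a1[[k]]]]) &&
        isTRUE(rhs[[p]]$atoms$arom[[rhs[[p]]$bonds$a2[[k]]]])
      sym <- if (both_arom) ":" else "-"
    }
    switch(sym,
           "-" = list(order = 1L, arom = FALSE),
           "=" = list(order = 2L, arom = FALSE),
           "#" = list(order = 3L, arom = FALSE),
           ":" = list(order = 1L, arom = TRUE))
  }

  # collect lhs mapped-pair bonds
  lhs_pair_bonds <- list()
  for (p in seq_along(lhs)) {
    pb <- lhs[[p]]$bonds; mp <- lhs[[p]]$atoms$map
    for (k in seq_len(nrow(pb))) {
      m1 <- mp[[pb$a1[[k]]]]; m2 <- mp[[pb$a2[[k]]]]
      if (!is.na(m1) && !is.na(m2)) {
        lhs_pair_bonds[[pair_key(m1, m2)]] <- TRUE
      }
    }
  }
  rhs_pair_bonds <- list()
  for (p in seq_along(rhs)) {
    pb <- rhs[[p]]$bonds; mp <- rhs[[p]]$atoms$map
    for (k in seq_len(nrow(pb))) {
      m1 <- mp[[pb$a1[[k]]]]; m2 <- mp[[pb$a2[[k]]]]
      if (!is.na(m1) && !is.na(m2)) {
        rhs_pair_bonds[[pair_key(m1, m2)]] <- rhs_bond_spec(p, k)
      }
    }
  }
  for (key in names(lhs_pair_bonds)) {
    if (is.null(rhs_pair_bonds[[key]])) {
      lab <- strsplit(key, "_", fixed = TRUE)[[1]]
      del_bond(lhs_label_atom[[lab[[1]]]], lhs_label_atom[[lab[[2]]]])
    }
  }
  for (key in names(rhs_pair_bonds)) {
    lab <- strsplit(key, "_", fixed = TRUE)[[1]]
    i <- lhs_label_atom[[lab[[1]]]]; j <- lhs_label_atom[[lab[[2]]]]
    if (is.null(i) || is.null(j)) next  # label not on lhs: handled with new atoms
    spec <- rhs_pair_bonds[[key]]
    if (is.null(lhs_pair_bonds[[key]])) {
      add_bond(i, j, spec$order, spec$arom)
    } else {
      k <- which((U$bonds$a1 == i & U$bonds$a2 == j) | (U$bonds$a1 == j & U$bonds$a2 == i))
      if (length(k)) {
        cur <- U$bonds[k[[1]], ]
        if (cur$order != spec$order || cur$arom != spec$arom) {
          U$bonds$order[[k[[1]]]] <- spec$order
          U$bonds$arom[[k[[1]]]] <- spec$arom
          touched[[i]] <- TRUE; touched[[j]] <- TRUE
        }
      }
    }
  }

  # 3. create unmapped rhs atoms and their bonds
  rhs_target <- vector("list", length(rhs))
  for (p in seq_along(rhs)) {
    mp <- rhs[[p]]$atoms$map
    rhs_target[[p]] <- rep(NA_integer_, rhs[[p]]$n)
    for (a in seq_len(rhs[[p]]$n)) {
      if (!is.na(mp[[a]])) {
        rhs_target[[p]][[a]] <- lhs_label_atom[[as.character(mp[[a]])]]
      }
    }
  }
  for (p in seq_along(rhs)) {
    for (a in seq_len(rhs[[p]]$n)) {
      if (!is.na(rhs_target[[p]][[a]])) next
      elems <- rhs[[p]]$atoms$elems[[a]]
      U$atoms <- rbind(U$atoms, data.frame(
        elem = elems[[1]], arom = isTRUE(rhs[[p]]$atoms$arom[[a]]),
        charge = if (is.na(rhs[[p]]$atoms$charge[[a]])) 0L else rhs[[p]]$atoms$charge[[a]],
        h = 0L, map = NA_integer_, ring = FALSE, stringsAsFactors = FALSE))
      U$n <- U$n + 1L
      prov <- rbind(prov, data.frame(mol = NA_integer_, atom = NA_integer_))
      touched <- c(touched, TRUE)
      rhs_target[[p]][[a]] <- U$n
    }
  }
  for (p in seq_along(rhs)) {
    pb <- rhs[[p]]$bonds; mp <- rhs[[p]]$atoms$map
    for (k in seq_len(nrow(pb))) {
      a1 <- pb$a1[[k]]; a2 <- pb$a2[[k]]
      if (!is.na(mp[[a1]]) && !is.na(mp[[a2]])) next  # handled above
      spec <- rhs_bond_spec(p, k)
      add_bond(rhs_target[[p]][[a1]], rhs_target[[p]][[a2]], spec$order, spec$arom)
    }
  }

  # 4. refill hydrogens on touched atoms
  for (i in which(touched)) {
    U$atoms$h[[i]] <- implicit_h(U, i)
    if (U$atoms$h[[i]] < 0L) return(NULL)
  }

  comp <- graph_components(U)
  # collapse exactly-equivalent matches (same label -> atom assignment and
  # same touched set); distinct orientations of a symmetric pattern survive
  labs <- names(lhs_label_atom)
  assign_str <- paste(sprintf("%s=%d", labs[order(as.integer(labs))],
                              unlist(lhs_label_atom)[order(as.integer(labs))]),
                      collapse = ",")
  edit_key <- paste0(assign_str, "|", paste(which(touched), collapse = ","))

  list(union = U, comp = comp, prov = prov, rhs_target = rhs_target,
       touched = touched, edit_key = edit_key)
}

pair_key <- function(m1, m2) paste(sort(c(m1, m2)), collapse = "_")

graph_components <- function(g) {
  if (!nrow(g$bonds)) return(seq_len(g$n))
  ig <- igraph::make_graph(rbind(g$bonds$a1, g$bonds$a2), n = g$n, directed = FALSE)
  as.integer(igraph::components(ig)$membership)
}

# Induced subgraph on a sorted atom index set; returns list(graph, index_map)
# where index_map[new] = old union index.
graph_subset <- function(g, atom_idx) {
  atom_idx <- sort(atom_idx)
  lookup <- integer(g$n); lookup[atom_idx] <- seq_along(atom_idx)
  keep <- g$bonds$a1 %in% atom_idx & g$bonds$a2 %in% atom_idx
  b <- g$bonds[keep, , drop = FALSE]
  if (nrow(b)) { b$a1 <- lookup[b$a1]; b$a2 <- lookup[b$a2] }
  rownames(b) <- NULL
  a <- g$atoms[atom_idx, , drop = FALSE]
  rownames(a) <- NULL
  list(graph = list(atoms = a, bonds = b, n = length(atom_idx)),
       index_map = atom_idx)
}
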