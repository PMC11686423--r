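# Independent oracles used to freeze expected values. These deliberately use
# different algorithms (symbolic label refinement, exhaustive subgraph
# enumeration via igraph VF2, direct evaluation of the greedy recurrence)
# than the package implementation they check.

# --- circular-feature oracle: symbolic environment identifiers -------------
# Radius-0..r atom environments as strings, refined iteratively; the feature
# set semantics match ECFP (neighbour trees), the representation does not.
oracle_env_features <- function(mol, radius = 2L) {
  g <- mol$graph
  n <- g$n
  nbrs <- lapply(seq_len(n), function(i) {
    nb <- aascore:::graph_neighbors(g, i)
    if (!nrow(nb)) return(nb)
    nb
  })
  lab <- vapply(seq_len(n), function(i) {
    paste(g$atoms$elem[[i]], g$atoms$charge[[i]], nrow(nbrs[[i]]),
          g$atoms$h[[i]], g$atoms$ring[[i]], g$atoms$arom[[i]], sep = ",")
  }, character(1))
  feats <- unique(lab)
  for (r in seq_len(radius)) {
    lab <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      if (!nrow(nb)) return(paste0("r", r, "{", lab[[i]], "}"))
      parts <- sort(vapply(seq_len(nrow(nb)), function(k) {
        bc <- if (nb$arom[[k]]) "a" else as.character(nb$order[[k]])
        paste0("(", bc, "|", lab[[nb$nbr[[k]]]], ")")
      }, character(1)))
      paste0("r", r, "{", lab[[i]], ";", paste(parts, collapse = ""), "}")
    }, character(1))
    feats <- c(feats, unique(lab))
  }
  unique(feats)
}

oracle_tanimoto <- function(a, b, radius = 2L) {
  fa <- oracle_env_features(a, radius)
  fb <- oracle_env_features(b, radius)
  length(intersect(fa, fb)) / length(union(fa, fb))
}

# --- exhaustive MCS oracle (small molecules only) --------------------------
# Largest k such that some connected induced k-atom subgraph of `a` is
# induced-subgraph-isomorphic (element + bond-class + ring colors) to `b`.
oracle_mcs_size <- function(a, b) {
  ga <- a$graph; gb <- b$graph
  to_igraph <- function(g) {
    ig <- igraph::make_graph(rbind(g$bonds$a1, g$bonds$a2), n = g$n,
                             directed = FALSE)
    igraph::V(ig)$color <- as.integer(factor(g$atoms$elem,
                                             levels = c("B","C","N","O","F","P","S","Cl","Br","I")))
    ecol <- integer(nrow(g$bonds))
    for (k in seq_len(nrow(g$bonds))) {
      base <- if (g$bonds$arom[[k]]) 4L else g$bonds$order[[k]]
      ecol[[k]] <- base + if (g$bonds$ring[[k]]) 10L else 0L
    }
    igraph::E(ig)$color <- ecol
    ig
  }
  iga <- to_igraph(ga); igb <- to_igraph(gb)
  n <- ga$n
  for (k in seq(min(ga$n, gb$n), 1L)) {
    subsets <- utils::combn(n, k, simplify = FALSE)
    for (s in subsets) {
      sub <- igraph::induced_subgraph(iga, s)
      if (!igraph::is_connected(sub)) next
      if (igraph::subgraph_isomorphic(sub, igb, method = "vf2",
                                      vertex.color1 = igraph::V(igb)$color,
                                      vertex.color2 = igraph::V(sub)$color,
                                      edge.color1 = igraph::E(igb)$color,
                                      edge.color2 = igraph::E(sub)$color)) {
        return(k)
      }
    }
  }
  0L
}

# --- greedy MaxMin reference ------------------------------------------------
oracle_maxmin <- function(pool, k, seed) {
  n <- length(pool)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- 1 - tanimoto(pool[[i]], pool[[j]])
  }
  smi <- vapply(pool, function(m) m$smiles, character(1))
  set.seed(seed)
  picked <- sample.int(n, 1L)
  while (length(picked) < k) {
    rest <- setdiff(seq_len(n), picked)
    mind <- vapply(rest, function(i) min(d[i, picked]), numeric(1))
    best <- rest[mind == max(mind)]
    picked <- c(picked, best[order(smi[best])][[1L]])
  }
  smi[picked]
}

# --- heavy-atom element multiset of a step side ----------------------------
step_reactant_elements <- function(step) {
  sort(unlist(lapply(step$raw$graphs, function(g) g$atoms$elem)))
}
step_product_side_elements <- function(step) {
  stopifnot(!is.null(step$aug))
  sort(c(step$product$graph$atoms$elem,
         unlist(lapply(step$aug$byproducts, function(g) g$atoms$elem))))
}
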