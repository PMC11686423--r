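# Reaction-center identification: atom mapping, leaving-group completion,
# radius-limited center extraction and compilation into a substructure query
# used for candidate-reactant search.

#' Ensure a validated step carries atom maps
#'
#' Template-backend steps carry their maps from the transformation itself and
#' bypass the mapper. External steps keep maps parsed from mapped reaction
#' SMILES verbatim; if maps are missing, a pluggable mapper
#' (`function(step) -> list of per-reactant map vectors`) is consulted. Steps
#' for which fewer than half of the product atoms end up mapped are discarded
#' (`NULL` return) with a logged reason.
#'
#' @param step round-trip-validated `aa_step`.
#' @param mapper optional atom-map backend; `NULL` means template/parsed maps
#'   only.
#' @return the mapped step, or `NULL` if mapping failed.
#' @export
map_reaction <- function(step, mapper = NULL) {
  have <- unlist(step$raw$maps)
  mapped_product_atoms <- length(unique(have[!is.na(have)]))
  if (mapped_product_atoms == 0L && !is.null(mapper)) {
    maps <- tryCatch(mapper(step), error = function(e) NULL)
    if (!is.null(maps)) {
      step$raw$maps <- maps
      have <- unlist(maps)
      mapped_product_atoms <- length(unique(have[!is.na(have)]))
    }
  }
  if (mapped_product_atoms < 0.5 * step$product$graph$n) {
    aa_log("INFO", "discarding step %s: only %d/%d product atoms mapped",
           step$template_name, mapped_product_atoms, step$product$graph$n)
    return(NULL)
  }
  step
}

#' Complete the atom map with leaving groups
#'
#' Reactant atoms with no product correspondence (e.g. the hydroxyl oxygen
#' lost as water in an amide coupling, or the halide of an alkylation) are
#' grouped into connected leaving fragments. Each fragment is appended to the
#' product side as a by-product and a second mapping pass labels it, so that
#' afterwards every reactant heavy atom is mapped to a product-side atom.
#' Steps with a complete first-pass map are returned unchanged.
#'
#' @param step mapped `aa_step`.
#' @return the step with an `aug` element: `byproducts` (list of graphs) and
#'   `maps` (completed per-reactant maps into the augmented product side,
#'   whose atoms are numbered product atoms first, by-product atoms after).
#' @export
complete_leaving_groups <- function(step) {
  np <- step$product$graph$n
  aug_maps <- step$raw$maps
  byproducts <- list()
  next_idx <- np

  for (r in seq_along(step$raw$graphs)) {
    g <- step$raw$graphs[[r]]
    mp <- aug_maps[[r]]
    loose <- which(is.na(mp))
    if (!length(loose)) next
    # connected fragments among the unmapped atoms of this reactant
    sub <- graph_subset(g, loose)
    comp <- graph_components(sub$graph)
    for (cid in sort(unique(comp))) {
      frag_local <- which(comp == cid)
      frag <- graph_subset(sub$graph, frag_local)
      byproducts[[length(byproducts) + 1L]] <- frag$graph
      # second pass: label the fragment atoms with augmented product indices
      orig <- sub$index_map[frag_local[order(frag_local)]]
      for (k in seq_along(frag$index_map)) {
        atom_in_reactant <- sub$index_map[[frag$index_map[[k]]]]
        mp[[atom_in_reactant]] <- next_idx + k
      }
      next_idx <- next_idx + frag$graph$n
    }
    aug_maps[[r]] <- mp
  }
  step$aug <- list(byproducts = byproducts, maps = aug_maps, n_product = np)
  step
}

# Augmented product-side neighbour view: for augmented index i, the set of
# (neighbour augmented index, bond code). Product atoms keep the product
# graph's bonds; by-product fragments keep their internal bonds.
aug_neighbors <- function(step, i) {
  np <- step$aug$n_product
  if (i <= np) {
    nb <- graph_neighbors(step$product$graph, i)
    if (!nrow(nb)) return(character(0))
    vapply(seq_len(nrow(nb)), function(k) {
      paste0(nb$nbr[[k]], "/", if (nb$arom[[k]]) "a" else nb$order[[k]])
    }, character(1))
  } else {
    off <- np
    for (bp in step$aug$byproducts) {
      if (i <= off + bp$n) {
        local <- i - off
        nb <- graph_neighbors(bp, local)
        if (!nrow(nb)) return(character(0))
        return(vapply(seq_len(nrow(nb)), function(k) {
          paste0(nb$nbr[[k]] + off, "/", if (nb$arom[[k]]) "a" else nb$order[[k]])
        }, character(1)))
      }
      off <- off + bp$n
    }
    character(0)
  }
}

#' Extract the reaction center of one reactant
#'
#' Core atoms are the atoms of the chosen reactant whose bond set (mapped
#' neighbour identity or bond order) differs between the reactant and the
#' augmented product side; the extended center adds every atom within graph
#' distance `radius` of a core atom. The extended center is compiled into a
#' substructure query (element, aromaticity and formal charge on atoms; bond
#' order and ring membership on bonds at the default strictness).
#'
#' @param step mapped, leaving-group-completed `aa_step`.
#' @param reactant_idx which reactant carries the center.
#' @param radius environment radius (default 2).
#' @param strictness `"loose"` (element only), `"default"` (element +
#'   aromaticity + charge) or `"strict"` (adds total-connectivity constraints).
#' @return an `aa_center`: `owner`, `core_atoms`, `extended_atoms`, `query`
#'   (pattern object) and `smarts` (serialized query).
#' @export
extract_center <- function(step, reactant_idx, radius = 2L,
                           strictness = c("default", "loose", "strict")) {
  strictness <- match.arg(strictness)
  if (is.null(step$aug)) step <- complete_leaving_groups(step)
  if (radius < 0L) stop_argument("radius must be >= 0")
  g <- step$raw$graphs[[reactant_idx]]
  mp <- step$aug$maps[[reactant_idx]]

  core <- integer(0)
  for (a in seq_len(g$n)) {
    p <- mp[[a]]
    if (is.na(p)) { core <- c(core, a); next }  # unmapped even after completion
    nb <- graph_neighbors(g, a)
    r_set <- if (nrow(nb)) sort(vapply(seq_len(nrow(nb)), function(k) {
      paste0(mp[[nb$nbr[[k]]]], "/", if (nb$arom[[k]]) "a" else nb$order[[k]])
    }, character(1))) else character(0)
    p_set <- sort(aug_neighbors(step, p))
    if (!identical(r_set, p_set)) core <- c(core, a)
  }
  if (!length(core)) {
    stop(aa_error("aa_center_error",
                  sprintf("empty reaction center on a validated step (%s, reactant %d)",
                          step$template_name, reactant_idx)))
  }

  extended <- core
  frontier <- core
  for (d in seq_len(radius)) {
    if (!length(frontier)) break
    nxt <- unique(unlist(lapply(frontier, function(a) graph_neighbors(g, a)$nbr)))
    frontier <- setdiff(nxt, extended)
    extended <- union(extended, frontier)
  }
  extended <- sort(extended)

  query <- center_query(g, extended, strictness)
  structure(list(owner = reactant_idx, core_atoms = sort(core),
                 extended_atoms = extended, radius = radius,
                 strictness = strictness,
                 query = query$pattern, smarts = query$smarts),
            class = "aa_center")
}

# Compile the induced subgraph on `atom_idx` into a pattern object plus a
# SMARTS string for reports.
center_query <- function(g, atom_idx, strictness) {
  sub <- graph_subset(g, atom_idx)$graph
  n <- sub$n
  elems <- as.list(sub$atoms$elem)
  arom <- sub$atoms$arom
  charge <- sub$atoms$charge
  xcount <- rep(NA_integer_, n)
  if (strictness == "loose") {
    arom <- rep(NA, n)
    charge <- rep(NA_integer_, n)
  }
  if (strictness == "strict") {
    xcount <- vapply(seq_len(n), function(i) {
      as.integer(sum(sub$bonds$a1 == i | sub$bonds$a2 == i) + sub$atoms$h[[i]])
    }, integer(1))
  }
  sym <- character(nrow(sub$bonds)); ring <- rep(NA, nrow(sub$bonds))
  for (k in seq_len(nrow(sub$bonds))) {
    sym[[k]] <- if (sub$bonds$arom[[k]]) ":" else
      c("-", "=", "#")[[sub$bonds$order[[k]]]]
    ring[[k]] <- if (strictness == "loose") NA else sub$bonds$ring[[k]]
  }
  pattern <- list(
    atoms = list(elems = elems, arom = as.logical(arom), charge = charge,
                 hmin = rep(NA_integer_, n), hexact = rep(NA_integer_, n),
                 xcount = xcount, map = rep(NA_integer_, n)),
    bonds = data.frame(a1 = sub$bonds$a1, a2 = sub$bonds$a2, sym = sym,
                       ring = ring, stringsAsFactors = FALSE),
    n = n
  )
  list(pattern = pattern, smarts = pattern_to_smarts(pattern))
}

# Readable SMARTS-style serialization of a query pattern (reports only).
pattern_to_smarts <- function(pattern) {
  n <- pattern$n
  if (!n) return("")
  atom_str <- vapply(seq_len(n), function(i) {
    e <- pattern$atoms$elems[[i]][[1]]
    ar <- pattern$atoms$arom[[i]]
    sym <- if (isTRUE(ar)) tolower(e) else e
    parts <- sym
    chg <- pattern$atoms$charge[[i]]
    if (!is.na(chg)) {
      parts <- paste0(parts, ";", if (chg >= 0) "+" else "-", abs(chg))
    }
    xc <- pattern$atoms$xcount[[i]]
    if (!is.na(xc)) parts <- paste0(parts, ";X", xc)
    paste0("[", parts, "]")
  }, character(1))
  bond_str <- function(k) {
    s <- pattern$bonds$sym[[k]]
    r <- pattern$bonds$ring[[k]]
    paste0(s, if (isTRUE(r)) ";@" else if (isFALSE(r)) ";!@" else "")
  }
  # linear DFS serialization; back edges become numbered ring closures with
  # the digit emitted at both endpoints
  nb <- nrow(pattern$bonds)
  inc_bonds <- function(a) which(pattern$bonds$a1 == a | pattern$bonds$a2 == a)
  other_end <- function(k, a) if (pattern$bonds$a1[[k]] == a) pattern$bonds$a2[[k]] else pattern$bonds$a1[[k]]
  # pre-pass: spanning tree (recursive DFS); remaining edges are back edges
  tree <- logical(nb); seen <- logical(n)
  dfs0 <- function(a) {
    seen[[a]] <<- TRUE
    for (k in inc_bonds(a)) {
      o <- other_end(k, a)
      if (!seen[[o]]) { tree[[k]] <<- TRUE; dfs0(o) }
    }
  }
  dfs0(1L)
  back <- !tree
  ring_of <- rep(NA_integer_, nb)
  ring_of[back] <- seq_len(sum(back))
  ring_first <- rep(TRUE, nb)

  visited <- logical(n); out <- character(0)
  push <- function(x) out[[length(out) + 1L]] <<- x
  dfs <- function(a) {
    visited[[a]] <<- TRUE
    push(atom_str[[a]])
    for (k in inc_bonds(a)) {
      if (back[[k]]) {
        if (ring_first[[k]]) {
          ring_first[[k]] <<- FALSE
          push(paste0(bond_str(k), ring_of[[k]]))
        } else push(as.character(ring_of[[k]]))
      }
    }
    kids <- Filter(function(k) tree[[k]] && !visited[[other_end(k, a)]], inc_bonds(a))
    for (i in seq_along(kids)) {
      k <- kids[[i]]
      o <- other_end(k, a)
      if (visited[[o]]) next
      last <- i == length(kids)
      if (!last) push("(")
      push(bond_str(k))
      dfs(o)
      if (!last) push(")")
    }
  }
  dfs(1L)
  paste0(out, collapse = "")
}

#' Does a candidate contain the extended reaction center?
#'
#' @param candidate `aa_mol`.
#' @param center `aa_center` from [extract_center()].
#' @return logical: TRUE iff the candidate has at least one substructure match
#'   of the extended-center query.
#' @export
center_matches <- function(candidate, center) {
  pattern_matches(center$query, candidate$graph)
}

#' @export
print.aa_center <- function(x, ...) {
  cat(sprintf("<ReactionCenter reactant %d: core {%s}, radius %d, query %s>\n",
              x$owner, paste(x$core_atoms, collapse = ","), x$radius, x$smarts))
  invisible(x)
}
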