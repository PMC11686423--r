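# SMILES -> molecular graph. Covers the dialect Open Babel emits for canonical
# nonisomeric SMILES of organic molecules (organic-subset atoms, aromatic
# lowercase forms, bracket atoms with explicit H/charge, ring closures incl.
# %nn, branches) plus atom-map labels as used by mapped reaction SMILES.
# Stereo bond symbols are tolerated and ignored (the package is nonisomeric
# throughout).

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)
.atomic_mass <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06,
                  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904)

# Graph representation: list(atoms = data.frame(elem, arom, charge, h, map,
# ring), bonds = data.frame(a1, a2, order, arom, ring), n). `order` is 1/2/3
# with aromatic bonds flagged separately; h is the implicit+explicit hydrogen
# count on the heavy atom.

parse_smiles_graph <- function(smiles) {
  s <- trimws(smiles)
  if (!nzchar(s)) stop_parse(smiles, "empty SMILES")
  if (grepl(".", s, fixed = TRUE)) {
    stop_parse(smiles, "multi-component SMILES (dot-disconnected)")
  }

  elem <- character(0); arom <- logical(0); charge <- integer(0)
  hexp <- integer(0)  # NA = implicit (organic subset); >=0 explicit (bracket)
  amap <- integer(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_sym <- character(0)

  prev_stack <- integer(0)  # branch stack
  prev <- NA_integer_
  pending_bond <- NA_character_
  ring_open <- list()       # closure id -> list(atom, sym)

  add_atom <- function(e, ar, ch, h, mp) {
    elem[[length(elem) + 1L]] <<- e
    arom[[length(arom) + 1L]] <<- ar
    charge[[length(charge) + 1L]] <<- as.integer(ch)
    hexp[[length(hexp) + 1L]] <<- as.integer(h)
    amap[[length(amap) + 1L]] <<- as.integer(mp)
    idx <- length(elem)
    if (!is.na(prev)) {
      b_a1[[length(b_a1) + 1L]] <<- prev
      b_a2[[length(b_a2) + 1L]] <<- idx
      b_sym[[length(b_sym) + 1L]] <<- pending_bond
    }
    prev <<- idx
    pending_bond <<- NA_character_
    invisible(idx)
  }

  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("-", "=", "#", ":")) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      i <- i + 1L  # stereo bond, read as single
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(prev_stack)) stop_parse(smiles, "unbalanced parenthesis")
      prev <- prev_stack[[length(prev_stack)]]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        id <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", id)) stop_parse(smiles, "bad %nn ring closure")
        i <- i + 3L
      } else {
        id <- ch; i <- i + 1L
      }
      if (is.na(prev)) stop_parse(smiles, "ring closure before any atom")
      if (!is.null(ring_open[[id]])) {
        op <- ring_open[[id]]
        sym <- if (!is.na(pending_bond)) pending_bond else op$sym
        b_a1[[length(b_a1) + 1L]] <- op$atom
        b_a2[[length(b_a2) + 1L]] <- prev
        b_sym[[length(b_sym) + 1L]] <- sym
        ring_open[[id]] <- NULL
        pending_bond <- NA_character_
      } else {
        ring_open[[id]] <- list(atom = prev, sym = pending_bond)
        pending_bond <- NA_character_
      }
    } else if (ch == "[") {
      close <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (close < 0) stop_parse(smiles, "unclosed bracket atom")
      content <- substr(s, i + 1L, i + close - 2L)
      at <- parse_bracket_atom(content, smiles)
      add_atom(at$elem, at$arom, at$charge, at$h, at$map)
      i <- i + close
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, NA_integer_); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, 0L, NA_integer_, NA_integer_); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, 0L, NA_integer_, NA_integer_); i <- i + 1L
      } else {
        stop_parse(smiles, sprintf("unexpected character '%s'", ch))
      }
    }
  }
  if (length(ring_open)) stop_parse(smiles, "unclosed ring bond")
  if (!length(elem)) stop_parse(smiles, "no atoms")

  finalize_graph(elem, arom, charge, hexp, amap, b_a1, b_a2, b_sym)
}

# Bracket atom content, e.g. "NH3+", "O-", "nH", "CH3:2", "13CH4".
parse_bracket_atom <- function(content, smiles) {
  x <- sub("^[0-9]+", "", content)             # isotope labels ignored
  mp <- NA_integer_
  m <- regmatches(x, regexec(":([0-9]+)$", x))[[1]]
  if (length(m)) { mp <- as.integer(m[[2]]); x <- sub(":[0-9]+$", "", x) }
  chg <- 0L
  m <- regmatches(x, regexec("(\\+{1,3}|-{1,3})([0-9]?)$", x))[[1]]
  if (length(m)) {
    sign <- if (substr(m[[2]], 1, 1) == "+") 1L else -1L
    mag <- if (nzchar(m[[3]])) as.integer(m[[3]]) else nchar(m[[2]])
    chg <- sign * mag
    x <- sub("(\\+{1,3}|-{1,3})[0-9]?$", "", x)
  }
  h <- 0L
  m <- regmatches(x, regexec("H([0-9]*)$", x))[[1]]
  if (length(m) && nchar(x) > 1L) {  # lone "[H]" unsupported; heavy atoms only
    h <- if (nzchar(m[[2]])) as.integer(m[[2]]) else 1L
    x <- sub("H[0-9]*$", "", x)
  }
  if (!grepl("^[A-Za-z][a-z]?$", x)) stop_parse(smiles, "bad bracket atom")
  ar <- grepl("^[a-z]", x)
  elem <- if (ar) {
    paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  } else x
  list(elem = elem, arom = ar, charge = chg, h = h, map = mp)
}

finalize_graph <- function(elem, arom, charge, hexp, amap, b_a1, b_a2, b_sym) {
  n <- length(elem)
  nb <- length(b_a1)
  order <- integer(nb); b_arom <- logical(nb)
  for (k in seq_len(nb)) {
    sym <- b_sym[[k]]
    if (is.na(sym)) {
      if (arom[[b_a1[[k]]]] && arom[[b_a2[[k]]]]) {
        b_arom[[k]] <- TRUE; order[[k]] <- 1L
      } else order[[k]] <- 1L
    } else if (sym == "-") order[[k]] <- 1L
    else if (sym == "=") order[[k]] <- 2L
    else if (sym == "#") order[[k]] <- 3L
    else if (sym == ":") { b_arom[[k]] <- TRUE; order[[k]] <- 1L }
  }

  ring_bond <- ring_membership(n, b_a1, b_a2)
  # An "aromatic" bond outside any ring is a plain single bond between two
  # aromatic systems (e.g. the biphenyl linker).
  b_arom[!ring_bond] <- FALSE
  ring_atom <- logical(n)
  ring_atom[c(b_a1[ring_bond], b_a2[ring_bond])] <- TRUE

  g <- list(
    atoms = data.frame(elem = elem, arom = arom, charge = charge,
                       h = hexp, map = amap, ring = ring_atom,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b_a1, a2 = b_a2, order = order,
                       arom = b_arom, ring = ring_bond),
    n = n
  )
  g$atoms$h <- vapply(seq_len(n), function(i) {
    if (!is.na(hexp[[i]])) hexp[[i]] else implicit_h(g, i)
  }, integer(1))
  g
}

# Ring bonds are the non-bridge edges of the molecular graph.
ring_membership <- function(n, a1, a2) {
  if (!length(a1)) return(logical(0))
  g <- igraph::make_graph(rbind(a1, a2), n = n, directed = FALSE)
  br <- igraph::bridges(g)
  out <- rep(TRUE, length(a1))
  out[as.integer(br)] <- FALSE
  out
}

# Implicit hydrogen filling for organic-subset atoms written without brackets.
implicit_h <- function(g, i) {
  elem <- g$atoms$elem[[i]]
  val <- .default_valence[[elem]]
  if (is.null(val)) return(0L)
  chg <- g$atoms$charge[[i]]
  val <- if (elem == "C") val - abs(chg) else val + chg
  inc <- g$bonds$a1 == i | g$bonds$a2 == i
  used <- if (isTRUE(g$atoms$arom[[i]])) {
    # one ring double bond is implied for aromatic C/N/P/B; pyrrole-type N and
    # aromatic O/S contribute a lone pair instead and are written bracketed
    # when they carry H
    sum(inc) + if (elem %in% c("C", "N", "P", "B")) 1L else 0L
  } else {
    sum(g$bonds$order[inc])
  }
  max(0L, as.integer(val - used))
}

# Neighbor list: for atom i, data.frame(nbr, order, arom, ring, bond).
graph_neighbors <- function(g, i) {
  k1 <- which(g$bonds$a1 == i); k2 <- which(g$bonds$a2 == i)
  data.frame(
    nbr = c(g$bonds$a2[k1], g$bonds$a1[k2]),
    order = c(g$bonds$order[k1], g$bonds$order[k2]),
    arom = c(g$bonds$arom[k1], g$bonds$arom[k2]),
    ring = c(g$bonds$ring[k1], g$bonds$ring[k2]),
    bond = c(k1, k2)
  )
}

bond_between <- function(g, i, j) {
  k <- which((g$bonds$a1 == i & g$bonds$a2 == j) |
             (g$bonds$a1 == j & g$bonds$a2 == i))
  if (length(k)) k[[1]] else NA_integer_
}

# Bond comparison code: aromatic bonds are their own order class.
bond_code <- function(g, k) {
  if (g$bonds$arom[[k]]) "a" else as.character(g$bonds$order[[k]])
}

graph_mw <- function(g) {
  m <- .atomic_mass[g$atoms$elem]
  if (anyNA(m)) return(NA_real_)
  sum(m) + sum(g$atoms$h) * .atomic_mass[["H"]]
}
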