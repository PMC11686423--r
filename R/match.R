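# Substructure query patterns and a backtracking (VF2-style) monomorphism
# matcher. Patterns come from two sources: parsed transformation patterns
# (SMARTS subset, see parse_pattern) and extracted reaction-center queries.
#
# Pattern atom fields:
#   elems  : allowed element symbols (character vector)
#   arom   : TRUE / FALSE / NA (NA = either)
#   charge : exact formal charge or NA (transformation patterns default to 0)
#   hmin   : minimum hydrogen count or NA
#   hexact : exact hydrogen count or NA
#   xcount : exact total connectivity (heavy degree + H) or NA
#   map    : atom-map label or NA
# Pattern bond fields:
#   sym  : "-", "=", "#", ":" or NA (default: ":" between two aromatic-only
#          atoms, otherwise "-")
#   ring : TRUE / FALSE / NA ring-membership constraint

parse_pattern <- function(pat) {
  elems <- list(); arom <- logical(0); charge <- integer(0)
  hmin <- integer(0); hexact <- integer(0); xcount <- integer(0)
  amap <- integer(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_sym <- character(0); b_ring <- logical(0)

  prev_stack <- integer(0); prev <- NA_integer_
  pending_sym <- NA_character_; pending_ring <- NA
  ring_open <- list()

  add_atom <- function(at) {
    k <- length(elems) + 1L
    elems[[k]] <<- at$elems
    arom[[k]] <<- at$arom
    charge[[k]] <<- at$charge
    hmin[[k]] <<- at$hmin
    hexact[[k]] <<- at$hexact
    xcount[[k]] <<- at$xcount
    amap[[k]] <<- at$map
    if (!is.na(prev)) {
      b_a1[[length(b_a1) + 1L]] <<- prev
      b_a2[[length(b_a2) + 1L]] <<- k
      b_sym[[length(b_sym) + 1L]] <<- pending_sym
      b_ring[[length(b_ring) + 1L]] <<- pending_ring
    }
    prev <<- k
    pending_sym <<- NA_character_; pending_ring <<- NA
    invisible(k)
  }

  i <- 1L; n <- nchar(pat)
  while (i <= n) {
    ch <- substr(pat, i, i)
    if (ch %in% c("-", "=", "#", ":")) {
      pending_sym <- ch; i <- i + 1L
      if (substr(pat, i, i + 1L) == "!@") { pending_ring <- FALSE; i <- i + 2L }
      else if (substr(pat, i, i) == "@") { pending_ring <- TRUE; i <- i + 1L }
    } else if (ch == "@") {
      pending_ring <- TRUE; i <- i + 1L
    } else if (ch == "!" && substr(pat, i + 1L, i + 1L) == "@") {
      pending_ring <- FALSE; i <- i + 2L
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- prev_stack[[length(prev_stack)]]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      id <- ch; i <- i + 1L
      if (!is.null(ring_open[[id]])) {
        op <- ring_open[[id]]
        b_a1[[length(b_a1) + 1L]] <- op$atom
        b_a2[[length(b_a2) + 1L]] <- prev
        b_sym[[length(b_sym) + 1L]] <- if (!is.na(pending_sym)) pending_sym else op$sym
        b_ring[[length(b_ring) + 1L]] <- TRUE  # SMILES ring closure is a ring bond
        ring_open[[id]] <- NULL
      } else {
        ring_open[[id]] <- list(atom = prev, sym = pending_sym)
      }
      pending_sym <- NA_character_; pending_ring <- NA
    } else if (ch == "[") {
      close <- regexpr("]", substr(pat, i, n), fixed = TRUE)
      if (close < 0) stop_argument(sprintf("unclosed bracket in pattern '%s'", pat))
      add_atom(parse_pattern_bracket(substr(pat, i + 1L, i + close - 2L), pat))
      i <- i + close
    } else {
      two <- substr(pat, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(blank_pattern_atom(two, FALSE)); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(blank_pattern_atom(ch, FALSE)); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(blank_pattern_atom(toupper(ch), TRUE)); i <- i + 1L
      } else {
        stop_argument(sprintf("unexpected character '%s' in pattern '%s'", ch, pat))
      }
    }
  }

  list(
    atoms = list(elems = elems, arom = arom, charge = charge, hmin = hmin,
                 hexact = hexact, xcount = xcount, map = amap),
    bonds = data.frame(a1 = b_a1, a2 = b_a2, sym = b_sym, ring = b_ring,
                       stringsAsFactors = FALSE),
    n = length(arom)
  )
}

blank_pattern_atom <- function(elem, arom) {
  list(elems = elem, arom = arom, charge = 0L, hmin = NA_integer_,
       hexact = NA_integer_, xcount = NA_integer_, map = NA_integer_)
}

# Bracket grammar: [Elem(,Elem)* X<d>? H<d>? charge? :map?]; "H" without a
# digit means "at least one hydrogen" (package dialect).
parse_pattern_bracket <- function(content, pat) {
  x <- content
  mp <- NA_integer_
  m <- regmatches(x, regexec(":([0-9]+)$", x))[[1]]
  if (length(m)) { mp <- as.integer(m[[2]]); x <- sub(":[0-9]+$", "", x) }
  chg <- 0L
  m <- regmatches(x, regexec("(\\+|-)([0-9]?)$", x))[[1]]
  if (length(m)) {
    mag <- if (nzchar(m[[3]])) as.integer(m[[3]]) else 1L
    chg <- if (m[[2]] == "+") mag else -mag
    x <- sub("(\\+|-)[0-9]?$", "", x)
  }
  hmin <- NA_integer_; hexact <- NA_integer_
  m <- regmatches(x, regexec("H([0-9]*)$", x))[[1]]
  if (length(m) && nchar(x) > 1L) {
    if (nzchar(m[[2]])) hexact <- as.integer(m[[2]]) else hmin <- 1L
    x <- sub("H[0-9]*$", "", x)
  }
  xc <- NA_integer_
  m <- regmatches(x, regexec("X([0-9])$", x))[[1]]
  if (length(m)) { xc <- as.integer(m[[2]]); x <- sub("X[0-9]$", "", x) }
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  if (!length(parts) || !all(grepl("^[A-Za-z][a-z]?$", parts))) {
    stop_argument(sprintf("bad bracket atom '[%s]' in pattern '%s'", content, pat))
  }
  ar <- grepl("^[a-z]", parts[[1]])
  elems <- vapply(parts, function(p) {
    paste0(toupper(substr(p, 1, 1)), substr(p, 2, nchar(p)))
  }, character(1), USE.NAMES = FALSE)
  list(elems = elems, arom = ar, charge = chg, hmin = hmin, hexact = hexact,
       xcount = xc, map = mp)
}

pattern_atom_ok <- function(p, ai, g, ti) {
  a <- g$atoms
  if (!(a$elem[[ti]] %in% p$atoms$elems[[ai]])) return(FALSE)
  ar <- p$atoms$arom[[ai]]
  if (!is.na(ar) && a$arom[[ti]] != ar) return(FALSE)
  chg <- p$atoms$charge[[ai]]
  if (!is.na(chg) && a$charge[[ti]] != chg) return(FALSE)
  if (!is.na(p$atoms$hexact[[ai]]) && a$h[[ti]] != p$atoms$hexact[[ai]]) return(FALSE)
  if (!is.na(p$atoms$hmin[[ai]]) && a$h[[ti]] < p$atoms$hmin[[ai]]) return(FALSE)
  if (!is.na(p$atoms$xcount[[ai]])) {
    deg <- sum(g$bonds$a1 == ti | g$bonds$a2 == ti)
    if (deg + a$h[[ti]] != p$atoms$xcount[[ai]]) return(FALSE)
  }
  TRUE
}

pattern_bond_ok <- function(p, bk, g, tk) {
  sym <- p$bonds$sym[[bk]]
  if (is.na(sym)) {
    a1 <- p$bonds$a1[[bk]]; a2 <- p$bonds$a2[[bk]]
    both_arom <- isTRUE(p$atoms$arom[[a1]]) && isTRUE(p$atoms$arom[[a2]])
    sym <- if (both_arom) ":" else "-"
  }
  tb_arom <- g$bonds$arom[[tk]]
  tb_ord <- g$bonds$order[[tk]]
  ok <- switch(sym,
    "-" = !tb_arom && tb_ord == 1L,
    "=" = !tb_arom && tb_ord == 2L,
    "#" = !tb_arom && tb_ord == 3L,
    ":" = tb_arom)
  if (!ok) return(FALSE)
  rng <- p$bonds$ring[[bk]]
  if (!is.na(rng) && g$bonds$ring[[tk]] != rng) return(FALSE)
  TRUE
}

# All monomorphism matches of `pattern` in graph `g`. Returns a list of
# integer vectors (pattern atom -> target atom); with first_only = TRUE stops
# at the first match. Patterns must be connected.
match_pattern <- function(pattern, g, first_only = FALSE) {
  np <- pattern$n
  if (np == 0L) return(list())
  # match order: DFS over the pattern so each atom after the first is bonded
  # to an earlier one
  p_order <- integer(0); seen <- logical(np)
  anchor <- rep(NA_integer_, np)  # bond row to an earlier pattern atom
  stack <- 1L
  while (length(stack)) {
    a <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[[a]]) next
    seen[[a]] <- TRUE
    p_order <- c(p_order, a)
    inc <- which(pattern$bonds$a1 == a | pattern$bonds$a2 == a)
    for (k in inc) {
      other <- if (pattern$bonds$a1[[k]] == a) pattern$bonds$a2[[k]] else pattern$bonds$a1[[k]]
      if (!seen[[other]]) {
        if (is.na(anchor[[other]])) anchor[[other]] <- k
        stack <- c(stack, other)
      }
    }
  }
  if (length(p_order) != np) stop_argument("disconnected pattern")

  matches <- list()
  assign_vec <- rep(NA_integer_, np)
  used <- logical(g$n)

  try_atom <- function(pos) {
    if (pos > np) {
      matches[[length(matches) + 1L]] <<- assign_vec
      return(first_only)
    }
    a <- p_order[[pos]]
    cand <- if (pos == 1L) seq_len(g$n) else {
      bk <- anchor[[a]]
      prev_p <- if (pattern$bonds$a1[[bk]] == a) pattern$bonds$a2[[bk]] else pattern$bonds$a1[[bk]]
      graph_neighbors(g, assign_vec[[prev_p]])$nbr
    }
    for (t in cand) {
      if (used[[t]]) next
      if (!pattern_atom_ok(pattern, a, g, t)) next
      # check every pattern bond from a to already-assigned atoms
      inc <- which(pattern$bonds$a1 == a | pattern$bonds$a2 == a)
      ok <- TRUE
      for (k in inc) {
        other <- if (pattern$bonds$a1[[k]] == a) pattern$bonds$a2[[k]] else pattern$bonds$a1[[k]]
        to <- assign_vec[[other]]
        if (is.na(to)) next
        tk <- bond_between(g, t, to)
        if (is.na(tk) || !pattern_bond_ok(pattern, k, g, tk)) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[[a]] <<- t; used[[t]] <<- TRUE
      done <- try_atom(pos + 1L)
      assign_vec[[a]] <<- NA_integer_; used[[t]] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  try_atom(1L)
  matches
}

pattern_matches <- function(pattern, g) {
  length(match_pattern(pattern, g, first_only = TRUE)) > 0L
}
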