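# Reaction templates: named, prioritized pairs of retro / forward
# transformation patterns in a SMIRKS-style subset notation
# ("LHS>>RHS", fragments dot-separated, atom-map labels link the two sides).

parse_transform <- function(text) {
  sides <- strsplit(text, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop_argument(sprintf("transformation '%s' must contain one '>>'", text))
  lhs <- lapply(strsplit(sides[[1]], ".", fixed = TRUE)[[1]], parse_pattern)
  rhs <- lapply(strsplit(sides[[2]], ".", fixed = TRUE)[[1]], parse_pattern)
  maps_of <- function(pats) sort(unlist(lapply(pats, function(p) p$atoms$map[!is.na(p$atoms$map)])))
  ml <- maps_of(lhs); mr <- maps_of(rhs)
  if (anyDuplicated(ml) || anyDuplicated(mr)) {
    stop_argument(sprintf("duplicate atom-map label in '%s'", text))
  }
  if (!all(mr %in% ml)) stop_argument(sprintf("unbalanced atom maps in '%s'", text))
  list(lhs = lhs, rhs = rhs, text = text)
}

#' Read a reaction-template set from a TSV file
#'
#' The file has columns `name`, `priority`, `retro` and `forward`; `retro`
#' maps a product substructure onto two or more reactant fragments and
#' `forward` is the inverse transformation. Templates are returned ordered by
#' increasing priority rank (lower = tried first).
#'
#' @param path TSV file; defaults to the set shipped with the package (amide,
#'   sulfonamide, ester, urea, N-alkylation, Williamson ether, Suzuki biaryl).
#' @return list of template objects (class `aa_templates`).
#' @export
read_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("templates", "default_templates.tsv", package = "aascore")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "priority", "retro", "forward")
  if (!all(need %in% names(df))) {
    stop_argument(sprintf("template file must have columns %s", paste(need, collapse = ", ")))
  }
  df <- df[order(df$priority), , drop = FALSE]
  tpl <- lapply(seq_len(nrow(df)), function(r) {
    retro <- parse_transform(df$retro[[r]])
    if (length(retro$lhs) != 1L) {
      stop_argument(sprintf("retro pattern of '%s' must have a single product side", df$name[[r]]))
    }
    if (length(retro$rhs) < 2L) {
      stop_argument(sprintf("retro pattern of '%s' must yield >= 2 reactants", df$name[[r]]))
    }
    list(name = df$name[[r]], priority = df$priority[[r]],
         retro = retro, forward = parse_transform(df$forward[[r]]))
  })
  structure(tpl, class = "aa_templates")
}

default_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_templates()
    cache
  }
})

#' @export
print.aa_templates <- function(x, ...) {
  cat(sprintf("<%d reaction templates>\n", length(x)))
  for (t in x) cat(sprintf("  %-18s priority %3d  %s\n", t$name, t$priority, t$retro$text))
  invisible(x)
}
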