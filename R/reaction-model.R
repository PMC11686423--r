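# Single-step retrosynthesis proposals, forward prediction, round-trip
# validation and reactant-set curation.
#
# ReactionStep (class aa_step):
#   reactants     list of aa_mol (>= 2 for retro steps)
#   product       aa_mol (the input compound for retro steps)
#   raw           list(graphs = raw reactant graphs, maps = per-reactant
#                 integer vectors raw-atom -> product-side atom index, NA for
#                 atoms introduced by the disconnection)
#   aug           product-side augmentation (leaving fragments), see
#                 complete_leaving_groups()
#   template_name character ("external" for text backends)
#   rank          integer position in the proposal list

new_step <- function(reactants, product, raw, template_name, rank) {
  structure(list(reactants = reactants, product = product, raw = raw,
                 aug = NULL, template_name = template_name, rank = rank),
            class = "aa_step")
}

#' @export
print.aa_step <- function(x, ...) {
  cat(sprintf("<ReactionStep #%d %s: %s >> %s>\n", x$rank, x$template_name,
              paste(vapply(x$reactants, function(m) m$smiles, character(1)),
                    collapse = " . "),
              x$product$smiles))
  invisible(x)
}

step_reactant_key <- function(step) {
  paste(sort(vapply(step$reactants, function(m) m$smiles, character(1))),
        collapse = ".")
}

#' Propose single-step retrosynthetic disconnections
#'
#' Applies the backend to the input molecule and returns up to `n_max` ranked
#' candidate disconnections. For the template backend the rank follows
#' (template priority, match position); duplicate reactant multisets collapse
#' to their first occurrence. Backend failure on a molecule logs a warning and
#' yields an empty list (the compound then scores 0).
#'
#' @param input_mol `aa_mol` to disconnect.
#' @param backend retro-capable backend (see [template_backend()]).
#' @param n_max maximum number of proposals (default 30).
#' @return list of `aa_step` objects.
#' @export
propose_retro <- function(input_mol, backend = template_backend(), n_max = 30L) {
  if (n_max < 1L) stop_argument("n_max must be >= 1")
  steps <- tryCatch(
    if (is_template_backend(backend)) {
      propose_retro_template(input_mol, backend$templates)
    } else {
      propose_retro_text(input_mol, backend, n_max)
    },
    error = function(e) {
      aa_log("WARN", "retro backend failed on %s: %s", input_mol$smiles,
             conditionMessage(e))
      list()
    })
  # collapse duplicate reactant multisets, keep rank order, truncate
  seen <- character(0); out <- list()
  for (s in steps) {
    key <- step_reactant_key(s)
    if (key %in% seen) next
    seen <- c(seen, key)
    s$rank <- length(out) + 1L
    out[[length(out) + 1L]] <- s
    if (length(out) >= n_max) break
  }
  out
}

propose_retro_template <- function(input_mol, templates) {
  steps <- list()
  for (tpl in templates) {
    apps <- apply_transform(tpl$retro, list(input_mol))
    for (app in apps) {
      st <- step_from_retro_application(tpl, app, input_mol)
      if (!is.null(st)) steps[[length(steps) + 1L]] <- st
    }
  }
  for (i in seq_along(steps)) steps[[i]]$rank <- i
  steps
}

# Build a ReactionStep from one retro application. Each rhs fragment pattern
# of the template identifies one reactant component; the application is
# rejected unless the edited graph splits into exactly that many components
# (intramolecular disconnections would leave a single fragment).
step_from_retro_application <- function(tpl, app, input_mol) {
  rhs <- tpl$retro$rhs
  ncomp <- max(app$comp)
  if (ncomp != length(rhs)) return(NULL)
  # component of each rhs fragment = component of its first mapped atom
  comp_of_frag <- vapply(seq_along(rhs), function(p) {
    app$comp[[app$rhs_target[[p]][[1L]]]]
  }, integer(1))
  if (anyDuplicated(comp_of_frag)) return(NULL)

  np <- input_mol$graph$n
  reactants <- list(); graphs <- list(); maps <- list()
  for (p in seq_along(rhs)) {
    idx <- which(app$comp == comp_of_frag[[p]])
    sub <- graph_subset(app$union, idx)
    mol <- graph_to_canonical_mol(sub$graph)
    if (is.null(mol)) return(NULL)
    reactants[[p]] <- mol
    graphs[[p]] <- sub$graph
    maps[[p]] <- ifelse(sub$index_map <= np, sub$index_map, NA_integer_)
  }
  new_step(reactants, input_mol,
           list(graphs = graphs, maps = maps), tpl$name, 0L)
}

propose_retro_text <- function(input_mol, backend, n_max) {
  if (is.null(backend$retro_fn)) stop_config("backend has no retro function")
  raw <- backend$retro_fn(input_mol$smiles, n_max)
  steps <- list()
  for (i in seq_along(raw)) {
    st <- tryCatch(step_from_mapped_smiles(raw[[i]], input_mol, rank = i),
                   aa_parse_error = function(e) {
                     aa_log("DEBUG", "dropping unparseable proposal '%s'", raw[[i]])
                     NULL
                   })
    if (!is.null(st)) steps[[length(steps) + 1L]] <- st
  }
  steps
}

# External proposals arrive as dot-separated (optionally atom-mapped) reactant
# SMILES. Atom-map labels, when present, are matched against labels the
# caller assigns to the product via mapped input; for the desk-scale path the
# product side is the canonical input and labels refer to its atom order.
step_from_mapped_smiles <- function(reactants_smiles, input_mol, rank) {
  parts <- strsplit(reactants_smiles, ".", fixed = TRUE)[[1]]
  if (length(parts) < 1L) stop_parse(reactants_smiles, "empty proposal")
  graphs <- lapply(parts, parse_smiles_graph)
  mols <- lapply(graphs, function(g) {
    m <- graph_to_canonical_mol(g)
    if (is.null(m)) stop_parse(reactants_smiles)
    m
  })
  maps <- lapply(graphs, function(g) {
    mp <- g$atoms$map
    ifelse(!is.na(mp) & mp >= 1L & mp <= input_mol$graph$n, mp, NA_integer_)
  })
  new_step(mols, input_mol, list(graphs = graphs, maps = maps),
           "external", rank)
}

#' Predict the top-1 forward product of a reactant set
#'
#' The template backend tries templates in priority order and applies the
#' first transformation whose reactant patterns jointly match the given
#' molecules (each molecule consumed by exactly one pattern); only the top-1
#' product is returned. Reagents must not be passed; every molecule is
#' treated as a reactant. Returns `NULL` when no template applies or the
#' backend output does not parse.
#'
#' @param reactants list of `aa_mol` (or character SMILES vector).
#' @param backend forward-capable backend.
#' @return an `aa_mol`, or `NULL`.
#' @export
predict_forward <- function(reactants, backend = template_backend()) {
  if (is.character(reactants)) {
    reactants <- lapply(reactants, function(s) {
      tryCatch(canonicalize(s), aa_parse_error = function(e) NULL)
    })
    if (any(vapply(reactants, is.null, logical(1)))) return(NULL)
  }
  if (!length(reactants)) stop_argument("at least one reactant required")
  if (is_template_backend(backend)) {
    predict_forward_template(reactants, backend$templates)
  } else {
    if (is.null(backend$forward_fn)) stop_config("backend has no forward function")
    out <- backend$forward_fn(vapply(reactants, function(m) m$smiles, character(1)))
    if (is.null(out) || !length(out) || is.na(out[[1]]) || !nzchar(out[[1]])) return(NULL)
    tryCatch(canonicalize(out[[1]]), aa_parse_error = function(e) {
      aa_log("DEBUG", "forward backend returned unparseable '%s'", out[[1]])
      NULL
    })
  }
}

predict_forward_template <- function(reactants, templates) {
  for (tpl in templates) {
    apps <- apply_transform(tpl$forward, reactants, max_applications = 1L)
    if (!length(apps)) next
    app <- apps[[1L]]
    # the product is the component holding the rhs-mapped atoms
    prod_comp <- app$comp[[app$rhs_target[[1L]][[1L]]]]
    sub <- graph_subset(app$union, which(app$comp == prod_comp))
    mol <- graph_to_canonical_mol(sub$graph)
    if (!is.null(mol)) return(mol)
  }
  NULL
}

#' Round-trip validation of a retrosynthesis step
#'
#' A proposed disconnection is eligible only if forward prediction on its
#' reactants regenerates the input compound exactly (canonical nonisomeric
#' SMILES equality). Forward failure counts as `FALSE`.
#'
#' @param step an `aa_step` proposed for `input_mol`.
#' @param fwd forward-capable backend.
#' @param input_mol the input compound the step must regenerate.
#' @return logical.
#' @export
round_trip_validate <- function(step, fwd = template_backend(), input_mol = step$product) {
  prod <- predict_forward(step$reactants, fwd)
  !is.null(prod) && mol_equal(prod, input_mol)
}

#' Curate ranked retrosynthesis proposals
#'
#' Applies, in order: (1) drop steps with any unparseable reactant, (2) drop
#' steps with fewer than 2 reactants, (3) drop steps where a reactant equals
#' the product, (4) drop duplicate reactant multisets, (5) drop steps failing
#' round-trip validation; then returns the first `k_keep` survivors in rank
#' order. Per-rule drop counts are logged and attached as the `drops`
#' attribute so the curation funnel can be audited.
#'
#' @param steps ranked list of `aa_step`.
#' @param input_mol the input compound.
#' @param fwd forward backend used for round-trip validation.
#' @param k_keep number of steps to keep (default 7).
#' @param rules character vector enabling individual rules; any of
#'   `"parseable"`, `"multi_reactant"`, `"product_identity"`, `"dedup"`,
#'   `"round_trip"` may be dropped for auditing.
#' @return curated list of `aa_step` (possibly empty), `drops` attribute holds
#'   per-rule counts.
#' @export
curate_reactant_sets <- function(steps, input_mol, fwd = template_backend(),
                                 k_keep = 7L,
                                 rules = c("parseable", "multi_reactant",
                                           "product_identity", "dedup",
                                           "round_trip")) {
  if (k_keep < 1L) stop_argument("k_keep must be >= 1")
  drops <- c(parseable = 0L, multi_reactant = 0L, product_identity = 0L,
             dedup = 0L, round_trip = 0L)
  seen <- character(0)
  out <- list()
  for (s in steps) {
    if ("parseable" %in% rules &&
        any(vapply(s$reactants, is.null, logical(1)))) {
      drops[["parseable"]] <- drops[["parseable"]] + 1L; next
    }
    if ("multi_reactant" %in% rules && length(s$reactants) < 2L) {
      drops[["multi_reactant"]] <- drops[["multi_reactant"]] + 1L; next
    }
    if ("product_identity" %in% rules &&
        any(vapply(s$reactants, function(m) mol_equal(m, input_mol), logical(1)))) {
      drops[["product_identity"]] <- drops[["product_identity"]] + 1L; next
    }
    key <- step_reactant_key(s)
    if ("dedup" %in% rules && key %in% seen) {
      drops[["dedup"]] <- drops[["dedup"]] + 1L; next
    }
    seen <- c(seen, key)
    if ("round_trip" %in% rules && !round_trip_validate(s, fwd, input_mol)) {
      drops[["round_trip"]] <- drops[["round_trip"]] + 1L; next
    }
    out[[length(out) + 1L]] <- s
    if (length(out) >= k_keep) break
  }
  for (rule in names(drops)) {
    if (drops[[rule]] > 0L) aa_log("INFO", "curation dropped %d step(s) by rule '%s'",
                                   drops[[rule]], rule)
  }
  attr(out, "drops") <- drops
  out
}
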