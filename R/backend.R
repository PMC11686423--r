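# Backend interface. A backend pair supplies single-step retrosynthesis and
# forward product prediction. The shipped deterministic backend applies the
# reaction-template set; external models (e.g. chemical-language models) can
# be plugged in through the text contract:
#   retro(product_smiles, n)  -> character vector of dot-separated reactant
#                                SMILES (optionally atom-mapped), ranked
#   forward(reactant_smiles)  -> a single product SMILES (or NA / "")
#
# Steps originating from the template backend carry full atom maps by
# construction; text-backend steps carry maps only if the backend emits
# mapped SMILES.

#' Create the deterministic reaction-template backend
#'
#' @param templates an `aa_templates` set (default: the shipped set).
#' @return backend object usable for both retrosynthesis and forward
#'   prediction in [score_compound()].
#' @export
template_backend <- function(templates = default_templates()) {
  structure(list(type = "template", templates = templates),
            class = "aa_backend")
}

#' Wrap external text-contract functions as a backend
#'
#' @param retro function(product_smiles, n) returning ranked dot-separated
#'   reactant SMILES strings (atom-mapped SMILES supported and preserved).
#' @param forward function(character vector of reactant SMILES) returning the
#'   top-1 product SMILES or NA.
#' @return backend object (class `aa_backend`).
#' @export
text_backend <- function(retro = NULL, forward = NULL) {
  structure(list(type = "text", retro_fn = retro, forward_fn = forward),
            class = "aa_backend")
}

#' @export
print.aa_backend <- function(x, ...) {
  cat(sprintf("<aascore %s backend>\n", x$type))
  invisible(x)
}

is_template_backend <- function(b) inherits(b, "aa_backend") && b$type == "template"
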