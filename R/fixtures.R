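# Synthetic fixture generation: toy reactant databases and input compounds so
# the whole pipeline runs and is testable with zero downloads.

.fixture_subs <- c(F = "F", Cl = "Cl", Br = "Br", Me = "C", OMe = "OC",
                   CF3 = "C(F)(F)F", Et = "CC")

fixture_family_space <- function(family) {
  subs <- .fixture_subs
  expand1 <- function(templates) {
    out <- character(0)
    for (tp in templates) {
      for (s in subs) out <- c(out, sub("{X}", s, tp, fixed = TRUE))
    }
    out
  }
  expand2 <- function(templates) {
    out <- character(0)
    for (tp in templates) {
      for (s1 in subs) for (s2 in subs) {
        out <- c(out, sub("{Y}", s2, sub("{X}", s1, tp, fixed = TRUE), fixed = TRUE))
      }
    }
    out
  }
  anilines <- c(
    "Nc1ccccc1",
    expand1(c("Nc1ccc({X})cc1", "Nc1cccc({X})c1", "Nc1ccccc1{X}")),
    expand2(c("Nc1ccc({X})cc1{Y}", "Nc1cc({X})ccc1{Y}")))
  acids <- c(
    "CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O", "OC(=O)C1CC1", "OC(=O)c1ccccc1",
    expand1(c("OC(=O)c1ccc({X})cc1", "OC(=O)c1cccc({X})c1",
              "OC(=O)C{X}")))
  amines <- c(
    "CCN", "CCCN", "CC(C)N", "NC1CCCCC1", "NCC1CCCCC1", "C1CCNCC1",
    expand1(c("NC1CCC({X})CC1", "NCc1ccc({X})cc1", "NCC{X}")))
  decoys <- c(
    "CCCCCC", "Cc1ccccc1", "CCOCC", "CCO", "CCCO", "OC1CCCCC1",
    "c1ccccc1", "C1CCCCC1",
    expand1(c("Oc1ccc({X})cc1", "CCc1ccc({X})cc1")))
  switch(family,
    anilines = data.frame(smiles = anilines, role = "center_matching",
                          stringsAsFactors = FALSE),
    acids = data.frame(smiles = acids, role = "center_matching",
                       stringsAsFactors = FALSE),
    amines = data.frame(smiles = amines, role = "center_matching",
                        stringsAsFactors = FALSE),
    mixed = {
      parts <- rbind(
        data.frame(smiles = anilines, role = "center_matching", stringsAsFactors = FALSE),
        data.frame(smiles = acids, role = "center_matching", stringsAsFactors = FALSE),
        data.frame(smiles = amines, role = "center_matching", stringsAsFactors = FALSE),
        data.frame(smiles = decoys, role = "decoy", stringsAsFactors = FALSE))
      parts
    },
    stop_argument(sprintf("unknown fixture family '%s'", family)))
}

#' Generate a toy reactant database
#'
#' Enumerates substituted members of a reactant family (ring substituents from
#' F, Cl, Br, methyl, methoxy, CF3, ethyl at enumerated positions), draws `n`
#' of them with the seeded generator, and prepares a reactant database from
#' the draw. The manifest records each member's SMILES and intended role
#' (center-matching or decoy; the `mixed` family includes alcohols,
#' hydrocarbons and phenols that must fail amine-center matches). Identical
#' `(family, n, seed)` calls yield identical manifests.
#'
#' @param family `"anilines"`, `"acids"`, `"amines"` or `"mixed"`.
#' @param n number of database members (capped with a warning if it exceeds
#'   the enumerable space).
#' @param seed integer seed for the draw.
#' @param profile database curation profile (default `"custom"`, no size
#'   limit — fixtures are small by construction).
#' @return list with `db` (an `aa_reactant_db`) and `manifest` (data.frame
#'   id, smiles, role).
#' @export
generate_fixture_db <- function(family, n, seed = 42L, profile = "custom") {
  if (n < 1L) stop_argument("n must be >= 1")
  space <- fixture_family_space(family)
  # canonical dedup of the enumerated space, preserving order
  can <- vapply(space$smiles, function(s) canonical_smiles(s), character(1),
                USE.NAMES = FALSE)
  keep <- !duplicated(can)
  space <- data.frame(smiles = can[keep], role = space$role[keep],
                      stringsAsFactors = FALSE)
  if (n > nrow(space)) {
    aa_log("WARN", "fixture family '%s' has only %d members; n capped",
           family, nrow(space))
    n <- nrow(space)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  picked <- sample.int(nrow(space))[seq_len(n)]
  manifest <- data.frame(
    id = sprintf("FIX%04d", seq_len(n)),
    smiles = space$smiles[picked],
    role = space$role[picked],
    stringsAsFactors = FALSE)
  db <- prepare_db(paste(manifest$smiles, manifest$id), profile = profile,
                   source_name = sprintf("fixture:%s(n=%d,seed=%d)", family, n, seed))
  list(db = db, manifest = manifest)
}

#' Fixture input compounds
#'
#' A fixed panel of small drug-like inputs covering every shipped template
#' class (amide, sulfonamide, ester, urea, N-alkylation, ether, biaryl) plus
#' benzene, which admits no multi-reactant disconnection and must score 0.
#'
#' @return named character vector of SMILES.
#' @export
fixture_input_compounds <- function() {
  c(acetanilide = "CC(=O)Nc1ccccc1",
    p_acetotoluidide = "CC(=O)Nc1ccc(C)cc1",
    benzanilide = "O=C(Nc1ccccc1)c1ccccc1",
    n_cyclohexyl_acetamide = "CC(=O)NC1CCCCC1",
    methanesulfonanilide = "CS(=O)(=O)Nc1ccccc1",
    benzenesulfonanilide = "O=S(=O)(Nc1ccccc1)c1ccccc1",
    methyl_benzoate = "COC(=O)c1ccccc1",
    ethyl_p_toluate = "CCOC(=O)c1ccc(C)cc1",
    n_methyl_n_phenylurea = "CNC(=O)Nc1ccccc1",
    n_methylbenzylamine = "CNCc1ccccc1",
    benzyl_ethyl_ether = "CCOCc1ccccc1",
    p_methylbiphenyl = "Cc1ccc(-c2ccccc2)cc1",
    benzene = "c1ccccc1")
}
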