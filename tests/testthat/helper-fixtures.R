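# Shared fixtures built in code at test time.

mol <- function(s) canonicalize(s)

# a small panel of molecules exercising the SMILES dialect
panel_smiles <- c(
  "c1ccccc1", "Cc1ccccc1", "CC(=O)Nc1ccccc1", "Cc1ccc(N)cc1F",
  "[NH3+]c1ccccc1", "CC(=O)[O-]", "c1ccccc1-c1ccccc1", "OB(O)c1ccccc1",
  "c1cc[nH]c1", "O=S(=O)(Nc1ccccc1)c1ccccc1", "CCOC(=O)c1ccc(O)cc1",
  "C1CC2CCC1CC2", "c1ccc2ccccc2c1", "O=C(Nc1ccccc1)Nc1ccc(Cl)cc1",
  "CN(C)c1ccncc1", "FC(F)(F)c1cccc(CNC2CCCC2)c1", "N#Cc1ccccc1")

# toy aniline-side DB from the candidate-search contract example
toy_amine_db <- function() {
  prepare_db(c("Nc1ccc(C)cc1 T01", "Nc1cccc(Cl)c1 T02",
               "NC1CCCCC1 T03", "Oc1ccccc1 T04"),
             profile = "custom", source_name = "toy")
}

# aniline-rich DB where mono-substituted members clear the 0.4 threshold
aniline_db <- function(extra = character(0)) {
  prepare_db(c("Nc1ccc(C)cc1 A01", "Nc1ccc(F)cc1 A02", "Nc1ccc(Cl)cc1 A03",
               "Nc1cccc(C)c1 A04", "Nc1ccccc1F A05", "Nc1ccc(OC)cc1 A06",
               "NC1CCCCC1 A07", "Oc1ccc(C)cc1 A08", extra),
             profile = "custom", source_name = "aniline_fixture")
}

amide_step_for <- function(input_smiles) {
  m <- mol(input_smiles)
  steps <- propose_retro(m)
  steps[[which(vapply(steps, function(s) s$template_name, character(1)) ==
                 "amide_coupling")[1]]]
}

# mapped reactant SMILES of a step (text-backend contract with atom maps)
mapped_reactants_smiles <- function(step) {
  parts <- vapply(seq_along(step$raw$graphs), function(r) {
    g <- step$raw$graphs[[r]]
    g$atoms$map <- step$raw$maps[[r]]
    aascore:::write_smiles_graph(g, with_maps = TRUE)
  }, character(1))
  paste(parts, collapse = ".")
}
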