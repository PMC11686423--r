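# aascore

Analog accessibility scoring for small molecules: how many close analogs of a
compound can be made in **one** synthetic step from purchasable building
blocks?

Hit prioritization usually asks "is this compound synthesizable?", but
hit-to-lead work immediately needs the follow-up: "how quickly can I explore
its neighbourhood?". `aascore` answers the second question with a concrete,
auditable number — the **analog accessibility score**, the count of unique,
scaffold-preserving analogs reachable by single-step retrosynthesis, reactant
replacement and forward re-assembly — together with the full synthesis route
for every analog.

## The method

For an input compound *M* with heavy-atom count *H(M)*:

1. **Retrosynthesis.** Propose up to `n_retro = 30` single-step
   disconnections `M => R1 + R2 (+ ...)`; keep at most `k_keep = 7` curated
   reactant sets. A set survives only if forward prediction regenerates *M*
   exactly (round-trip validation on canonical nonisomeric SMILES).
2. **Reaction center.** In each surviving reaction, the smallest reactant
   (by heavy atoms) is the *replaced reactant*. Its reaction center — the
   atoms whose bonding changes, after leaving groups are appended to the
   product side so the atom map is complete — is extended to all neighbours
   within graph radius 2 and compiled to a substructure query.
3. **Candidate search.** A purchasable-compound database is filtered to
   entries *C* satisfying both `center ⊆ C` (substructure) and
   `T(C, replaced) ≥ 0.4` (Tanimoto on 2048-bit radius-2 circular
   fingerprints, ECFP4-equivalent).
4. **Forward prediction + filters.** Each candidate is swapped in and the
   product *A* rebuilt by forward prediction; *A* is kept if it parses, is
   neither *M* nor one of its own reactants, and shares the scaffold:
   `|MCS(M, A)| / H(M) ≥ 2/3` in heavy atoms (connected MCS).

The score is `|unique analogs|`. Benzene — no multi-reactant disconnection —
scores 0.

The shipped reaction model is a deterministic template backend (amide,
sulfonamide, ester, urea, N-alkylation, Williamson ether, Suzuki biaryl
couplings) with complete atom maps by construction; external
retrosynthesis/forward models plug in through a text backend contract
(`retro(smiles, n)`, `forward(reactants)`), with atom-mapped SMILES preserved
verbatim.

## Worked example

```r
library(aascore)

db <- prepare_db(c("Nc1ccc(C)cc1 A01", "Nc1ccc(F)cc1 A02", "Nc1ccc(Cl)cc1 A03",
                   "Nc1ccc(OC)cc1 A04", "NC1CCCCC1 A05", "Oc1ccc(C)cc1 A06"),
                 profile = "custom", source_name = "demo")
res <- score_compound("O=C(Nc1ccccc1)c1ccccc1", db)   # benzanilide
print(res)
```

```
<AAscore O=C(c1ccccc1)Nc1ccccc1: 3>
  funnel: retro_proposals=1 curated_steps=1 candidates=3 raw_products=3 curated_products=3 eligible_analogs=3 unique_analogs=3
```

Benzanilide has one validated disconnection (benzoic acid + aniline); aniline
is the replaced reactant. Of the six database entries, the three
mono-substituted anilines carry the aromatic-amine center and reach Tanimoto
0.42 ≥ 0.4; 4-methoxyaniline stays below the threshold, and cyclohexylamine
and p-cresol fail the center match. All three products keep the full
benzanilide scaffold (MCS ratio 1.0), so the score is 3:

```r
res$analogs
#> [1] "Cc1ccc(cc1)NC(=O)c1ccccc1"  "Clc1ccc(cc1)NC(=O)c1ccccc1"
#> [3] "Fc1ccc(cc1)NC(=O)c1ccccc1"
```

Every analog comes with its route (`res$routes`): candidate, similarity,
unchanged reactants, product and MCS ratio, e.g.
`Cc1ccc(cc1)N + OC(=O)c1ccccc1 -> Cc1ccc(cc1)NC(=O)c1ccccc1 (sim 0.42, MCS 1.00)`.

## Command line

```sh
Rscript inst/cli/aascore score --smiles "CC(=O)Nc1ccccc1" --db building_blocks.smi --out report.json
Rscript inst/cli/aascore batch --input compounds.smi --db building_blocks.smi --csv summary.csv
Rscript inst/cli/aascore prepare-db --in raw.smi --profile zinc_style --out db.smi
Rscript inst/cli/aascore fixtures --family anilines --n 20 --out fixture.smi
Rscript inst/cli/aascore selftest
```

Reports are JSON with the config snapshot, per-stage funnel counts, database
provenance and reaction SMILES for every route; identical runs produce
byte-identical reports. Exit codes: 0 success, 2 input error, 3 partial
results.

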