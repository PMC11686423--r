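---
title: "Analog accessibility scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analog accessibility scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aascore)
```

## The score

A medicinal chemist judging a hit asks not only "can I make this?" but "how
many close analogs can I make quickly?". `aascore` operationalizes the second
question. For an input compound the pipeline

1. proposes single-step retrosynthetic disconnections (up to `n_retro`, default
   30) and keeps at most `k_keep` (default 7) curated reactant sets — a
   disconnection survives only if forward prediction on its reactants
   regenerates the input exactly (round-trip validation, by canonical
   nonisomeric SMILES equality);
2. for each surviving reaction, selects the smallest reactant by heavy-atom
   count (ties broken lexicographically) as the *replaced reactant*, extracts
   its reaction center — the atoms whose bonding changes — and extends it by
   every neighbour within graph radius `center_radius` (default 2);
3. searches a purchasable-compound database for *candidate reactants* that
   (i) contain the extended center as a substructure and (ii) have Tanimoto
   similarity at least `sim_threshold` (default 0.4) to the replaced reactant;
4. re-assembles a product for every candidate by forward prediction, drops
   products that fail to parse, equal the input, or equal one of their own
   reactants, and keeps products whose maximum-common-substructure (MCS)
   heavy-atom ratio against the input is at least `mcs_threshold`
   (default 2/3, with the input's heavy-atom count as the denominator).

The score is the number of **unique** analogs that survive; an analog reached
by several routes counts once, but all routes are retained in the report. A
compound with no multi-reactant disconnection (benzene is the canonical
example) scores 0 by construction.

## Reaction model

The shipped backend is a deterministic template engine. Seven templates cover
the bond classes most one-step medicinal-chemistry couplings disconnect:
amide (acid + amine), sulfonamide (sulfonyl chloride + amine), ester (acid +
aliphatic alcohol), urea (isocyanate + amine), N-alkylation (alkyl halide +
amine), Williamson ether (alkyl halide + aliphatic alcohol) and Suzuki-type
biaryl coupling (aryl halide + aryl boronic acid). Templates live in a TSV
file (`inst/templates/default_templates.tsv`) as paired retro/forward
transformation patterns in a SMIRKS-style subset: organic-subset and aromatic
atoms, bracket atoms with element alternation (`[Cl,Br,I]`), total-connectivity
(`X4`) and hydrogen-count constraints (`H2` exact; bare `H` means "at least
one", a deliberate dialect choice that keeps primary and secondary coupling
partners in one pattern), charges, atom maps, and ring/no-ring bond flags
(`-!@`). Unmapped left-side atoms are detached as leaving fragments; unmapped
right-side atoms are created; hydrogen counts of every touched atom are
refilled by standard valence rules.

Because the retro and forward patterns of one template are exact inverses,
template steps carry complete atom maps by construction and the desk-scale
path needs no external atom mapper. Leaving groups — reactant atoms with no
product correspondence, such as the hydroxyl oxygen lost as water in an amide
coupling — are grouped into connected fragments, appended to the product side
as by-products, and mapped in a second pass, after which every reactant heavy
atom is mapped (the test suite asserts element-wise heavy-atom conservation on
every fixture reaction).

External models plug in through a text contract: `retro(smiles, n)` returns
ranked dot-separated reactant SMILES (atom-mapped SMILES are parsed and
preserved verbatim), `forward(reactants)` returns one product SMILES. The
pipeline result is a pure function of the backend pair, the database and the
configuration; swapping a mock backend that reproduces the template backend's
text output yields identical scores, which the test suite also asserts.

Deliberate simplifications: only the top-1 forward product is considered per
candidate combination; single-reactant transformations (deprotections,
reductions) and multi-step routes are out of scope; reagents and conditions
are never modelled. A template can over-apply relative to real chemistry
(e.g. an amide N–H can act as the nucleophile pattern); round-trip validation
governs which disconnections enter scoring, so over-application costs
compute, not correctness of the count's definition.

## Chemical primitives

All molecules are reduced to canonical nonisomeric SMILES on ingest (Open
Babel canonicalization; stereo descriptors are stripped first). This is also
the identity used for database deduplication and unique-analog counting —
stereoisomers collapse deliberately, matching the resolution of the template
chemistry.

*Fingerprints.* Similarity uses binary circular fingerprints: radius-0..2
atom-environment identifiers (element, formal charge, heavy degree, hydrogen
count, ring membership, aromaticity; iterative neighbour hashing) folded to
2048 bits — the ECFP4-equivalent configuration. The same fingerprint serves
candidate qualification and MaxMin diversity picking; using one similarity
semantics everywhere is a deliberate choice, and radius/width are a single
config knob (`fp_params`). The tests pin the implementation against a
symbolic environment-enumeration oracle.

*MCS.* The scaffold filter uses the connected maximum common induced
substructure with atoms compared by element and bonds by order class
(aromatic bonds are their own class) plus ring membership. The search is
branch-and-bound with a wall-clock budget (`mcs_time_budget`, default 10 s
per pair); a timeout drops the analog conservatively and is logged. The ratio
denominator is always the input compound's heavy-atom count, so a large
analog containing the whole input scores ratio 1.

*Center queries.* At the default strictness a center query constrains element,
aromaticity and formal charge on atoms, and bond order plus ring membership
on bonds. This is the tightest contract that still lets ring-substituted
homologs of the replaced reactant match (the intended retrieval behaviour);
`center_strictness` can relax it to element-only or tighten it with
total-connectivity constraints. Queries are serialized as SMARTS-style
strings in reports for auditability.

## Database preparation

`prepare_db()` drops unparseable records, deduplicates on canonical
nonisomeric SMILES and applies a profile filter: `zinc_style` removes
molecules with more than 40 heavy atoms, `emolecules_style` removes molecular
weight above 250, `custom` takes explicit limits. Multi-component (salt)
records do not parse as single molecules and are dropped with a logged
reason. Per-stage counts are recorded as provenance and embedded in every
report. The replaced reactant itself is excluded from candidate hits — it
would regenerate the input, which is never an analog; its similarity of 1.0
would otherwise always qualify it.

## Failure modes

Candidate search can legitimately return nothing, and the reason is
diagnosed: the center pattern may be absent from the database, no entry may
reach the similarity threshold, or both. The pathological small-reactant case
— a one-heavy-atom replaced reactant (e.g. ammonia) whose extended center is
the whole molecule and whose fingerprint shares no environment with any
larger amine — surfaces as "no entry similar enough" with a
`center_covers_reactant` flag in the report. These diagnoses mirror the
situations in which desk inspection shows the method cannot propose analogs
for a route.

## Fixtures and what they do (and do not) show

`generate_fixture_db()` enumerates substituted anilines, benzoic/aliphatic
acids and aliphatic amines (substituents F, Cl, Br, methyl, methoxy, CF3,
ethyl at enumerated ring positions) plus decoys (phenols, hydrocarbons,
ethers, alcohols) and draws `n` members with a seeded generator, so the whole
pipeline runs and is testable offline. The fixtures emulate the *structure*
of a purchasable-reactant universe — families sharing a reaction center with
graded similarity to a query — at toy scale. They do not emulate its size,
its chemical diversity, or vendor-specific composition; passing tests
therefore demonstrate correctness of the pipeline's logic (oracle
equivalence, monotonicity, conservation laws, determinism), not retrieval
statistics transferable to multi-million-compound databases. Mono-substituted
ring homologs sit just above the 0.4 similarity threshold and disubstituted
ones just below it, which makes the threshold ladder informative at this
scale.

The test suite and the acceptance script use panels of about a dozen inputs
against databases of 15–60 entries; these sizes keep the exhaustive reference
enumerator (which re-scores every input by trying every template at every
site against every database entry) cheap enough to run on every check.

## Numerical and tie-breaking choices

- Proposal rank: (template priority, match position); duplicate reactant
  multisets collapse to the first occurrence. Curation preserves rank order
  and never reorders.
- Replaced-reactant ties (equal heavy-atom counts) break by lexicographic
  canonical SMILES; candidate ordering is similarity-descending with the same
  tie-break; MaxMin ties break the same way. Together with the absence of any
  unseeded randomness this makes identical runs byte-identical, which the
  test suite asserts at the report level.
- Hydrogen refilling after a bond edit uses standard valences with charge
  adjustment; atoms whose bonds are untouched keep their parsed hydrogen
  counts.
- Degenerate inputs: an empty post-filter database is a warning, not an
  error (every score is 0 with the funnel showing where records vanished);
  a backend failure on one compound yields an empty proposal list for that
  compound only.

## Known limitations

- The template set is a deliberately small, deterministic stand-in for a
  learned retrosynthesis model; coverage is the seven bond classes above.
  Compounds whose only disconnections fall outside them score 0.
- Stereochemistry is erased; enantioselective routes cannot be represented.
- Aromatic perception follows the canonicalizer; exotic tautomers are not
  normalized.
- The per-pair MCS budget makes extremely large or highly symmetric pairs
  fail conservative (analog dropped), biasing scores downward rather than
  upward.
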