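---
title: "Graph-based reaction-network exploration with ersnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based reaction-network exploration with ersnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ersnet)
```

## The model

`ersnet` works on the combinatorial skeleton of automated reaction
discovery. A molecule is a *molecular graph*: element symbols plus a
symmetric integer bond-order matrix. The central modeling commitment is the
**closed-shell valence condition**: every atom's total bond order must be a
member of its element's allowed-valence list (H 1; C 4; N 3; O 2; S 2/4/6;
P 3/5). Charged and radical species are unrepresentable by construction,
which matches the scope of neutral closed-shell exploration; sulfur and
phosphorus may settle at any of their allowed valences, so hypervalent
chemistry is reachable. Stereochemistry is ignored entirely: species
identity is the canonical key of the graph, so enantiomers and
diastereomers collapse to one network node. This is deliberate — the
exploration bookkeeping is graph-keyed, and distinguishing stereoisomers
would require 3-D information the package does not model.

An *elementary reaction step* (ERS) of class `bNfM` removes `N` bond-order
units and adds `M`. A unit is one step of integer bond order: breaking the
π bond of an alkene is one unit, so a concerted ring closure of the
open-chain aldohexose to its cyclic hemiacetal is a b2f2 event. Break
multisets may take both units of a double bond, and form multisets may add
two units between one atom pair — both are needed for carbonyl chemistry
(hemiacetal formation, ketene chemistry). Bond orders are capped at three.

## Enumeration and identity

`enumerate_candidates()` applies a step class exhaustively: every multiset
of `n_break` removable units times every valence-restoring multiset of
`n_form` formed units. Products are deduplicated by the canonical key of
the product species set; when several change sets reach the same product,
the representative with the fewest net changed units is retained, so each
candidate's `bNfM` label is its minimal step class. Output is sorted by
product key and fully deterministic.

Two identity notions coexist and the distinction matters for counting:

* a **no-op** change set (break X, re-form X) is not a reaction;
* a **degenerate exchange** (e.g. swapping hydroxyl hydrogens through a
  cyclic transfer) has a real, nonempty change set but regenerates a graph
  isomorphic to the reactant.

With `exclude_identity = TRUE` (the default) any candidate whose product
key equals the reactant key is dropped from the candidate list — ethane
yields exactly one candidate, ethene + H₂. The *enumeration-stage product
count* (`count_enumerated_products()`), however, counts every distinct
product graph the step class reaches, including the reactant regenerated by
degenerate channels; duplicate- and identity-filtering of reaction channels
belongs to the later characterization stage of the workflow. On open-chain
glucose these two conventions give 264 and 263 respectively.

For the constrained cyclic-b3f3 class, the packaged constraint requires the
minimal change set to form a single closed alternating cycle. This reading
is provisional (the class admits other formalizations) and counts derived
from it should be treated as indicative.

## Canonical keys

Species identity everywhere — deduplication, IRC-endpoint matching, network
nodes — is a canonical string key. Bond orders are encoded by subdividing
each bond with an auxiliary vertex colored by its order; canonical labeling
of the resulting element/order-colored graph (BLISS, via igraph) yields an
atom order under which the adjacency is serialized. Keys of isomorphic
graphs are identical by construction; distinctness for non-isomorphic
graphs is exercised in the test suite against an independent colored-VF2
isomorphism oracle over enumerated product pools. Multi-component graphs
(species sets) sort their component keys, so fragment order never matters.

## Thermochemistry surrogate

Heats of reaction are estimated by a bond-increment model:
ΔH = Σ E(broken units) − Σ E(formed units), with a packaged table of
standard mean bond energies per (element pair, order) unit in kJ/mol
(internally converted to kcal/mol; 1 kcal = 4.184 kJ). The table entry for
order *k* is the increment from order *k−1*, so breaking one unit of a
double bond uses the π-increment. This estimator sits behind the same
interface a component-increment or quantum thermochemistry backend would
use; it is coarse, and the packaged enthalpy filter counts are therefore
*internally* consistent rather than comparable to published
quantum-thermochemistry counts. The pre-pruning threshold is an
endothermicity cap (`delta_h <= threshold`): exothermic channels always
pass. The conventional default is 80 kJ/mol; the comparison direction is a
package choice, made because pre-pruning exists to drop strongly
endothermic channels.

## Characterization backends

All electronic-structure work is abstracted behind a backend contract:
`(candidate, conformer slot, level) → transition-state record`. Reaction
conformers are abstract attempt slots — the package does not model
geometries, only the bookkeeping over attempts.

The **surrogate backend** is deterministic and explicitly non-physical. Its
low-level barrier is `max(ΔH, 0) + 30 + J`, with `J` a hash-derived jitter
in [0, 20) kcal/mol per (candidate, conformer, seed); the high level adds a
hash offset in [−5, 5); gradient calls are hash-drawn integers in [4, 15].
The ΔH term (clamped at zero) makes endothermic channels slower, the floor
of 30 kcal/mol keeps all barriers physical, and the jitter width is wide
enough that conformer ranges and the 50 kcal/mol down-selection are both
exercised. `unintended_fraction` reroutes a deterministic subset of
candidates' IRC endpoints to a sibling channel of the same reactant, which
is the mechanism for testing unintended-channel mining and intended-rate
statistics; `fail_fraction` produces unconverged attempts. Identical seeds
give byte-identical record streams.

The **replay backend** serves records from a versioned JSON-lines archive,
matched by (reactant key, product key, conformer slot, level); unmatched
requested slots come back as failed placeholders with a warning, so partial
archives replay cleanly. An adapter invoking a real engine would implement
the same generic.

Outcome classification compares IRC endpoint keys with the candidate's
reactant/product keys as an *unordered* pair: a transition state traversed
in either orientation confirms the putative reaction. Conformer aggregation
reports the best (minimum) ΔG‡ and the max−min range over intended records
only. Merging of "identical" transition states across conformers is not
geometric here (there are no geometries); records are identified by their
endpoint keys, which is a proxy for the RMSD-based merging a geometric
pipeline would do.

## Network construction

`explore_network()` runs the funnel per round: enumerate → ΔH-filter →
low-level characterize → keep candidates whose best low-level ΔG‡ beats the
50 kcal/mol down-selection default → high-level characterize → classify →
mine unintended channels → expand the pool. Seeds are always explored;
non-seed products enter later rounds only with ≥ 3 heavy atoms (small
molecules like water are terminal nodes), under the optional
kinetic-relevance barrier cutoff, and rounds after the first are
unimolecular only — cross reactions between intermediates are neglected,
which keeps the recursion linear in the product count.

Nodes are single species; a fragmentation A → B + C is stored as **one
edge** from A to the largest fragment with the co-fragments annotated, so
the edge count equals the validated-reaction count. Pathway search expands
the annotation: the reaction also connects A to each co-product at the same
barrier. Traversing an edge backward uses the thermochemistry-consistent
reverse barrier ΔG‡ − ΔH. Duplicate (node pair, label) edges keep the
lower-barrier representative. Unexplored nodes carry machine-readable
exclusion reasons (`small_molecule`, `barrier_cap`, `max_depth`).

## Minimax pathways

The most kinetically favorable route between two species is the one whose
*largest* barrier is smallest. `minimax_pathway()` solves this in two
stages: a bottleneck variant of Dijkstra's algorithm (path cost = running
maximum of directed barriers) fixes the optimal bottleneck B\*, then a
breadth-first search over the subgraph of edges with barrier ≤ B\* returns
a fewest-edge witness, with deterministic lexicographic tie-breaking on
node keys. Correctness rests on the bottleneck cost being monotone under
path extension; the test suite checks both stages against exhaustive
simple-path enumeration on 50 random networks per run.
`kinetically_favorable_products()` ranks all reachable species by their
bottleneck from a source, the per-network analogue of a rate-limiting-step
coloring from the seed.

## Performance statistics

Over high-level records, with distinct products (by canonical key) as the
denominator: the success rate is the fraction of attempted products with at
least one converged record — a product whose only converged records are
unintended still counts as a success, since a transition state was
localized; the intended rate additionally requires an intended record and
is therefore bounded above by the success rate. Total gradient calls sum
over all high-level attempts, and GCPI divides that total by the number of
distinct intended products (undefined when none). The fixture-record
generator drives these estimators with known parameters: one uniform draw
per product decides convergence (`u < converged_prob`) and intent
(`u < intended_prob`), so intended products are a subset of converged ones
and both empirical rates are exact binomial samples of their parameters.

## What the synthetic layers do and do not show

The surrogate backend and fixture generator emulate the *shape* of a
characterization campaign: conformer multiplicity, convergence failures,
unintended rerouting, gradient-call accounting. They do not emulate real
potential-energy surfaces — barriers are hash noise around a thermochemical
floor, conformer couplings and barrier–structure correlations are absent,
and surrogate-derived network topologies, rates and GC totals are
exercises, not predictions. Passing tests demonstrate that the enumeration,
classification, mining, pathway and statistics machinery is correct and
deterministic; they say nothing about the accuracy of any electronic
structure method.

## Numerical and design choices

* Bond perception from coordinates uses covalent radii with scale 1.2
  (configurable); bond orders are then raised greedily, shortest eligible
  bond first, until every atom reaches an allowed valence. The scale is the
  standard heuristic choice; perception failures name the offending atoms.
* Problem sizes in the test suite are chosen for exhaustive verifiability:
  brute-force enumeration oracles run on molecules up to ethanol, pathway
  oracles on networks of ≤ 8 nodes, statistics recovery on 500-product
  streams — each the smallest scale at which the property is
  non-trivially exercised.
* All randomness is derived either from explicit seeds through R's RNG
  (restored after use) or from a platform-independent string hash, so every
  pipeline artifact is byte-reproducible.
* Energies are kcal/mol internally; kJ/mol is accepted at configuration
  boundaries, because thresholds are conventionally quoted in kJ/mol and
  barriers in kcal/mol.
* Ties everywhere (dedup representatives, main fragments, pathway choices)
  break lexicographically on canonical keys, for cross-platform
  determinism.

## Known limitations

Aromaticity, tautomer canonicalization, protonation states, conformers as
geometric objects, ions, radicals, excited states and transition metals are
out of scope. The SMILES dialect is a Kekulé subset (no aromatic lowercase,
charges, stereo descriptors). The bond-increment thermochemistry ignores
ring strain and resonance, so its ΔH values are order-of-magnitude guides.
The cyclic-b3f3 constraint is provisional. Bimolecular enumeration is
single-step (the recursive driver is unimolecular), matching the
no-external-reactant assumption of thermal degradation studies.
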