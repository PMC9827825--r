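# ersnet

Graph-based elementary-reaction-step enumeration and reaction-network
exploration in R.

`ersnet` is for computational chemists and kineticists who want to study the
*combinatorial* layer of automated reaction discovery — which products a
reactant can reach in one elementary step, how candidate reactions are
pruned and validated, and which multi-step routes are kinetically
favorable — without coupling every experiment to a quantum-chemistry engine.
The package reproduces the bookkeeping of modern automated
transition-state-search workflows at desk scale: the electronic-structure
stages are served by a pluggable backend (a deterministic surrogate, or a
replay of archived characterization records).

## The method

Molecules are **valence-valid molecular graphs**: atoms over C, H, N, O, S,
P plus a symmetric integer bond-order matrix, with every atom's total bond
order in its element's allowed-valence list (S and P are polyvalent). Only
neutral closed-shell species are representable — no charges or radicals.

On top of that sit five stages:

1. **Enumeration.** An elementary reaction step `bNfM` removes `N`
   bond-order units and adds `M`. `enumerate_candidates()` applies a step
   class (b2f2 by default) exhaustively, keeps valence-valid products, and
   deduplicates them by a canonical graph key (element- and
   bond-order-colored canonical labeling), so stereoisomers collapse and
   atom numbering never matters.
2. **Enthalpy pre-pruning.** A bond-increment estimate of the heat of
   reaction ΔHr° (sum of broken-unit energies minus formed-unit energies)
   discards strongly endothermic channels, conventionally at 80 kJ/mol.
3. **Characterization bookkeeping.** Each surviving candidate is attempted
   over `k` reaction-conformer slots at a low and a high level; each attempt
   yields a transition-state record (converged?, ΔG‡, gradient calls, IRC
   endpoint graphs). A converged record is **intended** when its IRC
   endpoints match the putative reactant/product pair (in either
   orientation), otherwise **unintended**.
4. **Mining and recursion.** Unintended records whose IRC endpoint matches a
   known reactant are mined as extra reaction channels. Validated reactions
   become network edges; products with at least three heavy atoms re-enter
   the reactant pool for the next exploration round.
5. **Analysis.** `minimax_pathway()` finds the route minimizing the maximum
   barrier (the bottleneck, i.e. the most kinetically favorable pathway);
   `compute_statistics()` reports the four standard efficiency numbers:
   success rate, intended rate, total gradient calls (GC), and gradient
   calls per intended product (GCPI).

## Worked example

Unimolecular degradation of γ-ketohydroperoxide (KHP, `O=CCCOO`), the
classic benchmark for automated reaction exploration:

```r
library(ersnet)

khp <- fixture_molecules("khp")
cands <- khp |> enumerate_candidates() |> estimate_reaction_enthalpy()
nrow(cands)                        # 37 distinct b2f2 candidates
nrow(filter_by_enthalpy(cands))    # 26 pass the 80 kJ/mol cap
dplyr::arrange(cands, delta_h)[1:3, c("product_smiles", "ers_label", "delta_h")]
#>   product_smiles ers_label delta_h
#> 1      O=CCC=O.O      b2f2  -69.55
#> 2   O=CC(C1)O1.O      b2f2  -62.62
#> 3   O=C(CC1)O1.O      b2f2  -62.62
```

The most exothermic channels are water loss to malonaldehyde and to the
epoxy/cyclic ether aldehydes. A full two-round exploration with the
deterministic surrogate backend:

```r
net <- explore_network(khp, explore_config(max_iterations = 2, seed = 1))
net
#> <reaction_network> 160 nodes, 426 edges (426 intended, 0 mined), 3924 records

glance(compute_statistics(net$records))
#>   n_products_attempted ... success_rate intended_rate total_gc  gcpi
#> 1                  203 ...            1             1    17309 85.27
```

The surrogate backend converges every attempt and follows the putative
reaction unless an `unintended_fraction` is configured, hence the rates of
1; the GC/GCPI numbers exercise the cost accounting. Bottleneck analysis
ranks products by the worst barrier on their best route from KHP:

```r
fav <- kinetically_favorable_products(net, canonical_key(khp))
head(fav)   # bottleneck ΔG‡ (kcal/mol) and step count per reachable species
```

Every quantity above is deterministic for a fixed seed; the `explore` CLI
subcommand (`inst/cli/ersnet.R`) writes the same network as GraphML, JSON,
edge-list CSV and a record archive, byte-identically across runs.

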