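---
title: "Computing exact molecular assembly indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing exact molecular assembly indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massembly)
```

## The quantity

The molecular assembly index MA of a molecule is the fewest joining
operations needed to construct its hydrogen-suppressed molecular graph from
single-bond building blocks, when any previously assembled fragment may be
reused at no additional cost. Building blocks (one-bond fragments over the
molecule's atom and bond alphabet) are free; each join glues two existing
fragments by identifying a shared set of atoms. A molecule with N bonds can
always be built naively in N - 1 joins, and a counting argument gives
ceiling(log2 N) as a lower bound, so

    ceiling(log2 N) <= MA <= N - 1

for a connected molecule. MA is of interest as a structure-aware complexity
measure: it responds to global reuse of substructure, which distinguishes it
from fingerprint- or subgraph-count-based complexity scores.

## Label conventions

`massembly` works on vertex/edge-labelled graphs. Atom labels are element
symbols only: formal charges are stored but ignored by default (an option
re-includes them), and stereochemistry, isotopes and tautomer state are out
of scope. Bond labels combine the unordered endpoint elements with a
bond-order category, and **aromatic bonds are their own category** rather
than being kekulised. The aromatic convention is the one under which all six
benzene ring bonds are mutually duplicatable; it is calibrated by the worked
benzoic-acid example (MA = 6), which a kekulised labelling cannot reproduce
in general because alternating single/double ring bonds split into two label
classes. `parse_smiles(..., kekulize = TRUE)` is available when the
alternating convention is wanted explicitly.

Edge indices follow input order and are stable: every fragment in the
package is a boolean edge mask over this fixed indexing, which is what makes
fragment arithmetic (removal, splitting, hashing) cheap and deterministic.

## The search

Computing MA by enumerating assembly pathways forwards is hopeless; the
engine instead searches backwards over *duplicatable subgraphs*, following
the standard top-down formulation:

1. **Preprocessing.** A bond whose label occurs once can never lie in two
   edge-disjoint isomorphic subgraphs, so all unique bonds are deleted from
   consideration in one linear pass.
2. **Duplicate enumeration (once).** All connected subgraphs with at least
   two occurrences are grown breadth-wise from 2-edge seeds, one adjacent
   edge at a time, grouped into isomorphism classes. Acyclic fragments are
   classified exactly by a rooted-at-centre canonical tree string; cyclic
   fragments are bucketed by an invariant key (label multiset, degree
   sequence, edge count, cycle rank) and resolved by explicit backtracking
   isomorphism inside the bucket. Classes are linked parent-to-child by
   one-edge growth (first parent only), forming a DAG that is built once and
   reused; occurrence growth is deduplicated by mask so the same subgraph is
   never re-generated along different growth orders.
3. **Fragmentation.** A removal step picks a class and an edge-disjoint pair
   of its occurrences, each lying inside a single fragment of the current
   state. The edges of *both* occurrences are deleted, the remnants are
   split into connected components with a union-find pass, and one copy of
   the duplicate becomes the state's new first fragment (it still has to be
   built, and its interior remains available for further duplication).
   Removing a k-edge duplicate saves k - 1 joins, accumulated in the
   duplicate sum S; for an input with N bonds in c edge-bearing components,
   `MA = N - c - max(S)`. Single-edge remnants are building blocks and are
   dropped from the stored state.

   The "delete both, keep one copy" bookkeeping deserves a note, because a
   natural-looking alternative -- deleting one occurrence and keeping both
   the copy and the intact partner live -- silently overcounts S: it admits
   pathways that re-harvest savings from material whose construction cost
   was already discounted (a uniform 7-bond chain would come out at MA 3,
   below the true minimal addition chain length 4, and benzoic acid at 5).
   The implemented semantics reproduces the addition-chain identity and the
   brute-force oracle everywhere we can afford to check (all 679,063
   connected labelled graphs with up to 7 edges over a 2-atom x 2-bond
   alphabet, plus seeded random trees).
4. **Ordering.** Duplicates are processed in decreasing size and sizes never
   increase along a pathway. This is lossless: a later, larger duplicate
   cannot lie inside the copy of an earlier, smaller one, so any optimal
   pathway can be exchanged into non-increasing size order. We deliberately
   do *not* impose a total order within one size class: an exchange argument
   fails there, because same-size removals can destroy each other's
   occurrence pairs, and a strict intra-size rule can forbid the only order
   that collects both savings. Permutation duplicates among equal-size
   removals are instead absorbed by the state table.
5. **Dynamic programming.** States (first fragment plus the sorted remaining
   fragments) are hashed; a state is re-expanded only when revisited with a
   strictly higher S. Collisions are harmless: full keys are compared, and
   superseded records are frozen rather than mutated so that the parent
   chain used for pathway reconstruction stays internally consistent.
6. **Branch-and-bound.** The size-monotonicity gives every state a cap m on
   all future duplicates, which bounds the residual S through a conditional
   addition-chain argument: for fragments of sizes L_i,

       S_residual <= max over x in 2..m of
                     [ -ceiling(log2 x) + sum_i (L_i - ceiling(L_i / x)) ]

   with the logarithmic term paid once across fragments. A state is pruned
   when S + bound <= best S found so far (strict improvement required: one
   optimal pathway suffices). The bound is applied both before expanding a
   state and again on each child's fragments right after splitting. Fragment
   sizes entering the bound count only bonds covered by some occurrence of a
   matchable class -- uncovered bonds can never participate in a duplicate,
   so the restriction keeps the bound admissible while tightening it.
   Admissibility is verified exhaustively in the test suite against a
   capped brute-force search on every reachable state of chains up to 12
   bonds and of the fixture molecules. An optional two-part refinement
   (bonds coverable at size m bounded at cap m, the rest at cap m - 1) is
   implemented behind `refined_split_bound()` but not enabled in the search:
   on our fixtures its extra tightness did not pay for its bookkeeping,
   matching its published assessment.
7. **Anytime behaviour.** Every state visited yields a valid upper bound
   N - c - S; improvements are recorded with wall-clock timestamps, so a
   budget-limited run (`timeout`, `max_states`) returns the best bound with
   `converged = FALSE` and a monotone trace rather than failing.

Pathway reconstruction follows stored parent pointers from the best state
back to the root; each step reports the duplicate, its partner occurrence,
and the remnant components. Replaying the steps through `apply_removal()`
reproduces the final state exactly, which the tests assert mechanically;
where several co-optimal pathways exist the deterministic child order makes
the reported one reproducible for a given input order.

## Joint assembly spaces and JAO

A set of molecules is handled as a single disconnected graph whose
components share one label alphabet. Occurrence pairs may then straddle
components, so shared scaffolds are built once; the joint index of two
identical molecules equals the index of one (the abstract object is
constructed once). The generalised formula `MA = N - c - S` with c
edge-bearing components makes exactly this identity hold, and an isolated
atom ("molecule" with no bonds) contributes nothing.

The Joint Assembly Overlap is

    JAO(A, B) = (MA_A + MA_B - MA_AB) / MA_AB,

a Jaccard-like score in [0, 1]: 1 for identical molecules, 0 when the pair
shares no construction. When a joint search is stopped by its budget, MA_AB
is an upper bound, so with exact individual indices the reported JAO is a
lower bound; `jao()` flags this with `exact = FALSE` rather than hiding it.
Degenerate inputs are handled explicitly: if both molecules are single
bonds, the joint index is 0 and JAO is defined as 1 exactly when the bonds
are identical (an error otherwise).

## Fixtures, oracle, and what the tests do and do not show

Everything runs offline from generated fixtures: labelled paths, cycles,
stars, seeded random trees (Pruefer construction), an exhaustive generator
of all connected labelled graphs up to 7 edges (grown one edge at a time
and deduplicated by interned canonical codes), peptides built N-to-C from
standard residue topologies with free neutral termini (the convention under
which the tripeptide reference values reproduce), and a small named-SMILES
dictionary (benzoic acid, benzene, the 20 amino acids).

The independent oracle is an exhaustive removal recursion with none of the
production heuristics -- no ordering rule, no bound, no state table, both
members of each pair tried as the kept copy -- correct purely by
completeness, and capped at 12 edges. Agreement between the optimised
search and this oracle on the exhaustive small-graph family and on random
trees, together with the addition-chain identity MA(chain of n) = l(n)
computed by an independent iterative-deepening chain search for n up to 20,
is the package's exactness evidence.

These fixtures probe topology and labelling, not chemistry: they say
nothing about charge or stereochemistry conventions (deliberately outside
the labels), about kekulised versus aromatic conventions beyond the
benzoic-acid calibration, or about runtime on molecules much beyond ~50
bonds, where the state space grows exponentially and only the anytime upper
bound is practical. Problem sizes used by the default suites -- 7-edge
exhaustive families, 10-edge trees, 12-bond chains for admissibility,
tripeptide pairs (38-40 bonds) for the joint searches -- were chosen as the
largest sizes at which the brute-force cross-checks themselves remain
trustworthy and quick on a single CPU.

## Numerical and design choices

* Edge masks are 128-bit fixed-width bitsets; inputs beyond 128 bonds are
  rejected rather than silently truncated.
* Negative bound values clamp to zero (S is a sum of non-negative k - 1
  terms).
* Tie-breaks are everywhere resolved by the fixed edge indexing: occurrence
  pairs are order-normalised, component splits are ordered by smallest
  contained edge index, fragments sort by mask order. Results are therefore
  byte-reproducible for a given input order, and MA itself is invariant
  under re-ordering (asserted by tests).
* The minimum duplicate size is 2 edges: a 1-edge duplicate saves k - 1 = 0
  joins and only inflates the state space.
* Non-matchable classes (at least two occurrences, none disjoint) are kept
  in the DAG -- growth through them can still reach matchable supergraph
  classes only when their own occurrence count stays at two or more, so
  growth is pruned below that.
* The 20-amino-acid joint space is used only to exercise the anytime
  contract (decreasing upper bound, honest `converged = FALSE` under a
  small state budget); its terminal value depends on the budget by nature
  and is asserted nowhere.

## Known limitations

Exactness in reasonable time is limited to single organic molecules of
roughly 50-75 bonds (more for disconnected joint inputs, which have fewer
duplicatable subgraphs per bond); beyond that the anytime bound is the
product. Graphs with very high vertex degree inflate the 2-edge seed set
quadratically. The SMILES reader covers the organic subset plus bracket
atoms; exotic valence models, polymers and reaction SMILES are out of
scope, and SDF ingestion (via ChemmineR) reads V2000 connection tables
only.
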