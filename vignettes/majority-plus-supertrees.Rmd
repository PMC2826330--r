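---
title: "Majority-rule (+) supertrees: model, exact solver, and data reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Majority-rule (+) supertrees: model, exact solver, and data reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(majplus)
```

## The problem

A supertree method combines a *profile* $P = (t_1, \dots, t_k)$ of
phylogenetic trees with partially overlapping leaf sets into a single tree
on the union leaf set $\mathcal{L}(P)$. The majority-rule (+) criterion
extends the familiar majority-rule consensus to this setting: each input
tree is *expanded* to the full leaf set by grafting the missing taxa onto
it, and the expansions are chosen so that the expanded trees lie as close
as possible, in total Robinson–Foulds (RF) distance, to their majority-rule
consensus. Formally, a *representative selection* $R = (T_1,\dots,T_k)$
picks for each $t_i$ a plenary tree $T_i$ displaying it; its score is
$s(R) = \sum_i d(\mathrm{Maj}(R), T_i)$. Each $\mathrm{Maj}(R)$ for an
optimal $R$ is an *optimal candidate supertree*, and the method's output,
$\mathrm{Maj}^+(P)$, is the strict consensus of all optimal candidate
supertrees. In the consensus case (equal leaf sets) the output has a
closed characterization: it displays exactly the plenary splits $X$ whose
*displaying* trees outnumber the trees *incompatible* with $X$; ties
exclude the split. (The rendered source we implemented from drops the
formal definitions of the two tree-count sets right after they are
introduced; we adopt the only reading consistent with the consensus
characterization and the scoring identities, namely displayers vs.
incompatibles, and use it uniformly.)

Computing an optimal candidate supertree is NP-hard — compatible quartet
profiles have optimum zero, so a polynomial solver would decide quartet
compatibility — which motivates an exact integer-programming formulation
rather than a polynomial algorithm.

## From spans to fill-ins

The span of an input tree (all plenary trees displaying it) is unwieldy
because refinements of polytomies cannot be bounded in advance. The model
therefore works with the *restricted span*: plenary trees each of whose
nontrivial splits extends a *distinct* nontrivial split of the input tree,
so the split count is preserved. A member of the restricted span is
exactly a *fill-in* of the MRP-style matrix representation $M(P)$: rows
are taxa, columns are input splits, entries are 1/0 for the two sides and
`?` where the taxon is absent from the column's tree (for rooted trees the
root side is 1, cluster members 0). Assigning every `?` a 0/1 value —
subject to the columns of each tree remaining pairwise compatible — yields
one plenary extension per input tree.

Every selection obtained this way has an *adjusted score*
$\tilde{s}(G)$: over the distinct plenary splits $X$ occurring in $G$,
majority splits (displayers $>$ incompatibles) contribute the number of
incompatible trees, minority splits contribute the number of displaying
trees. The adjusted score equals the RF distance from the majority-rule
(+) consensus of $G$ to the *completion* of $G$ (each tree augmented with
every compatible majority split); `adjusted_score()` computes both
quantities and refuses to return if they disagree. Minimizing
$\tilde{s}$ over the restricted span yields the optimal candidates, and
$\mathrm{Maj}^+(P)$ is the strict consensus of
$\{\mathrm{Maj}^+(G): G \text{ optimal}\}$.

## The integer linear program

`build_ilp()` emits, per matrix: fill-in variables $F_{xi}$ (fixed where
$M(P)$ is 0/1); pattern indicators $\Gamma^{ab}_{rpq}$ and $B^{ab}_{pq}$
for the four row patterns of a column pair; compatibility $C_{pq}$ via the
four-gametes condition (a pair is incompatible exactly when patterns 00,
01, 10, 11 all occur; rooted clusters carry an implicit root row, so only
00/01/10 are tested); equality indicators $E_{pq}$ (equal fills, or equal
up to complement in the unrooted case, via two auxiliary indicators);
duplicate markers $D_p$; per-tree occurrence and compatibility indicators
$S^{(1)}_{ij}, S^{(2)}_{ij}$; majority indicators $w_i \iff \sum_j
(S^{(1)}_{ij} + S^{(2)}_{ij}) > k$; and penalty units $z_{ij} \iff w_i
\wedge \neg S^{(2)}_{ij} \wedge \neg D_i$. The objective
$\min \sum_i (1 - w_i) + \sum_{ij} z_{ij}$ counts exactly the adjusted
score: one unit per column occurrence of a minority split, one unit per
incompatible tree per distinct majority split. Boolean definitions are
linearized the standard way ($x \iff a \wedge b$ as $x \le a$, $x \le b$,
$x \ge a + b - 1$, and De Morgan duals), and the majority threshold uses a
pair of big-M-free inequalities. Constant propagation is applied at
emission: fixed $F$ entries collapse their dependent pattern terms, so the
emitted model is typically far smaller than the nominal $O(nm^2)$ family
sizes recorded in `nominal_counts`.

Two design points deserve a note. First, the $z$ definition uses the
"first column representing the split" marker $\neg D_i$, which is what
makes $\sum z$ count each distinct majority split once per incompatible
tree; a per-occurrence variant would overcount duplicated splits. Second,
the printed linearizations in our source material were not recoverable
verbatim, so the constraints here are reconstructed from the logical
contracts above; the oracle-equivalence tests (below) would expose any
deviation that changed the feasible set or the optimum.

## Solving and verification

No mixed-integer solver library is available to this package, so it ships
its own exact solver for these binary programs (`src/bnb.cpp`): a
depth-first branch-and-bound over two-sided rows $lo \le a^\top x \le hi$
with incremental activity bounds, unit-style propagation (a variable whose
either value would violate a row is fixed immediately), and objective
lower-bound pruning. Branching is restricted to the fill-in variables in a
fixed order: once all $F$ are assigned, propagation determines every
dependent indicator, so the search explores at most $2^U$ nodes for $U$
question marks and in practice far fewer. The solver is deterministic;
`solve_ilp()` accepts a user-supplied backend function instead, and
`export_ilp()` writes LP/MPS files for external solvers.

After the optimum $G^\*$ with score $s^\*$ is found, each nontrivial split
$A|B$ of the candidate $T^\* = \mathrm{Maj}^+(G^\*)$ is *verified*: a
feasibility sub-ILP adds the score cap $\tilde{s} \le s^\*$, per-column
match indicators $\mu_i$ (the column's fill equals the fixed pattern of
$A|B$; equality or complement when unrooted), and the prohibition
$w_i + \mu_i \le 1$. If this is feasible, some optimal candidate avoids
$A|B$ and the split is excluded from the strict consensus; if infeasible,
it is retained. A sub-ILP that hits its time limit leaves the split
*undecided* and flags the result as partial — undecided splits are
reported separately, never silently included. The solved objective is
always cross-checked against the combinatorially recomputed adjusted
score of the decoded selection; a mismatch is raised as an internal error
rather than repaired.

## Data reduction

For profiles beyond the ILP's comfortable range, a *reducible set* $S$ —
a taxon set such that every input tree has a full split (trivial allowed)
with one side exactly $S \cap \mathcal{L}(t_j)$ — splits the problem in
two: the *reduced profile* contracts each tree's minimal subtree spanning
its share of $S$ to a supertaxon leaf, and the *satellite profile*
contracts everything outside $S$ to an attachment leaf. Contraction keeps
exactly the splits whose edge has the contracted leaves entirely on one
side. Satellite trees reduced to fewer than two member taxa carry no
information and are dropped (*compressed satellite*); degenerate
reduced-side trees (fewer than two leaves) are dropped symmetrically.
Solving the parts independently and splicing at the marker leaves gives
the $S$-restricted majority-rule (+) supertree, with scores additive
across subproblems. The greedy search considers input-tree clusters by
decreasing size (ties in canonical label order, a choice the original
account leaves open), accepting disjoint validated sets; user-specified
clades are validated the same way and take precedence. The heuristic's
output is not guaranteed to equal the unrestricted
$\mathrm{Maj}^+(P)$ — optimal candidates need not display a reducible
set — so the exact optimum is a lower bound on the restricted score, and
the package always re-validates user sets rather than assuming them.
Satellites whose matrices are still large are decomposed recursively. A
satellite taxon whose every occurrence is in compressed-away trees has no
placement information within $S$; it is reattached at the satellite root,
maximally unresolved.

## The synthetic-profile generator

`generate_profile()` emulates the regime the method is meant for: a
single underlying phylogeny sampled by overlapping studies. It draws a
uniform-split random binary model tree on `n_taxa` leaves, keeps each
leaf of each of the `k_trees` input trees with probability
`1 - deletion_probability` (topping up at random to the structural floor
of 3 leaves rooted / 4 unrooted), restricts the model tree to the kept
leaves, contracts each split with probability `contraction_probability`,
and applies `perturbation_count` split replacements (one split swapped
for a random alternative compatible with the remainder — a deliberately
simple conflict operator; it cannot represent coordinated rearrangements
such as SPR moves). Defaults are `deletion_probability = 0.2`, no
contraction, no perturbation: moderate taxon overlap and no conflict,
the cleanest setting in which the method's zero-score law must hold.
Everything is a deterministic function of `seed`. What passing tests on
these profiles do *not* show: behaviour on real data with correlated
taxon sampling, rogue taxa, or systematic conflict between studies —
the generator's conflicts are independent and unstructured.

## Numerical and degenerate-input choices

* All split handling is exact integer/character arithmetic; the only
  floating point is inside the solver, with a $10^{-6}$ feasibility
  tolerance against integer row bounds.
* Canonical split orientation: the side containing the byte-order
  smallest taxon is stored as 1 (rooted: cluster members are 1
  internally, 0 in the exported matrix, matching the root-side-is-1
  convention). Label ordering is byte-wise, so output is independent of
  the session locale.
* Trees with no nontrivial splits stay in the profile — they affect the
  majority threshold and the tallies — but contribute no matrix columns.
* An all-star profile short-circuits to the star supertree with score 0.
* The Newick writer emits children sorted by smallest leaf label;
  parsing suppresses degree-two nodes and discards branch lengths
  (the method is topology-only).
* Enumeration (`enumerate_fillins`, `brute_force_optimal`) refuses
  matrices with more than 20 question marks by default; it exists as an
  independent oracle, not as a solution path.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the full pipeline against
the enumeration oracle on 100+ random profiles with up to 7 taxa, 4 trees
and 14 question marks (rooted and unrooted), plus fixed fixtures for the
consensus, reduction and degenerate cases; these sizes keep the oracle
exhaustive while exercising every constraint family of the ILP. The exact
pipeline itself handles much larger instances; the enumeration bound, not
the solver, sets the scale of the comparisons.

## Known limitations

* Model size grows as $O(nm^2)$ in the total split count $m$; densely
  resolved profiles with many trees are better served by the reduction
  heuristic, whose output is $S$-restricted rather than exact.
* Only one optimal selection is materialized; the strict consensus over
  all optima is obtained through the verification loop, not by
  enumerating optima.
* The support/conflict report and the reducible-set search are defined
  for rooted profiles (cluster semantics), as is conventional.

## A worked call

```{r example}
p <- read_profile(c("((a,b),c);", "((c,d),b);"), rooted = TRUE)
fit <- majority_plus_supertree(p)
fit
fit$verification
```

The two inputs overlap in `b` and `c` only; the optimum grafts the
missing taxa at zero cost (score 0) and verification confirms which
candidate clusters are present in every optimal candidate tree.
```{r oracle}
bf <- brute_force_optimal(p)
identical(write_newick(bf$supertree), write_newick(fit$supertree))
```
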