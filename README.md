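# majplus — majority-rule (+) supertrees by exact integer programming

`majplus` builds a supertree from a profile of phylogenetic trees whose
leaf sets overlap only partially — the situation faced whenever published
phylogenies of related clades, each sampling different taxa, are to be
combined into one synthesis tree. It implements the **majority-rule (+)**
criterion, the extension of majority-rule consensus to the supertree
setting: unlike matrix-representation-with-parsimony (MRP), it provably
never outputs unsupported groups.

## The method

Given a profile $P = (t_1,\dots,t_k)$ with union leaf set
$\mathcal{L}(P)$, every input tree is expanded to a plenary tree on
$\mathcal{L}(P)$ that displays it (a *representative selection*
$R = (T_1,\dots,T_k)$). The score of a selection is its total
Robinson–Foulds distance to its majority-rule consensus,
$s(R) = \sum_i d(\mathrm{Maj}(R), T_i)$, and the output
$\mathrm{Maj}^+(P)$ is the strict consensus of $\mathrm{Maj}(R)$ over all
optimal $R$. Finding an optimal candidate is NP-hard, so the package:

1. encodes the profile as an MRP-style 0/1/? matrix $M(P)$ whose valid
   0/1 completions (*fill-ins*) are exactly the restricted representative
   selections;
2. minimizes the *adjusted score* — per distinct split, the count of
   incompatible trees if its displayers are in the majority, otherwise
   the count of displaying trees — with a polynomial-size exact integer
   linear program over the fill-in variables (four-gametes compatibility,
   duplicate detection, majority thresholds, all as linear constraints
   over binaries);
3. verifies each split of the optimal candidate by a feasibility sub-ILP
   (can another optimum avoid this split?), yielding the strict consensus
   $\mathrm{Maj}^+(P)$ exactly;
4. optionally decomposes large profiles via *reducible sets* — taxon sets
   separated from the rest in every input tree — into a reduced problem
   plus satellite problems that are solved independently and spliced,
   with additive scores.

The ILPs are solved by the package's own exact branch-and-bound solver
for binary programs (compiled code; deterministic), which branches only
on the fill-in variables and fixes everything else by propagation.
Models can also be exported in LP/MPS format for external solvers. A
brute-force fill-in enumerator provides an independent oracle on small
instances, and a seeded synthetic-profile generator supplies test data.

## Worked example

Two rooted trees overlapping in two taxa:

```r
library(majplus)
p   <- read_profile(c("((a,b),c);", "((c,d),b);"), rooted = TRUE)
fit <- majority_plus_supertree(p)
fit
#> majority-rule (+) supertree fit: n = 4, m = 2, k = 2, U = 2
#> optimal adjusted score: 0
#> verification: 2 of 2 candidate splits retained
#> supertree: ((a,b),(c,d));
```

Score 0 means the inputs can be expanded without any conflict: the two
clusters `{a,b}` and `{c,d}` are grafted together at no Robinson–Foulds
cost, and the verification loop confirms both clusters occur in **every**
optimal candidate tree, so they belong to $\mathrm{Maj}^+(P)$:

```r
fit$verification
#>   split           status
#> 1   c,d in_majority_plus
#> 2   a,b in_majority_plus
```

A larger, conflicting profile from the generator (12 taxa, 4 trees, 83
question marks — far beyond exhaustive enumeration), solved exactly and
then again with the reducible-set heuristic:

```r
g    <- generate_profile(12, 4, deletion_probability = 0.3,
                         perturbation_count = 1, rooted = TRUE, seed = 42)
fit2 <- majority_plus_supertree(g$profile)
fit2
#> majority-rule (+) supertree fit: n = 12, m = 23, k = 4, U = 83
#> optimal adjusted score: 4
#> verification: 9 of 9 candidate splits retained
#> supertree: (((((t01,(t04,t10,t11)),((t02,t06),(t07,t08))),(t03,t09)),t12),t05);

res <- reduced_supertree(g$profile)
res$subproblems
#>        label n  m  U score
#> 1    reduced 8 17 27     4
#> 2 satellite1 3  1  0     0
#> 3 satellite2 3  1  0     0
#> 4 satellite3 3  1  0     0
#> 5 satellite4 3  3  0     0
```

The minimum adjusted score 4 says four split-units of conflict remain
after optimal expansion; the decomposition localizes all of it in the
reduced problem (scores are additive across subproblems).

Other entry points: `majority_plus_consensus()` (polynomial, equal leaf
sets), `adjusted_score()`, `support_report()` (per-cluster
support/conflict/irrelevant counts), `cw_audit()` (the four display
guarantees), `export_matrix()`/`export_ilp()`, and a CLI at
`inst/scripts/majplus-cli.R` with `supertree`, `consensus`, `score`,
`report-support` and `simulate` subcommands.

## Layout

```
R/                core: split algebra, Newick I/O, consensus machinery,
                  matrix encoding, ILP builder, solver driver, reduction,
                  support/conflict, profile generator
src/bnb.cpp       exact branch-and-bound solver for the binary programs
tests/testthat/   unit, property and acceptance tests (oracle-backed)
scripts/          acceptance script
vignettes/        methods vignette (model, assumptions, design choices)
inst/scripts/     command-line interface
```
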