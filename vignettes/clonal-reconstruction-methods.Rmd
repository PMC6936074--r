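---
title: "Reconstructing clonal histories from time-course allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal histories from time-course allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

## The model

An evolving asexual population (the motivating case is an *E. coli*
long-term evolution experiment sampled by pooled whole-population
sequencing) descends from a single founder clone.  Each new mutation —
here restricted to SNVs under the infinite sites assumption, so every
mutation arises exactly once — creates a new clone whose haplotype is its
parent's haplotype plus the new variant.  The ancestry of the clones is a
rooted tree $T$ with the founder at the root; the haplotype of a clone is
the set of variants on its root path.

Pooled sequencing at time point $i$ yields the variant allele frequency
(VAF) $f_{i,j}$ of each variant $j$: the summed population frequency of
all clones carrying $j$, i.e. the frequency of the subtree below $j$.
Writing $c_{i,k}$ for the frequency of clone $k$ at time $i$ (the clonal
frequency matrix, CFM), the two representations are linked by

$$ f_{i,j} = \sum_{k \,\in\, \mathrm{subtree}(j)} c_{i,k}, \qquad
   c_{i,k} = f_{i,k} - \sum_{j \in ch(k),\ t_j \le i} f_{i,j}, $$

with the founder's allele frequency fixed at 1 (`vaf_from_truth()` and
`compute_cfm()`; the pair is an exact inverse, which the test suite
verifies on thousands of simulated instances).

Because spontaneous mutation strikes a clone in proportion to its
abundance, the probability that variant $i$ (first seen at time $i$ of a
"square" course with one new mutation per time point) arose in clone
$pr(i)$ is approximated by that clone's frequency at the preceding time
point.  The likelihood of a candidate tree is therefore

$$ L(T) = \prod_{i=2}^{N} C_{(i-1),\,pr(i)}, $$

and the reconstruction problem is to maximize it over all parent maps
with $pr(i)$ born before $i$.  A tree is *invalid* when at any time a
clone's children jointly exceed the parent's own allele frequency; a tree
with a nonpositive likelihood factor is equally unusable and treated the
same way during search (the validity test only catches strict excess).

A note on the root: we represent the founder as an explicit node 0 with
allele frequency 1, and allow it as a parent candidate at every step.
This makes the factor for every variant well defined (variant 1's factor
is the empty-product 1) and handles real data in which the founder
lineage persists alongside the mutants.

## Search algorithms

* **ET** (`exhaustive_tree_search()`): depth-first enumeration of all
  parent assignments with two sound prunings — a branch dies when a
  likelihood factor falls to $\le$ `tol` (later factors never exceed 1,
  so the product cannot recover) and when the running child-frequency sum
  breaches validity.  The result is identical to full enumeration, which
  the tests confirm against an independent brute-force oracle.  Inputs
  beyond 12 variants are refused (factorial space).
* **GT** (`greedy_tree_search()`): grows the tree root-down, at each step
  taking the parent with the largest current clone frequency, with
  backtracking to the next-best choice when a placement admits no valid
  completion.  Candidate lists at each level are sorted by descending
  clone frequency with ties broken toward the earliest-born clone, so the
  output is deterministic.  Worst case $O(N!)$, best case $O(N^2)$
  candidate evaluations; a configurable `node_budget` guards runaway
  backtracking (unlimited by default for the direct searches; the
  permutation layer caps each permutation's evaluation at 1e5 placements,
  orders of magnitude beyond what any completed greedy search needs,
  because a dead-end ordering — especially under sequenced-clone
  constraints — can otherwise trigger factorial backtracking before the
  search concedes.  An evaluation that exhausts its budget counts as
  having no valid tree, and a replicate where every ordering does so is
  reported as a failure, never silently approximated).
* **Sparse time courses**: when several mutations first appear at the
  same observed time point, their birth order is unknown.
  `extend_vaf()` inserts one virtual row per extra mutation, copying the
  observed time-$t$ values for already-introduced variants and zero for
  the rest (the VAFs are taken as approximately constant across the
  unobserved interval; copying the $t$ endpoint keeps the last inserted
  row identical to the observed row — the $t{-}1$ endpoint would be an
  equally defensible convention, and the choice is localized in
  `extend_vaf()`).  **EP** scores every combination of within-group
  orders ($\prod_i n_i!$ extensions); **GP** commits the
  maximum-likelihood order group by group (scoring each permutation on
  the matrix truncated at that group's observed time), backtracking to
  the previous group's next-best order when a later group admits no valid
  tree — $\sum_i n_i!$ evaluations in the best case, $\prod_i n_i!$ in
  the worst.
* **RP-RT** (`reconstruct(..., "rp-rt")`): the random baseline — a
  uniform order per co-appearing group and a uniformly random valid
  parent per variant, seed-deterministic.

### Constrained search with sequenced clones

Haplotypes of individually sequenced clones restrict the search twice.
First, if variant $v$ occurs in sequenced clones $A_{j}$, then $v$'s
parent variant must lie in $\bigcup_j A_j \setminus \{v\}$ — with one
amendment: when that union contains no variant born before $v$ (always
the case for the earliest constrained variant), the founder is the only
legal parent, so the candidate set falls back to it.  Taking the rule
literally would leave such variants with no parent at all; the fallback
is exact, because the parent clone's haplotype is contained in every
clone carrying $v$, hence the parent variant is either in the union or is
the founder.  Second, for every pair of sequenced clones, the variants of
their intersection must be ancestors of every variant in their symmetric
difference (the shared path forms before the branch; anything else
violates infinite sites).  The second rule is checked incrementally on
partial trees (only placed variants can violate it) and once more on the
final tree.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `neg_tol` | 0 | How far below zero an implied clone frequency may fall before a tree is rejected (unitless frequency). 0 is right for noise-free simulation; 0.4 is a practical setting for read-count VAFs, where entries in $[-0.4, 0)$ are treated as noisy zeros, clamped, and each CFM row renormalized to 1 (clamp first, then renormalize). |
| `similarity_tol` | 0.05 | Maximum per-time-point VAF difference for merging co-appearing variants into one mutation group; matches the 0.05 VAF calling floor. Merged columns carry the per-time mean of their members. |
| `tol` | 1e-9 | Floor for likelihood factors and slack for validity comparisons; frequencies are ratios of read counts, so exact-zero tests would misfire. |
| `alpha` | 50 | Dirichlet concentration of the simulator's between-step drift; the step-to-step s.d. of a frequency-$p$ clone is about $\sqrt{p(1-p)/(\alpha+1)}$. |
| `init_fraction_range` | (0.1, 0.5) | Range of the fraction of its parent's frequency a newborn clone captures. |
| calling thresholds | 0.05 / 10 / 6 | Strict (\>) minima for VAF, read depth and variant reads; strand balance below 0.25 zeroes a site's support at that time point. |

## The simulator, and what passing tests do and do not show

`simulate_population()` emulates the clonal-expansion process the
likelihood assumes: one new clone per step, parent drawn in proportion to
the current clone frequencies, newborn size a uniform fraction of the
parent, then one step of Dirichlet drift (order: sample, birth, drift —
so the recorded step-$i$ composition is exactly the distribution from
which the next parent is drawn).  `observe_vaf()` subsamples time points
(always keeping the final step so late clones are seen), either a fixed
count or $K \sim B(n, 0.6)$; `add_sequencing_noise()` optionally
binomial-samples read-count VAFs at a given depth (off by default — the
evaluation experiments are noise-free).

The drift process is the one deliberate stand-in in the package: the
generative process it emulates is described only as "a stochastic
process" in the motivating work, so we chose a standard compositional
model (Dirichlet centred on the current composition) with the volatility
`alpha` exposed.  This choice matters a great deal for headline accuracy
numbers.  Reconstruction recall is limited by how concentrated the
parent-sampling distribution is: under weak drift (large `alpha`) many
lineages coexist, the parent draw is genuinely ambiguous, and even the
exact maximum-likelihood tree cannot recover it reliably; under strong
drift (`alpha` near 1) lineages sweep and go extinct, parent identity is
nearly deterministic, and greedy recall rises accordingly.  At the
default `alpha = 50` the full-resolution experiment (100 populations of
15 clones observed at 15 time points, `scripts/acceptance.R`) recovers
roughly half of the clone haplotypes — well short of the ~0.85 reported
for the original simulation design, which evidently operated in a far
more volatile, sweep-like regime.  We keep `alpha = 50` as the documented
study condition rather than calibrating it to the published recall;
`run_experiment(..., alpha = )` exposes the sensitivity directly.  The
trend results are robust to this choice: recall grows with temporal
resolution, constrained search helps monotonically, and the greedy
pipeline dominates the random baseline at every population size.

The simulator is also neutral (no selection coefficients) and noise-free
by default, so passing tests certify the combinatorial and statistical
machinery — likelihood, validity, search order, constraint pruning,
metrics — not the fidelity of any particular biological volatility
regime, and say nothing about mapping/calling artifacts upstream of the
VAF matrix beyond the count-level filters in `counts_to_vaf()`.

## Numerical and degenerate-input choices

* Validity and negativity comparisons carry an absolute 1e-9 tolerance;
  CFM rows are renormalized after clamping.
* A likelihood factor of exactly 0 invalidates a tree for ranking but is
  distinguished from a validity violation in diagnostics.
* Ties in the greedy argmax go to the earliest-born candidate; ties in
  ET's optimum go to the first tree found under that same ordering, so
  both searches are reproducible.
* $N = 1$ inputs are legal everywhere (empty likelihood product, value 1).
* Mutation groups larger than 10 are refused by the permutation search
  (more than $4 \times 10^7$ candidate orders), the analogue of the
  exhaustive tree search's 12-variant cap; a birth order that places a
  required ancestor after its dependent variant is recognized as
  infeasible without running the tree search.
* Observed rows at which no variant first appears cannot take part in a
  square extension and are dropped with a warning when they carry signal.
* Variants never observed above zero (a subtree extinct before every
  observation) are dropped by `observe_vaf()`; evaluation then scores
  recall over the observed variants with truth haplotypes restricted to
  that set.
* All stochastic entry points (`simulate_population()`, `observe_vaf()`,
  `add_sequencing_noise()`, the random baselines, `run_experiment()`)
  are seed-deterministic; the experiment driver derives per-replicate
  seeds so the same populations are shared across algorithms, time-point
  conditions and constraint levels.  Topology and drift share one stream
  inside the simulator because the parent choice depends on the drifted
  frequencies — they are not separable components.

## Problem sizes used in the checks

The packaged experiments use the study's own scales: 100 replicates per
condition; 15 clones for the temporal-resolution sweep (6, 10, 12, 14,
15 observed time points); 20 clones with binomially sampled observation
times for the constrained-search benefit (0, 2, 4, 8 supplied true
haplotypes, nested per replicate); 10/15/20 clones for the baseline
comparison; 200 random instances of up to 7 variants for the
exact-search/oracle equivalence; 1000 instances for the forward/inverse
round trip.

## Known limitations

* The drift stand-in above: absolute recall levels are not comparable
  across volatility regimes.
* Likelihood comparison on sparse inputs scores each tree on its own
  square extension (the predicted tree on the search's extension, the
  true tree on the truth-ordered extension), since a single common
  extension need not exist.
* Sequenced-clone haplotypes are taken as exact; sequencing errors in
  clone assemblies are not modelled.
* No copy-number or structural variation, and no violation handling for
  the infinite sites assumption.

## A worked example

```{r example}
F <- rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3))
r <- reconstruct(F, "et")
r$tree
r$likelihood$value
round(r$cfm$values, 3)
```

The three-variant course is reconstructed as founder → v1 → {v2, v3}
with likelihood $1.0 \times 0.6 = 0.6$: v2 must arise in clone v1 (the
founder is fully displaced at time 1), and just before v3 appears clone
v1 still holds frequency $1.0 - 0.4 = 0.6$ against v2's $0.4$, so v1 is
the likelier host.  The greedy and exhaustive searches agree here, and
the CFM rows recover the clone frequencies at each observed time point.
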