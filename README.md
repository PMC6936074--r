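# clonetrace

Maximum-likelihood reconstruction of clonal evolutionary history from
time-course pooled sequencing.  Given the variant allele frequencies
(VAFs) of an evolving asexual population — typically an *E. coli*-style
long-term evolution experiment sequenced as a pool at successive time
points — `clonetrace` infers which clone each new mutation arose in
(the clonal tree), the haplotype of every clone, and the clone
frequencies at every observed time point.

## The model in brief

Under the clonal model with the infinite sites assumption, a variant's
VAF is the summed frequency of all clones carrying it, and a spontaneous
mutation strikes a clone in proportion to its abundance.  For a VAF
matrix `F` with one new mutation per time point, the likelihood of a
candidate parent map `pr` is

```
L(T) = prod_{i=2..N}  C[i-1, pr(i)],
C[i, k] = f[i, k] - sum of f[i, j] over children j of k born by time i
```

with the founder's allele frequency fixed at 1.  Trees whose implied
clone frequencies go negative are invalid.  The package provides:

* exhaustive (`et`) and greedy-with-backtracking (`gt`) tree searches;
* permutation search over the unknown birth order of mutations that
  first appear at the same observed time point (`ep-*`, `gp-gt`), with
  the square lower-triangular matrix extension this requires;
* constrained search using haplotypes of individually sequenced clones;
* the random baseline (`rp-rt`);
* a clonal-expansion simulator with Dirichlet frequency drift, the
  evaluation metrics (clone recall, log likelihood ratio) and a
  replicated experiment driver;
* count-table preprocessing (strand-balance, calling and temporal
  consistency filters) and Muller-plot / haplotype-table export.

## Worked example

```r
library(clonetrace)
F <- rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3))
r <- reconstruct(F, "et")
r$tree
#> Clonal tree on 3 variants (+ founder)
#>   v1 <- founder
#>   v2 <- v1
#>   v3 <- v1
r$likelihood$value
#> [1] 0.6
round(r$cfm$values, 3)
#>    founder  v1  v2  v3
#> t1     0.0 1.0 0.0 0.0
#> t2     0.0 0.6 0.4 0.0
#> t3     0.1 0.1 0.5 0.3
```

Variant 2 must have arisen in clone v1 (the founder is fully displaced
at time 1, so its factor is `1.0`), and variant 3 more likely arose in
v1 (frequency `1.0 - 0.4 = 0.6` just before it appears) than in v2
(`0.4`); the product `1.0 * 0.6 = 0.6` is the maximum over all valid
trees.  The clonal frequency matrix rows give the clone composition at
each time point and feed straight into `export_muller()` for plotting
with any Muller-plot library.

On sparse data, mutations co-appearing at one time point are ordered by
the permutation search:

```r
truth <- simulate_population(15, seed = 1)       # 15 clones, Dirichlet drift
Fobs  <- observe_vaf(truth, 6, seed = 2)         # only 6 time points observed
fit   <- reconstruct(Fobs, "gp-gt")
clone_recall(fit$tree, project_tree(truth$tree, Fobs$variant_ids),
             variants = Fobs$variant_ids)
#> [1] 0.4
```

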