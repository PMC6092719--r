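---
title: "Core subset selection: models, measures and search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core subset selection: models, measures and search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresampler)
```

## The problem

A genebank holds a collection $\mathcal{A}$ of $n$ accessions — plant
lines, varieties, or clones — characterized by molecular markers,
phenotypic traits, or a precomputed dissimilarity matrix. A *core
collection* is a fixed-size subset
$\mathcal{C} \subset \mathcal{A}$, $|\mathcal{C}| = k$, chosen to
represent the collection's diversity with minimal redundancy. Writing
$F(\mathcal{C})$ for a quality measure, the selection problem is

$$\mathcal{C}^* = \underset{\mathcal{C} \in \Omega}{\mathrm{argmax}}\, F(\mathcal{C}),
\qquad \Omega = \{\mathcal{C} \subset \mathcal{A} : |\mathcal{C}| = k\},$$

with measures to be minimized entering as $-F$. The space $\Omega$ has
$\binom{n}{k}$ elements, so beyond toy sizes the optimum must be found
by heuristic search.

## Evaluation measures

All distance-based measures read a symmetric $n \times n$ matrix
$d \in [0,1]$ with zero diagonal, computed from the data or supplied
directly:

* **E-NE** (entry-to-nearest-entry), maximized for *diversity*:
  $\frac{1}{k} \sum_{i \in \mathcal{C}} \min_{j \in \mathcal{C}, j \ne i} d(i,j)$.
  Unlike the classical average entry-to-entry distance it does not
  overrepresent extremes, and unlike the raw minimum distance it
  changes smoothly under single swaps, which local search needs.
* **A-NE** (accession-to-nearest-entry), minimized for
  *representativeness*:
  $\frac{1}{n} \sum_{a \in \mathcal{A}} \min_{j \in \mathcal{C}} d(a,j)$,
  where selected accessions contribute 0.
* **DMIN**, the minimum pairwise distance among entries, is *reported
  but never optimized*: many swaps leave it unchanged, so it gives a
  local search no gradient. Maximizing E-NE keeps it high indirectly —
  `min_distance()` is exposed for evaluation only.
* **avg-EE**, the mean pairwise entry distance, kept as a comparator.
* **HE**, average expected heterozygosity per locus, maximized for
  allelic richness on marker data:
  $HE = \frac{1}{L} \sum_{l=1}^{L} \bigl(1 - \sum_{a=1}^{n_l} \hat p_{la}^2\bigr)$,
  with $\hat p_{la}$ the mean allele-$a$ frequency at locus $l$ over
  the core entries (entries carry within-accession frequency vectors,
  which generalizes allele counting to any ploidy or pooled sample).

Genotype dissimilarity uses the Modified Rogers distance
$MR(i,j) = \sqrt{\sum_l \sum_a (p_{ila} - p_{jla})^2 / (2L)}$, scaled
so opposite homozygotes at every locus are at distance 1. Phenotype
dissimilarity uses Gower's coefficient with equal trait weights:
range-scaled absolute difference for quantitative traits (0 when the
observed range is 0), 0/1 matching for qualitative ones. **Missing
data policy** (a choice of this package; the measures themselves do
not prescribe one): loci or traits missing in either accession are
deleted pairwise, and a locus enters a core's HE average whenever at
least one entry observes it. Frequency vectors that do not sum to 1
within $10^{-6}$ are an error rather than being renormalized, so
evaluation is deterministic.

## Weighted index and normalization

Several measures can be optimized jointly as
$F(\mathcal{C}) = \sum_i \alpha_i F_i(\mathcal{C})$ with
$\sum \alpha_i = 1$, minimized measures negated. Because raw scales
differ (an A-NE of 0.05 and an HE of 0.6 are not comparable), each
sign-adjusted measure is first normalized to $[0,1]$ by an
upper/lower-bound map $(v - L_i)/(U_i - L_i)$, clamped. The bounds are
the *Pareto minimum* construction implemented in
`compute_normalization_ranges()`: $U_i$ is the best value found by a
dedicated single-objective search, and $L_i$ is the worst value
measure $i$ takes across the single-objective optima of *all*
objectives. The interval therefore spans exactly the conflict region
of the Pareto front. The bound searches use random descent with
seed-derived sub-seeds and the caller's budget, so ranges are
reproducible; a measure whose interval collapses ($U_i \le L_i$, all
optima coincide) is dropped from normalization with a warning and
treated as the constant 1. Single-objective runs are not normalized —
normalization is monotone, so the optimum is unchanged and the raw
value is more interpretable.

## Search engines

All engines move through the **single-swap neighbourhood**: replace
one selected accession with one unselected accession ($k(n-k)$
moves). Swap candidates are scored incrementally: nearest and
second-nearest entry caches for E-NE and A-NE, per-locus frequency
sums for HE, and the pairwise sum for avg-EE, so one proposal costs
$O(k)$, $O(n)$ or $O(A)$ instead of a full re-evaluation. A dedicated
checker (`cpp_delta_check`) verifies the incremental values against
from-scratch evaluation to below $10^{-12}$.

* **Random descent** (`random_descent()`, the "fast mode"): start
  from a uniform random $k$-subset, draw a uniform random swap, accept
  if and only if it is *strictly* better. Ties are rejected.
* **Parallel tempering** (`parallel_tempering()`, the default): $p =
  10$ Metropolis searches at fixed temperatures spread *linearly* over
  $[10^{-8}, 10^{-4}]$ (linear, not logarithmic, spacing is the plain
  reading of "equally spread"). A replica at temperature $t$ accepts a
  swap with probability $p(\Delta, t) = 1$ if $\Delta > 0$, else
  $e^{\Delta/t}$ — so ties are accepted here, since $e^0 = 1$; the two
  engines' rules differ and both are kept as stated. After every $q =
  500$ steps per replica, one exchange pass over the adjacent pairs
  $(1,2), (2,3), \ldots, (p-1,p)$ attempts to swap current selections
  with probability $q(\Delta_r, t_r, t_{r+1}) = 1$ if $\Delta_r > 0$,
  else $e^{(1/t_r - 1/t_{r+1})\Delta_r}$. How often to exchange, and
  in what order, is not fixed by the algorithm's definition; one
  ordered pass per round is the simplest schedule that pushes good
  solutions towards cold replicas, and it keeps a sequential execution
  bit-identical for a given seed, which we prioritized over raw
  parallel speed. The best solution across all replicas is tracked
  separately, so the reported trace never decreases even though
  replicas accept inferior moves.
* **Genetic algorithm** (`genetic_algorithm()`): population 25;
  each generation creates 5 children by tournament selection (best of
  5 random candidates), crossover, and mutation, then discards 5 by
  roulette to keep the population size fixed. Crossover repeatedly
  adds an accession selected in either parent until size $k$ — since
  draws are uniform over the parents' union, this is implemented as a
  uniform $k$-sample of the union. Mutation applies random descent
  until 5000 consecutive proposals bring no improvement. Discard
  weights are $1/F$; if a fitness is non-positive (possible with raw
  sign-adjusted measures), all fitnesses are shifted by
  $|\min F| + 10^{-9}$ first, since $1/F$ is otherwise undefined.

Stop conditions (`stop_condition()`) combine wall-time and
evaluation-count limits, absolute or since-last-improvement; the
default is 10 s without improvement, which adapts the effective
runtime to the collection size. Tests and scripted experiments use
evaluation counts instead so that results are machine-independent.
Every engine is deterministic given its seed; the compiled kernels use
a self-contained splitmix64 generator so results are identical across
platforms.

## Baselines

* **GDOpt** (`gdopt_select()`) clusters the collection with PAM
  k-medoids and selects the $k$ medoids. PAM is implemented from the
  classical description — BUILD (greedy medoid addition) then SWAP
  (best improving medoid/non-medoid exchange until none exists) — and
  is deterministic with lowest-index tie-breaks. The PAM objective
  equals $n \cdot$ A-NE of the medoid core, which makes GDOpt the
  natural representativeness baseline. Note that SWAP certifies only
  exchange-local optimality: on unstructured instances it can (like
  any PAM implementation) return a certified local optimum above the
  global one.
* **SimEli** (`simeli_select()`) repeatedly finds the closest
  remaining pair and eliminates one member until $k$ remain. The
  `"A-RA"` criterion scores each member by its mean distance to the
  other remaining accessions (pair partner excluded — whether the
  partner counts is not fixed by the method's description; excluding
  it is the reading adopted here) and eliminates the smaller score;
  the `"HE"` criterion eliminates the member whose removal leaves the
  higher expected heterozygosity. All ties break towards the lower
  index, making the procedure fully deterministic.

## Synthetic data

`synthetic_spec()` + the generators produce the three structural
regimes the tool targets, without shipping any data: biallelic SNP
panels (population allele frequency per locus from a spread-controlled
prior, accession dosages binomial as under random mating), multiallelic
SSR-like panels (2–10 alleles per locus, two draws per accession),
mixed trait tables (28 qualitative + 11 quantitative by default), and
direct distance matrices, either uniform or clustered with guaranteed
group separation (within-group distances U(0.02, 0.15), between-group
U(0.4, 0.95)). `inject_duplicates()` plants groups of exact copies to
probe duplicate avoidance. The generators emulate *structure* only —
marker counts, allelic richness, missingness, duplication — not
population-genetic realism: there is no linkage disequilibrium, drift,
or pedigree, and no attempt to match any real collection's values. A
passing test on synthetic data therefore demonstrates algorithmic
correctness and the qualitative behaviour of the measures, not
numerical agreement with any particular germplasm panel. The triangle
inequality is deliberately not enforced for uniform random matrices:
none of the nearest-entry measures require metricity.

## Numerical and design choices

* Core sizes given as fractions round half up, clamped to
  $[2, n-1]$; $k = 1$ is excluded because E-NE has no "closest other
  entry" there.
* Distance matrices must be symmetric within $10^{-9}$ with an exactly
  zero diagonal; sub-tolerance asymmetry is averaged away on input.
* Sub-seeds for repeated runs are `base_seed + run_index`, so any run
  in a sweep or comparison can be reproduced in isolation.
* Brute-force enumeration (`brute_force_optimum()`) refuses instances
  above $10^6$ subsets and breaks ties towards the lexicographically
  smallest index set.
* Exact ties in nearest-entry caches resolve by insertion order; this
  only affects which of two equal-valued neighbours is recorded, never
  the measure value.

## Problem sizes used in the shipped experiments

The test-suite and acceptance-script experiments run at sizes chosen
to finish in minutes on one CPU while staying in the regimes of
interest: the exhaustive-oracle suite at $n = 12$, $k = 4$ (495
subsets, 30 instances); the engine comparison on one synthetic SNP
panel at $n = 500$, $L = 200$, $k = 100$ (20%), 10 runs per engine at
$5 \times 10^5$ evaluations each — a scaled-down analogue of
long-runtime convergence experiments; and the Pareto sweep versus
SimEli-HE on an SSR panel at $n = 200$, $k = 40$, 21 weight settings
at step 0.05. Under the clustered oracle instances, random descent
reaches the global optimum in roughly 40% of runs — it is a plain
hill-climber and stalls in the first local optimum it meets — while
parallel tempering reaches it essentially always; this gap is exactly
the motivation for tempering.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
geno <- generate_genotypes(synthetic_spec(n = 100, loci = 200, seed = 42))
ds <- core_dataset(genotypes = geno)
res <- parallel_tempering(ds, objective_config(list(objective("E-NE"))),
                          k = 20, stop_condition(max_evals = 1e5),
                          seed = 7)
res
evaluate_core(ds, res$core, objective_config(list(objective("E-NE"))))$report
```

## Limitations

* Variable-size core sampling is out of scope; the measures here are
  not comparable across core sizes.
* DMIN cannot be selected as an objective (by design, see above).
* Ordinal traits are not modelled; treat them as qualitative or
  pre-code them numerically.
* Replicas of the tempering search run sequentially; the
  deterministic-schedule contract trades away multi-core speed.
* Gower and Modified Rogers are the only built-in dissimilarities;
  anything else can be supplied as a precomputed matrix.
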