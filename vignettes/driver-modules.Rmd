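---
title: "Balanced mutually exclusive driver modules: model and methods"
author: "unicovex package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced mutually exclusive driver modules: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unicovex)
```

## The problem

Somatic mutation calls from a cancer cohort form a binary gene-by-sample
matrix. Two regularities motivate module-level driver discovery. First,
mutations in genes of the same driver pathway tend to be *mutually
exclusive*: a single hit is usually enough to deregulate the pathway, so
most samples carry at most one mutated gene per pathway. Second, the
mutation-frequency landscape has a *long tail*: most mutated genes are rare,
so frequency alone cannot separate drivers from passengers.

Coverage-plus-exclusivity objectives such as the Dendrix weight
$W(M) = 2\,|\bigcup_i P_i| - \sum_i |P_i|$ (coverage minus coverage overlap,
where $P_i$ is the set of samples in which gene $g_i$ is mutated) can be
dominated by a single high-frequency gene: a module made of one frequent
gene plus noise and a strictly exclusive, evenly covered module can receive
the same weight. This package therefore scores, in addition to coverage and
exclusivity, how *balanced* the exclusive coverage of a module is.

## The score

For a module $M = \{g_1, \dots, g_s\}$, let $P_i$ be the mutated samples of
$g_i$ and $EP_i \subseteq P_i$ its *exclusively* mutated samples — samples
where no other module gene is mutated. With $n_i = |P_i|$ and
$n'_i = |EP_i|$:

* **exclusive degree** $\mathrm{Ex}(g_i) = n'_i / n_i$;
* **exclusive score** $\mathrm{Ex}(M) = \frac1s \sum_i \mathrm{Ex}(g_i)$,
  which is 1 exactly when the $P_i$ are pairwise disjoint;
* **exclusive entropy** $H(M) = -\sum_i p_i \log_2 p_i$ with
  $p_i = n'_i / n'$ and $n' = \sum_i n'_i$, the Shannon entropy (bits) of
  how the exclusive coverage distributes over the genes. It is maximal,
  $\log_2 s$, iff all $n'_i$ are equal;
* **composite score** $\mathrm{score}(M) = \mathrm{cov}(M)\,
  \mathrm{Ex}(M)\, H(M)$, where $\mathrm{cov}(M) = \min_i n_i$ is the
  minimum per-gene coverage.

A four-gene strictly exclusive module whose eight exclusive samples split
evenly (2, 2, 2, 2) scores $H = 2.0$ bits; the unbalanced split (4, 2, 1, 1)
scores $H = 1.75$ bits, although both have the same coverage. The entropy
term is what penalizes modules whose coverage is carried by one gene.

Conventions for degenerate cases: $0 \log 0 = 0$; $H(M) = 0$ when $n' = 0$
(no exclusive sample means no balance information, and the composite is 0);
singleton modules have $H = 0$ and therefore always score 0, so reported
modules have 2–5 genes.

Two coverage notions coexist in this literature: the minimum per-gene
coverage and the union coverage $|\bigcup_i P_i|$. The composite uses the
minimum — the conservative reading, under which one rare gene caps the whole
module — while union coverage is what sample covering needs. Both are
computed and reported side by side (`minCoverage()`, `unionCoverage()`), and
the Dendrix weight is carried in every report for comparison, never for
selection.

## Candidate discovery

Search is constrained by a gene *influence network*: an undirected weighted
graph whose weights are topological influence scores, typically derived from
a protein–protein interaction network by an insulated heat diffusion
(random walk with restart, `diffuseInfluence()`,
$F = \beta (I - (1-\beta) W)^{-1}$ with $W$ the column-normalized adjacency
and restart probability $\beta = 0.45$ by default). Precomputed influence
networks can be read directly as weighted edge lists; the diffusion operator
exists so the tool is self-contained. The two directed influences of a pair
are symmetrized by their minimum by default (both genes must influence each
other); `max` and `mean` are available.

The network is first *reduced* by a single global weight cutoff keeping the
$\lceil d\,|V|/2 \rceil$ heaviest edges, for a target average degree
$d = 15$ — about the average degree of a real PPI network. Ties at the
threshold weight are all kept, so the achieved degree can slightly exceed
the target; a per-node top-$k$ rule was rejected because it is not a global
"remove small-weight edges" operation. Around every seed gene present in
both the reduced network and the recurrence-filtered matrix, a *local
network* of up to 100 genes is extracted by breadth-first search; within a
BFS step neighbors are visited by descending edge weight, then
lexicographically, making extraction fully deterministic.

Inside each local network, a candidate module is *grown greedily*
(`growModule()`): starting from the seed, the pool gene maximizing
$\mathrm{Ex}$ of the grown module is added at each step. We read "maximizes
its exclusive score" as maximizing the grown module's $\mathrm{Ex}$ (one
consistent objective, matching the stopping rule), not the candidate's own
exclusive degree. Ties on $\mathrm{Ex}$ go to the candidate yielding the
larger union coverage, then to the lexicographically smaller symbol. Growth
stops at size 5 or when the best attainable $\mathrm{Ex}$ falls strictly
below the cutoff 0.95 (a candidate reaching 0.95 exactly is still added).
All intermediate modules of sizes 2 up to the final size enter the catalog:
sub-modules are candidates in their own right. Genes mutated in fewer than
2 samples are never considered.

The catalog (`buildCatalog()`) deduplicates by gene set and sorts each size
class by descending composite. Per size class, modules are then *selected*
in score order until every coverable sample is covered
(`selectCoveringModules()`); samples that no module of that size can touch
are reported as uncoverable rather than looped on.

## Sample-specific prediction and consensus

Within each size group 2–5, selected modules are fed to a classic greedy
minimum set cover (`greedySetCover()`): repeatedly pick the module covering
the most not-yet-covered samples (a module covers a sample when at least one
of its genes is mutated there), ties broken by higher composite, then by
gene-set key. Sizes are covered separately because greedy covering is
biased toward large modules. Each sample's *sample-specific driver modules*
are all chosen modules that cover it; the four size groups are reported side
by side rather than merged, since no principled merge rule presents itself.

When several influence networks are available, the final predictions are
the *consensus modules* supported by at least 2 networks
(`consensusModules()`). Exact gene-set identity is the default agreement
rule (the strictest reading); an optional Jaccard rule merges modules from
different networks at a configurable similarity threshold, because
cross-network module identity is otherwise undefined. Selection happens per
network and consensus afterwards, matching the per-network character of the
candidate search.

## Evaluation

`precisionRecall()` scores the union of consensus genes against a reference
cancer-gene list: precision is hits over predicted; recall divides by the
reference genes *mutated in the cohort* (unmutated reference genes are
unrecoverable). For curves, every cohort-mutated gene is ranked by the
maximum composite of any catalog module containing it (0 if none) — the
ranking rule is a package choice, stated here because nothing in the method
prescribes one. `rankedCurves()` reports the PR curve with the
average-precision step integral (trapezoidal PR interpolation is optimistic
and is avoided) and the ROC curve with the usual trapezoid.

## The planted-cohort simulator

`generatePlantedCohort()` provides ground truth without any download. It
emulates: (i) mutually exclusive planted modules — samples are partitioned
into blocks, one per module, and each covered sample mutates exactly one
module gene, drawn from a configurable balance distribution; (ii) an
exclusivity *leak* $\varepsilon$ that adds a second module gene to a covered
sample with probability $\varepsilon$; (iii) a long-tailed passenger
background, with the $r$-th passenger gene mutated per sample with
probability $\mathrm{rate} \cdot r^{-\alpha}$ ($\alpha = 2$ by default,
top rate 0.05); and (iv) a network wiring each truth module as a heavy
clique plus light random decoy edges. A deterministic allocation mode
apportions exclusive counts exactly (largest remainder), so the entropy
worked examples are exact rather than stochastic. Everything is driven by a
mandatory seed; the same seed regenerates a byte-identical cohort.

What the simulator does *not* emulate: mutational signatures, hypermutator
samples, copy-number or expression effects, and realistic PPI topology
(scale-free degree structure). Passing recovery tests therefore show that
the search and scoring machinery behaves as designed under its own model
assumptions — not that those assumptions hold in any real cohort.

One property worth understanding: on a toy graph that fits entirely inside
a single 100-gene local network, the topological constraint is vacuous, and
unions of high-coverage genes drawn from *different* planted modules can
legitimately outscore the planted modules themselves (they are pairwise
disjoint by construction, so $\mathrm{Ex} = 1$, with a higher minimum
coverage). Topology is the only thing separating parallel pathways in this
model. Recovery tests therefore plant modules on separate graph components
(`separateComponents = TRUE`), which is the small-scale analogue of a real
cohort where 100-gene neighborhoods are a tiny fraction of an
11,000-gene network.

```{r recovery}
cohort <- generatePlantedCohort(nSamples = 120, nGenes = 60, nModules = 3,
                                moduleSize = 4, passengerRate = 0.05,
                                separateComponents = TRUE, seed = 42)
rec <- recoveryHarness(cohort)
rec$perModule
```

## Parameters

| parameter | default | meaning |
|---|---|---|
| `localSize` | 100 genes | BFS local-network cap |
| `maxSize` | 5 genes | maximal module size |
| `exCutoff` | 0.95 | minimal $\mathrm{Ex}$ of a grown module (strict stop below) |
| `minRecurrence` | 2 samples | recurrence filter for considered genes |
| `targetAvgDegree` | 15 | reduced-network average degree |
| `minSupport` | 2 networks | consensus support |
| `agreement` | exact | consensus identity rule (`jaccard` optional, threshold 0.5) |
| `beta` | 0.45 | diffusion restart probability |
| `symmetrize` | min | directed-influence symmetrization |

All defaults are the standard operating values of the method; they are also
what `unicovexConfig()` returns and what the command-line front end uses.

## Numerical and determinism notes

* $\mathrm{Ex}$ comparisons use a $10^{-12}$ tolerance; exclusive scores are
  ratios of small integers and the cutoff comparison must not be decided by
  floating-point representation error.
* Every ordering in the pipeline has a total, documented tie-break ending in
  lexicographic gene order, so identical inputs and configuration produce
  byte-identical catalogs, covers and consensus files. The only randomness
  in the package lives in the simulator, behind its seed.
* Degree reduction is idempotent; growth chains are strictly nested; the
  greedy cover's contract is its pick sequence (validity always, the usual
  $1 + \ln n$ guarantee versus the optimum), not optimality.

## Problem sizes used by the test suite

Unit and property tests run on matrices of up to ~25 genes × 15 samples with
exhaustive (per-sample enumeration, subset enumeration, exhaustive set
cover) oracles; the oracle-equivalence sweep uses 200 seeded random
instances of at most 10 genes × 12 samples; recovery runs use cohorts of 120
samples × 60 genes with 3 planted 4-gene modules, and the leak-rate sweep
averages 5 seeds per grid point. These sizes make every expected value
independently checkable by brute force while exercising all code paths.

## Limitations

The method favors strictly exclusive modules: with the 0.95 cutoff, modules
with moderate but real exclusivity are never grown. The minimum-coverage
term makes scores sensitive to the rarest module gene. Consensus by exact
identity is conservative — near-identical modules from different networks
need the Jaccard rule to merge. And the greedy search offers no optimality
or significance guarantee; scores are selection heuristics, not p-values.
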