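---
title: "Detecting monotonically expressed genes with network-weighted screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting monotonically expressed genes with network-weighted screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megrank)
```

## The problem

Tumor progression is ordered: pathologic stages (I–IV, or sub-stages such
as IA/IB/IIA/IIB, optionally preceded by a normal-control group) encode a
direction of travel. A gene whose mean expression moves monotonically along
that ordering — always up, or always down — is a different biological object
from one that spikes at a single stage or follows a U-shape, and a screen
for such monotonically expressed genes (MEGs) needs two ingredients a plain
differential-expression test does not supply: an *ordinal* notion of stage,
and a *shape* constraint on the stage profile.

`megrank` implements a three-step screen with an optional network weighting
in front, plus two comparators, and a planted-signal simulator that lets
every claim in this vignette be checked by running code.

## The GeneRank weighting

For one sample with expression vector $e \in \mathbb{R}^p$, the weighted
expression $r$ solves

$$(I_p - d\,W \tilde D^{-1})\, r = (1-d)\, e,$$

with $W$ the $p \times p$ binary symmetric adjacency of a gene-interaction
network, $\tilde D$ the diagonal degree matrix, and $d \in [0,1)$ a damping
parameter. This is the PageRank idea transplanted to expression: a gene's
score blends its own expression with the scores of its interaction
partners, each partner's contribution diluted by that partner's degree. At
$d = 0$ the solution is $e$ itself; as $d \to 1$ topology dominates. The
practical consequence is that a hub gene with a subtle but consistent
expression trend can accumulate evidence from its neighbourhood and survive
a screen it would otherwise fail.

Numerical choices, all of which are contract-tested:

* **Zero-degree convention.** Isolated genes would make $D$ singular; we
  set their diagonal entry to 1. Their column of $W$ is all-zero, so their
  solution is exactly $r_k = (1-d)e_k$ regardless of the convention — the
  unit entry only avoids a division by zero. This also means expression
  genes absent from the network (kept by the default
  `isolated_policy = "keep"` of `align_to_genes()`) pass through the
  weighting as a pure rescaling, which the rank-based test downstream
  ignores.
* **$d = 1$ is rejected**, not supported as a limit: the system matrix is
  singular there. The default is $d = 0.5$, an even balance.
* **Solver.** A direct solve (dense below 500 genes, sparse LU above) with
  a hard residual contract
  $\|(I - dW\tilde D^{-1})r - (1-d)e\|_\infty \le \mathrm{tol}\cdot
  \max(1, \|e\|_\infty)$, default tolerance $10^{-8}$, one round of
  iterative refinement, and an error rather than a silent degradation if
  the contract cannot be met. Power-iteration approximations are
  deliberately out of scope: at these sizes the exact solve is cheap and
  the contract is checkable.
* **The solved vector is used as-is.** One could instead rank-transform
  $r$ within each sample; both readings of "weighted expression values"
  are defensible, we default to the raw solution and expose
  `rank_transform = TRUE` in `generank_matrix()`. Similarly, classic
  GeneRank assumes nonnegative input; we do not shift by default (the
  linear system is well-posed either way) and expose
  `shift_nonneg = TRUE` for centred inputs.

## The three-step screen

`identify_megs()` takes any genes × samples matrix — raw or weighted — and
a `stage_design()`:

1. **Kruskal–Wallis per gene** across stage groups (tie-corrected $H$,
   $\chi^2_{K-1}$ p-value, via `stats::kruskal.test`). A rank test is the
   right tool here because the GeneRank transform changes scales
   per sample-column only through a fixed linear system; what should matter
   is ordering, not magnitude. Zero-variance genes get $(H=0, p=1)$ and
   stay in the family, so the adjustment's $m$ equals the gene count.
2. **Adjustment** across genes: Benjamini–Hochberg by default (the
   standard for expression screens), Bonferroni or none as options.
3. **Monotone classification** of the stage-mean profile
   $\bar x_{(0)} , \bar x_1, \dots, \bar x_K$ (control first when
   present): `MI` if nondecreasing with at least one strict increase, `MD`
   if nonincreasing with at least one strict decrease, `none` otherwise.
   Non-strict chains tolerate plateaus, which real staged data produce
   constantly; requiring at least one strict step excludes the constant
   profile, which satisfies both non-strict chains but is not
   differentially expressed in any direction (and could not pass step 2
   anyway).

Two sequencing decisions were genuinely open and are fixed as follows:
direction labels are assigned **after** thresholding (a gene is "an MEG at
$\alpha$", and `meg_summary()` re-derives counts over the conventional grid
$\{0.05, 0.1, 0.15, 0.2\}$ from the stored unthresholded `trend` column,
which also makes the counts provably nondecreasing in $\alpha$); and
control samples are **included** in the Kruskal–Wallis grouping by default
(they are a group like any other), with `control_in_test = FALSE` to
restrict the test to tumor stages while keeping the control at the head of
the monotone chain.

## The MFSelector comparator

`mfselect()` scores each gene by its total discriminating error. For each
cumulative split $k$ (first $k$ stage groups vs the rest), a
*discriminating line* is a threshold on the gene's expression; under the
increasing direction, lower-side samples above the line and upper-side
samples at or below it are misclassified. `DEtotal` is the sum over the
$K-1$ splits of the minimum misclassification. Conventions, fixed and
tested rather than recovered from any external implementation:

* **Candidate lines** are all observed values of the gene, plus a sentinel
  below all observations that concedes the whole lower side. The sentinel
  guarantees the per-split bound
  $\min \le \min(n_\text{lower}, n_\text{upper})$; the rest of the
  candidate set contains every optimum a finer grid could find, because
  the misclassification function only changes at data points.
* **Boundary rule:** a sample exactly at the line counts as below it. One
  consequence worth knowing: a tie across a split boundary always costs an
  error, so `DEtotal` $= 0$ forces the $K-1$ minimizing lines to be
  strictly ordered — the "perfect monotone" flag coincides with a zero
  score under this convention.
* **Decreasing direction by negation**, making the duality
  `detotal(v, dec) == detotal(-v, inc)` exact by construction (the
  boundary rule mirrors with it).
* **Permutation null:** stage labels are permuted (by default one shuffle
  per round shared by all genes, preserving between-gene correlation of
  the null; `per_gene_perms = TRUE` switches to independent nulls), and
  the p-value uses the add-one estimator
  $(1 + \#\{\text{perm} \le \text{obs}\})/(B+1)$, never zero. Exact
  enumeration over all distinct label assignments is available for small
  cohorts (`exact = TRUE`). Adjustment reuses the same BH step as the main
  screen rather than a separate q-value estimator — one fewer estimator to
  validate, at the cost of a slightly more conservative cutoff.

DEtotal depends on the data only through within-gene ranks, so it is
invariant to any strictly increasing transform — asserted on random
fixtures, along with equality to a brute-force enumeration oracle on
hundreds of random genes.

## What the simulator emulates, and what it does not

`simulate_expression()` produces Gaussian noise around a baseline of 7 on a
log-like scale — the regime of post-summarization microarray values and
log2(FPKM+1) RNA-seq — with planted MI genes shifted by
$k \cdot \texttt{effect\_step} \cdot \texttt{noise\_sd}$ at the $k$-th
stage group and MD genes mirrored. Defaults are four stages of 15 samples,
a one-noise-sd step, and 50 + 50 planted among the gene universe: a
mid-sized staged cohort with a minority of genuinely monotone genes. A
`plateau` shape (rising over the first half of the transitions, then flat)
exercises the tie-tolerance of the monotone chain; a `hub_planted` mode
places the signal on the highest-degree network nodes, the configuration
the GeneRank weighting is designed to reward. `simulate_network()` supplies
Erdős–Rényi and preferential-attachment (scale-free) topologies via
`igraph`, the latter with a deterministic edge count and heavy-tailed
degrees.

The simulator deliberately does **not** model probe-level artifacts, batch
effects, count overdispersion, or correlated background genes; nor does it
couple expression to network distance except through `hub_planted`.
Passing recovery tests therefore demonstrates that the procedure's
statistics behave as designed under clean ordinal signal — sensitivity
$\ge 0.9$ at a one-sd step with controlled false-discovery proportion and
zero direction flips — not that any particular cohort will yield similar
counts. On real data, preprocessing (normalization, batch correction) is
assumed done upstream; the only transform offered at read time is
`log2(x+1)` for FPKM-like input.

## Problem sizes and determinism

The shipped tests run the recovery study at 1000 genes × 60 samples, the
solver contracts at up to 2000 genes, and the DEtotal oracle sweeps at
$n \le 30$ with hundreds of random genes — sizes chosen so the whole suite
exercises every contract in well under a minute while leaving the
statistics clearly out of the small-sample regime. Every stochastic step
(simulation, permutation) takes an explicit seed, uses it locally without
touching the caller's RNG state, and is bit-reproducible; pipeline runs
with identical configuration produce byte-identical output files.

## Known limitations

* Gene identifiers are matched as exact case-sensitive strings; symbol
  aliasing between an expression platform and a network resource must be
  resolved upstream.
* The monotone filter classifies empirical stage means; with tiny groups a
  true plateau is called `none` whenever noise tips an adjacent pair the
  wrong way. Trend tests with explicit ordinal alternatives
  (Jonckheere–Terpstra, isotonic regression) are out of scope by design.
* The network is unweighted and undirected; confidence scores and edge
  direction are ignored at parse time.
* MFSelector's permutation null is exchangeable across all samples; designs
  with structure (batches, pairing) would need a restricted permutation
  scheme the package does not provide.
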