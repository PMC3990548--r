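---
title: "Methods: weighted co-expression networks, module detection and preservation in coexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted co-expression networks, module detection and preservation in coexnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
library(dplyr)
```

`coexnet` analyzes matched two-condition time-course expression data the
way weighted co-expression network analysis treats any transcriptome: genes
become nodes, correlation magnitude becomes connection strength, and the
questions — which modules exist, where they persist, when they are active,
who their hubs are — become network statistics. This vignette records the
model, every tunable that matters, and the design choices that were
genuinely open, so that results can be interpreted and the package
maintained without reverse-engineering the code.

## The network model

For one condition with gene × sample matrix $X$ (log-ratio scale,
samples ≥ 3), the pipeline computes:

1. **Correlation.** Pearson $r_{ij} = \mathrm{cor}(x_i, x_j)$. Constant
   rows have undefined correlation and are rejected by name rather than
   silently propagated as `NA`.
2. **Adjacency.** $a_{ij} = |r_{ij}|^\beta$, an *unsigned* network: the
   analysis cares about co-regulation magnitude, and anti-correlated genes
   belong to the same program (their membership kME is simply negative).
   Signed and signed-hybrid variants are deliberately out of scope.
   The diagonal is set to 0 so connectivity $k_i = \sum_{j \ne i} a_{ij}$
   and the shared-neighbour sums exclude self-connections; the
   topological-overlap diagonal is reported as 1 by convention.
3. **Topological overlap.**
   $t_{ij} = \dfrac{l_{ij} + a_{ij}}{\min(k_i,k_j) + 1 - a_{ij}}$, with
   $l_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$. With a zero diagonal this is
   exactly `(A %*% A + A) / (pmin.outer(k,k) + 1 - A)`; the matrix form is
   checked against a triple-loop oracle to $10^{-10}$ in the test suite.
   $1 - t_{ij}$ is the clustering dissimilarity.

**Choosing $\beta$.** The default is the conventional unsigned choice
$\beta = 6$; `power = "auto"` applies the scale-free topology criterion:
the smallest candidate (1–20) whose connectivity distribution reaches
$R^2 \ge 0.85$ in a log–log regression. The fit bins $k$ into 10
equal-count (quantile) bins — robust to the heavy tail a scale-free
distribution must have — and regresses $\log_{10}$ bin *density*
(count / (total × bin width)) on $\log_{10}$ mean $k$. With equal-count
bins the raw frequency is constant by construction, so density is the
quantity that carries the distribution's shape. $R^2$ is forced to 0 when
the slope is non-negative: "scale-free" requires decay, and without the
sign guard a rising line could score well. If no candidate reaches the
target, the best-fitting power is used with a warning rather than an
error, since a forced choice with a diagnostic beats none.

## Module detection

Modules are branches of the average-linkage (UPGMA) dendrogram of
$1 - \mathrm{TOM}$, extracted with a dynamic tree cut:

- merges above `cut_height` (default 0.995) are never binding — a static
  cut;
- below it, a branch is split when **both** sub-branches contain at least
  `min_module_size` genes (default 30, the reference default for this
  analysis family) **and** the height gap between the merge and its taller
  sub-branch exceeds a sensitivity threshold set by `deep_split` (0–4,
  default 2, mapping to gaps of 0.40/0.25/0.15/0.08/0.03 × `cut_height`).
  The gap condition prevents shattering a homogeneous module whose internal
  merges climb gradually, while still separating genuinely distinct
  programs glued together just below the cut height;
- clusters below the size floor, and leaves stranded by splits, are
  `"unassigned"`.

This cut is this package's own algorithm in the spirit of dynamic
tree cutting; it does not promise label-identical output with other
implementations — the accuracy contract is planted-module recovery
(adjusted Rand index against ground truth), which the acceptance suite
checks. Module labels follow decreasing size through the conventional
colour sequence (largest = turquoise); colours are presentation, not
semantics.

**Eigengenes.** A module's eigengene is the first right singular vector of
its row-standardized block — the unit-norm sample profile explaining the
largest share of variance (`variance_explained` = first squared singular
value over the total, checked against a full decomposition to $10^{-10}$).
Sign is arbitrary in an SVD, so it is oriented toward the mean
standardized expression, with an exact tie broken toward the first gene —
a pure reproducibility device.

**kME refinement.** After the cut, each gene moves to the module whose
eigengene it matches best, iterating assignment → eigengene recomputation
to a fixed point (cap 10 iterations; clean planted data reaches it in ≤ 3).
Absolute kME is used both for the argmax and for the `kme_min = 0.3`
threshold, consistent with the unsigned adjacency: a gene with kME −0.95
is a strong member, and hubs with negative kME are legitimate calls. Genes
below 0.3 against every eigengene become unassigned. Each iteration's
objective (sum of winning |kME|) is monitored and never decreases on the
test fixtures. Modules reduced below two genes are dropped, since an
eigengene of one gene is meaningless. One consequence worth knowing: with
24 samples, a noise gene's |kME| exceeds 0.3 against *some* eigengene
fairly often, so detected modules absorb a fringe of background genes;
recovery is therefore scored on the genes with true module labels.

## Module preservation

Preservation of a module (defined in one network, evaluated in another)
uses one representative from each statistic family:

- **density**: mean intramodular adjacency in the evaluation network —
  are the module's genes still strongly interconnected?
- **connectivity**: Pearson correlation between the module's intramodular
  connectivity vectors (row sums of the module submatrix) in the two
  networks — is the *pattern* of hubness preserved?

Each observed statistic is standardized against a permutation null built
from `n_perm` (default 200, minimum 50) random gene sets of the same size
drawn from outside the module, and
$Z_{\mathrm{summary}} = (Z_{\mathrm{density}} + Z_{\mathrm{connectivity}})/2$.
One statistic per family keeps the permutation cost desk-scale while
retaining both evidence types the composite is meant to balance.
Thresholds: strong evidence above 10, none below 2, weak between; the
boundary values 2 and 10 themselves classify as *weak*, closing the
half-open intervals the strict inequalities would leave. A module with
$Z_{\mathrm{summary}} < 2$ is flagged `specific` — present where it was
detected, absent where it was tested, the signature of a
condition-specific program. Degenerate nulls (zero spread, e.g. a constant
adjacency) yield ±Inf sentinels with a warning instead of `NaN`; a
zero-variance connectivity vector yields statistic 0 with a warning.

Under the null — random gene sets in networks without planted structure —
both Z statistics should be approximately standard normal; the acceptance
suite verifies mean within ±0.3 and SD within [0.7, 1.3] over 200 sets.
Note that in a network *with* real modules, random sets overlapping them
are not null draws, and their Z spread legitimately exceeds 1.

**Direction.** `module_preservation(ref_network, test_network, partition)`
takes the partition from `ref_network` and evaluates in `test_network`.
The pipeline detects modules in the test condition and evaluates them in
the reference condition (modules found after perturbation, tested in
controls); the reverse direction is a matter of argument order.

**Stage-wise preservation** fixes the modules from the full test-condition
network and re-evaluates them against networks rebuilt from each stage's
samples. Stages follow the canonical three-phase division of liver
regeneration — priming 2–6 h, proliferative 6–72 h, termination 72–168 h —
with boundary time points assigned to the earlier stage (6 h → priming,
72 h → proliferative), since the printed intervals overlap and a
deterministic rule is needed; both boundaries are arguments of
`assign_stage()`. Stages with fewer than 4 samples are skipped with a
warning: with the default design the termination stage has a single time
point (three replicates) and cannot support a correlation network. A
caveat inherent to the approach: preservation within a stage requires the
module's temporal program to *vary* within that stage's time points, so
even a globally planted module can score low in a stage where its profile
happens to be flat.

## Gene significance and hubs

Gene significance is the absolute two-sample t statistic between
conditions. The default is Welch (unequal variances), the safer reading of
an unqualified "t-test"; a pooled-variance variant is available via
`moderated = TRUE` but off by default. The same Welch machinery drives the
`filter_by_ttest()` gene filter (default α = 0.05, no multiple-testing
correction — the filter reproduces a raw-threshold selection step, not an
inference), whose type-I calibration on pure noise is part of the
acceptance suite.

The hub of a module is its maximal-|kME| gene — membership primarily,
gene significance only as a tie-break, then gene ID. kME and intramodular
connectivity are nearly interchangeable rankings; fixing one rule makes
calls deterministic. Simulations in the test suite show the called hub's
planted loading reliably sits in the top quartile of its module; the top
decile is *not* a reliable guarantee at 24 samples, because
$\mathrm{cor}(u)$ flattens as the loading $u \to 1$ and sampling noise
dominates the ranking among the strongest members.

Edge export applies a strict `> 0.3` connection-strength threshold by
default and writes Cytoscape-style edge and node tables (node attribute:
module and whole-network connectivity).

## The synthetic-data generator

The generator emulates the structure of a two-condition regeneration
time-course study: eight sampling times (2, 6, 12, 24, 30, 36, 72, 168 h)
with three replicates each per condition, expression on a mean-zero
log-ratio scale (ratios to a time-zero control), planted modules and
i.i.d. Gaussian background. The replicate count is a parameter rather than
a constant because published sample tallies of such designs are ambiguous
about the replicate structure.

Each module follows a latent single-factor model,
$x_i = u_i \cdot e + \varepsilon$: a smooth temporal eigenprofile $e$
(random quadratic-plus-Fourier function over rank-spaced time, standardized;
rank spacing because the design is dense early and sparse late), loadings
$u_i$ uniform in the spec'd membership range, and noise with
`noise_sd = 0.4` by default — chosen so that default-strength modules are
clearly detectable yet far from trivial (within-module correlations well
below 1, background |cor| ≈ 0.17 at 24 samples). The single-factor form
matches the analysis' own summary of a module by its first singular
vector, which is what makes planted truth a fair oracle.

Two design choices deserve emphasis:

- **Orthogonal programs.** Successive module eigenprofiles are
  Gram–Schmidt-orthogonalized within a study. Independent random smooth
  profiles over only eight time points are frequently near-collinear
  (|cor| > 0.9), which would make "distinct" planted modules genuinely
  indistinguishable and the ground truth ill-defined. Orthogonalization
  encodes the intended semantics: distinct modules are distinct temporal
  programs. The number of modules is bounded by the time grid's dimension;
  exceeding it raises an error rather than silently planting duplicates.
- **Preservation classes as loading transforms.** In the reference
  condition, preserved modules re-use the same eigenprofile and loadings
  (independent noise), weak modules halve the loadings — one monotone knob
  linking loading strength to preservation evidence — and test-specific
  modules are replaced by pure noise. Halved loadings land modules near
  the weak/none boundary at the default design; that is a property of the
  evidence scale, not a bug.

Everything is a deterministic function of the configuration, including its
seed; identical configurations produce bit-identical studies, and the full
pipeline is byte-reproducible.

What the generator does **not** emulate: probe-level structure and
normalization artifacts, batch effects, heavy-tailed or count-distributed
noise, correlated backgrounds, overlapping module membership, and
module-size or hub-degree distributions of real transcriptomes. Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration under the stated model, not robustness to the full messiness
of microarray data; the probe-collapse and ratio-to-control steps exist
for real inputs but are exercised on constructed fixtures.

## Numerical and validation choices

- Problem sizes in the tests: recovery uses five modules of 30–60 genes
  plus 200 background genes and 24 samples per condition over 30 seeds;
  preservation discrimination uses 40/35-gene modules with 120 background
  genes and 200 permutations over 30 seeds; null calibration uses 200
  random 20-gene sets in 220-gene noise networks. These sizes give stable
  medians and rates while keeping the default suite fast.
- Correlations are clipped to [−1, 1] after `cor()` to absorb floating
  drift; TOM is clipped at 1 for the same reason.
- Exact-equality contracts (TOM of a clique is 1, of an empty graph the
  identity; rank-1 variance-explained is 1) are asserted at $10^{-12}$ or
  exactly; oracle comparisons at $10^{-10}$.
- Ratios are log2-transformed by default before correlation
  (`log2_transform = FALSE` to disable): correlation networks on raw
  ratios are skewed by scale.
- Ties in `select_most_connected()` break by descending connectivity then
  gene ID; probe collapse orders genes lexicographically — determinism
  over convention.

## Known limitations

- Dense matrix algebra only: intended for desk-scale analyses (up to a few
  thousand genes after filtering), not genome-scale blockwise processing.
- No merging of modules with highly correlated eigengenes; if the cut
  oversplits a program, the pieces stay separate.
- One density and one connectivity statistic rather than the full
  composite families; no medianRank or quality statistics.
- The dynamic tree cut is behaviourally, not bit-for-bit, comparable with
  other implementations.
- The t-test gene filter assumes roughly normal per-gene noise; its
  calibration is verified under that assumption only.
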