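---
title: "Network-based nomination of radioresistance driver genes: models and methods"
author: "radregnet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based nomination of radioresistance driver genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radregnet)
```

## The problem

Radioresistant cancer cell lines derived by fractionated irradiation carry
broad chromosomal deletions and amplifications affecting thousands of
genes, and only a handful of replicates exist per condition. Per-gene
statistics cannot separate the few driver alterations from the mass of
passengers. radregnet implements a network-based alternative: candidate
alterations are defined jointly from copy number and expression, and each
candidate is scored by how strongly its expression alteration propagates
through a gene regulatory network onto established radioresistance marker
genes, judged against a degree-preserving permutation null. Surviving
candidates are evaluated as relapse markers in irradiated patients.

## Models, stage by stage

### Gene-level copy-number calls

Segmented aCGH profiles (SEG records, 1-based inclusive coordinates) are
mapped to genes by genomic overlap. A gene spanning several segments
receives the overlap-length-weighted mean of their log2-ratios — a
deterministic rule for breakpoint genes. States are trinarized at an
absolute log2-ratio cutoff of 0.1 with strict inequalities: values exactly
at the cutoff stay "unchanged". The cutoff is deliberately permissive; it
only feeds the candidate filter and does not enter network inference.
Internally coordinates are converted to GenomicRanges objects; the SEG
interface stays 1-based inclusive.

### Differential expression by a three-state Gaussian HMM

Replicate log2 intensity matrices are quantile normalized (all replicates
of both conditions together), and the per-gene mean difference
(resistant − sensitive) is arranged along the chromosomal gene order, one
sequence per chromosome. A three-state hidden Markov model (under,
unchanged, over) with Gaussian emissions is trained by Baum–Welch on the
pooled sequences with one shared parameter set: dependence along a
chromosome is positional and cannot span chromosome ends. Initialization:
state means −1.25 / 0 / +1.25, state-specific free variances at 0.5²,
sticky transitions (0.9 self), uniform initial distribution. The mean of
the middle state is left free and states are relabeled by sorted means
after training; variances are floored at 1e−4 on collapse. Genes are
assigned states by posterior decoding, with exact posterior ties broken
toward "unchanged". The log-likelihood trace is retained and asserted
non-decreasing in the test suite.

An HMM borrows strength from chromosomal neighbors, which matters because
replicate contrasts at n = 3 vs 3 are underpowered for per-gene t-tests.

### Direct candidates

A gene is a direct driver candidate when both layers agree in direction:
increased copy number with overexpression ("up") or reduced copy number
with underexpression ("down"). Opposite-direction genes are counted and
reported but excluded.

### Regulatory network inference

For each gene, its expression across an independent tumor cohort is
modeled as a sparse linear combination of its own copy number and the
expression of all other genes. The lasso is tuned by 10-fold
cross-validation at minimum CV error (favoring recall over parsimony);
each selected predictor receives a significance p-value from the
covariance test on the lasso path, and expression predictors with
p < 1e−3 (configurable) are kept. Predictors are standardized and the
copy-number column is penalized like any other. Same-chromosome predictors
within 50 positions of the target in the chromosomal gene order are pruned
as likely copy-number co-passengers ("local regulators"); the pruning
follows the significance test. Surviving predictors define signed directed
edges (activator/inhibitor by coefficient sign).

Implementation notes that matter for correctness: the covariance-test
statistic compares lasso fits at consecutive entry knots on a dense
lambda grid; variables entering at the same grid knot are placed together
in the restricted set so none is credited the whole group's improvement,
and the solver tolerance is tightened to 1e−9 because solver noise larger
than the residual variance inflates the statistic. The residual variance
is estimated by OLS on the full design when n comfortably exceeds p, else
from the cross-validated lasso fit with a degrees-of-freedom correction.
Per-target fits share a deterministic fold assignment derived from one
seed, so results are independent of execution order.

A structural caveat, measured on synthetic ground truth: per-gene
regression identifies each gene's Markov blanket, not its parent set. A
regulated gene ("child") is marginally highly correlated with its
regulator, enters the lasso path early, and its entry improvement is
genuine signal — so reversed edges receive honestly tiny p-values and no
significance threshold removes them. On the strong-signal preset the
directed recall is ~0.9 with perfect sign agreement, while directed
precision plateaus near 0.7; the false edges are dominated by reversals
of true edges. For propagation this is benign (blanket edges carry real
predictive signal), but the network should not be read as causally
oriented edge by edge.

### Predictive-power node weights

Each gene's model is applied to a held-out cohort split (default 20%),
and the Pearson correlation between predicted and observed expression is
the gene's weight. Genes without a model get weight 0.

### Network propagation and the permutation null

The impact of candidate *a* on gene *b* is
|signal(a)| · |Σ walks a→…→b, length ≤ 5, Π (edge coefficient ×
node weight)|, computed by iterated products of the weighted adjacency
matrix. The source signal is the candidate's observed expression
log2-ratio in the cell-line contrast (candidates are defined by their
expression change, which is the propagated quantity). Node weights are the
predictive-power correlations clipped below at 0, applied at every node a
walk enters: unpredictable genes silence walks through them. "All paths"
is unbounded in cyclic graphs; truncation at length 5 is the standard
resolution, and the max-norm of the last retained term is reported as a
convergence diagnostic (walk sums decay geometrically when the weighted
spectral radius is below 1). Self-impacts are excluded; the signed walk
sum is reduced to a magnitude at the end.

Each candidate's mean absolute impact over the marker set is compared with
the same quantity under 10 degree-preserving network permutations
(repeated pairwise regulator swaps between targets, 10× edge-count
attempts, rejecting self-loops and duplicates; coefficients travel with
the moved predictor slot; the 10 permuted networks are shared across
candidates). A one-sided one-sample t-test on the 10 differences per
candidate, Benjamini–Hochberg correction over candidates, and q < 0.01
define the significant driver set. Zero-variance differences are
degenerate: p is 0 if all are positive, else 1, with a warning.

### Transfer to patient relapse data

Candidates are first filtered for consistent behavior: among irradiated
patients who relapsed, the Pearson correlation (rank correlation
available) between pre-treatment expression and months-to-relapse must be
negative for "up" candidates and positive for "down" candidates, with
strict inequalities. Each surviving candidate is then dichotomized at the
expression cutoff minimizing the asymptotic log-rank p-value, under the
hard constraint of at least 8 patients per group; candidate cutoffs are
midpoints between consecutive sorted unique expression values, the low
group is "expression ≤ cutoff", and p-value ties resolve to the smaller
cutoff. No selection-bias correction is applied to the reported p-values
(the optimal-cutoff selection is itself part of the procedure being
replicated); the exact permutational log-rank p-value is computed for
selected markers as a guard against small-sample optimism — exhaustively
over all group-size-preserving label assignments when their number is at
most 1e7, otherwise by at least 1e6 seeded Monte-Carlo permutations with
the mode reported. Cohorts where a gene allows no feasible cutoff are
reported infeasible rather than given p = 1. FDR is estimated twice:
Benjamini–Hochberg (conservative) and a Storey-type estimate scaling BH
by the estimated null proportion at λ = 0.5 (liberal). Cox
proportional-hazards models with and without the candidate group term
quantify the candidate's contribution beyond age, T-stage, Gleason score
and PSA.

## The synthetic-data generator

Every input has a synthetic counterpart with recoverable truth:

* **Network**: genes placed on chromosomes with strictly increasing
  coordinates; a requested fraction of regulator→target coefficients drawn
  nonzero (uniform magnitudes, configurable inhibitor fraction); the
  matrix rescaled to spectral radius below 1. Expression solves the
  simultaneous system x = (I − Wᵀ)⁻¹(β⊙c + ε) — cycles permitted, matching
  the simultaneous linear model rather than forcing a DAG.
* **Cohort**: per patient, contiguous gene segments on each chromosome
  carry Gaussian copy-number shifts (log2-ratio scale throughout);
  expression follows the linear model with per-gene Gaussian noise.
* **Cell-line pair**: broad multi-gene and focal single-gene segments are
  planted, each driver inside a focal alteration whose sign matches its
  direction; SEG records tile every chromosome with boundaries at
  midpoints between genes, so gene-level mapping recovers the planted
  values exactly. Driver expression shifts are pinned at the configured
  effect (default 2.85, the scale of strong validated markers in real
  resistant lines) by a fixed-point adjustment of the driver inputs —
  network feedback would otherwise cancel some planted shifts — and
  propagate downstream through the network. Replicates (3 vs 3) add
  Gaussian noise around base intensities drawn uniformly on 4–12 (log2
  scale): a wide base spread keeps shifted genes interior to the intensity
  distribution, where quantile normalization of a small panel is
  well-behaved.
* **Relapse**: exponential proportional hazards with log-hazard linear in
  standardized driver expression (sign tied to driver direction);
  administrative censoring at a single follow-up horizon hitting the
  requested censored fraction; clinical covariates simulated independently
  of the drivers so parameter-recovery tests are clean (confounding can be
  added by the user).

What the generator does **not** emulate: probe-level microarray structure,
batch effects, realistic covariate joint distributions, nonlinear
regulation, and measurement-platform differences between cohort and cell
lines. Passing tests demonstrate internal correctness and recoverability
under the linear model, not performance on real arrays.

### Study presets and problem sizes

`syntheticStudy()` fixes the validation conditions:

* `"strong"` (recovery benchmarks): 100 genes / 10 chromosomes, average
  out-degree ≈ 2, edge weights 0.4–0.9 against residual noise sd 0.1,
  CNA-rich cohort of 400 patients (per-chromosome segment probability 0.8,
  shift sd 0.8, segments of 2–6 genes).
* `"full"` (end-to-end): the same conditions at 300 genes — enough genes
  for stable quantile normalization and HMM estimation — with drivers
  whose hazard effect is 2 per expression SD.
* `"desk"`: 300 genes / 300 patients at the generator defaults.

Two sizing choices deserve their rationale. First, edge density and edge
strength are coupled: the spectral-radius rescale divides all weights by
roughly the mean out-degree, so the presets keep the average out-degree
near 2 to keep individual edges strong — raising density without raising
gene count would silently weaken every edge. Second, planted drivers are
sampled among genes with a direct regulatory target at least as strong as
the median edge, and each driver's strongest target is planted as a
marker: on desk-scale graphs the degree-preserving null reaches most of
the genome within five steps, so only candidates with strong short paths
to markers are distinguishable from that null — which is exactly the
phenomenon the planted truth is meant to carry.

## Numerical and design choices

* Quantile normalization delegates to limma; missing values are imputed by
  row medians beforehand (an explicit error if not).
* Overlap enrichment uses the exact hypergeometric tail, one-sided by
  default — every use in the pipeline is an over-representation test; the
  two-sided Fisher form is available.
* The exact log-rank statistic is the standard chi-square form, evaluated
  vectorized over label assignments (verified against survival::survdiff);
  assignments with zero log-rank variance contribute statistic 0.
* The "local gene cutoff of 50" is interpreted as gene-index distance in
  chromosomal order on the same chromosome (a per-gene ordered annotation
  makes this well-defined); a physical-distance variant would need
  platform-specific tuning. Predictors exactly at distance 50 are removed.
* λ at minimum CV error rather than the 1-SE rule: the target network is
  deliberately dense, favoring recall.
* The pipeline fans one global seed out to per-stage seeds via a fixed
  affine map, so stages are independently reproducible and the whole run
  is deterministic under one seed.
* Pipeline problem sizes in the shipped validation: recovery benchmarks at
  100 genes × 400 patients; the end-to-end run at 300 genes × 400
  patients. These are the package's chosen desk-scale study conditions;
  cohort-scale fits (tens of thousands of genes) use the same code but are
  expected to run for hours.

## Known limitations

* Directed edge orientation is not identified (Markov-blanket ceiling
  discussed above); precision against a directed ground truth plateaus
  near 0.7 even at strong signal.
* The covariance test's Exp(1) null is asymptotic; at very small n or
  near-deterministic expression its calibration degrades.
* Optimal-cutoff log-rank p-values are reported without selection-bias
  correction, mirroring the replicated procedure; the exact permutational
  p-value guards the final marker calls but is itself conditional on the
  selected cutoff.
* Quantile normalization of very small gene panels (≲100 genes) distorts
  extreme quantiles when a large fraction of genes is truly shifted; the
  end-to-end preset therefore uses 300 genes.
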