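# radregnet

Network-based nomination of radioresistance driver genes from paired
radioresistant/radiosensitive omics profiles.

## The problem

Cancer cell lines that survive fractionated irradiation accumulate broad
chromosomal deletions and amplifications: thousands of genes change copy
number, hundreds change expression, and with three replicates per
condition no per-gene statistic separates the few drivers from the mass of
passengers. `radregnet` implements a network-based strategy for this
setting, aimed at computational biologists analyzing paired
resistant/parental designs:

1. **Copy-number calls** — segmented aCGH profiles (SEG) are mapped to
   genes by overlap-length-weighted averaging and trinarized at
   |log2-ratio| > 0.1 (strict).
2. **Differential expression** — quantile-normalized replicate contrasts
   are arranged along the chromosomal gene order and segmented by a
   three-state Gaussian hidden Markov model (under / unchanged / over,
   initial means −1.25 / 0 / +1.25), decoded by posterior state
   probabilities.
3. **Direct candidates** — genes whose copy-number and expression calls
   agree in direction.
4. **Regulatory network** — from an independent tumor cohort, each gene's
   expression x_g is modeled as a sparse linear combination of its own
   copy number c_g and all other genes' expression:
   x_g = β_g c_g + Σ_{r≠g} w_{rg} x_r + ε, fitted by cross-validated
   lasso with a covariance-test significance filter and local-regulator
   pruning; signed edges (w_{rg} ≷ 0) form a directed network.
5. **Network propagation** — each candidate's expression alteration is
   propagated along all directed walks up to length 5
   (impact(a→b) = |signal(a)| · |Σ_walks Π edge coefficient × node
   weight|), scored as the mean impact on known radioresistance marker
   genes and tested against 10 degree-preserving network permutations
   (one-sided t-test, Benjamini–Hochberg, q < 0.01).
6. **Patient transfer** — significant drivers with sign-consistent
   expression–relapse correlations in irradiated patients are evaluated as
   relapse markers by optimal-cutoff Kaplan–Meier splitting under a
   ≥ 8-patients-per-group constraint, with exact permutational log-rank
   p-values, conservative/liberal FDR estimates and covariate-adjusted Cox
   models.

A synthetic-data generator (`generateGroundTruthNetwork()`,
`simulatePatientCohort()`, `simulateCellLinePair()`,
`simulateRelapseTimes()`, bundled presets in `syntheticStudy()`) supplies
every input with recoverable ground truth, so the full pipeline can be
exercised and validated without any external download.

## Worked example

```r
library(radregnet)

## overlap of reduced-copy-number genes between two resistant lines,
## from the published 2x2 counts (one-sided hypergeometric):
overlapFisherFromCounts(389, 6109, 765, 24625)
#> [1] 7.160817e-56

## a full synthetic study with planted truth:
st   <- syntheticStudy("full", seed = 1)     # network + cohort + record
pair <- simulateCellLinePair(st$truth, st$record, seed = 2)
clin <- simulateRelapseTimes(st$cohort$expression, st$record, seed = 3)

cfg <- pipelineConfig(
  annotation         = geneAnnotation(st$truth),
  segments           = pair$segments,
  resistant          = pair$resistant,
  sensitive          = pair$sensitive,
  cohort_expression  = st$cohort$expression,
  cohort_copy_number = st$cohort$copy_number,
  clinical           = clin,
  marker_genes       = markerGenes(st$record),
  seed               = 4)
res <- runPipeline(cfg)
#> cna: 37 segments -> 300 genes (52 reduced, 12 increased)
#> de: 300 genes (24 under, 101 over); HMM iterations=81
#> candidates: 23 same-direction (3 opposite-direction)
#> network: inferred on 320 patients, 775 edges (26 inhibitor); mean holdout correlation 0.936
#> impact: 3 candidates with q < 0.01 against 10 permuted networks
#> transfer: 3 consistent candidates, 3 markers at approximate log-rank p < 0.05

sel <- res$marker_table$gene_id[res$marker_table$selected]
mean(trueDrivers(st$record)$gene_id %in% sel)
#> [1] 0.75
```

Reading the output: of 300 genes, 64 carry a copy-number call and 125 a
differential-expression call; 23 agree in direction and become direct
candidates. The inferred cohort network (775 signed edges) propagates each
candidate's expression alteration onto the 4 planted marker genes; 3
candidates beat the degree-preserving permutation null at q < 0.01, all
of them survive the consistency filter and split the irradiated patients
into early/late relapse groups at log-rank p < 0.05 — recovering 3 of the
4 planted drivers (the fourth's marker edge falls below the network's
detection limit in this draw).

Every run is reproducible: the same configuration and seed give
byte-identical outputs, and `runPipeline(cfg, out_dir = ...)` writes all
result tables, the network and a parameter-echoing run log with the
package's own readers/writers (`readSeg()`, `readRegulatoryNetwork()`,
...). A thin command-line driver is installed at
`system.file("scripts", "radregnet", package = "radregnet")` with
`simulate` and `run-all` subcommands.

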