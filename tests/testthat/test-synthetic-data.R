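test_that("generated networks honor density, sign mix and solvability", {
  net <- generateGroundTruthNetwork(100, density = 0.02,
                                    frac_inhibitor = 0.03, seed = 1)
  W <- edgeWeights(net)
  m <- sum(W != 0)
  requested <- 0.02 * 100 * 99
  expect_lt(abs(m - requested) / requested, 0.1)
  expect_equal(sum(W < 0), round(0.03 * m))
  expect_true(all(diag(W) == 0))
  expect_lt(max(Mod(eigen(W, only.values = TRUE)$values)), 1)

  ann <- geneAnnotation(net)
  for (ch in unique(ann$chrom)) {
    s <- ann$start[ann$chrom == ch]
    expect_true(all(diff(s) > 0))
  }

  all_pos <- generateGroundTruthNetwork(50, density = 0.05,
                                        frac_inhibitor = 0, seed = 2)
  expect_true(all(edgeWeights(all_pos) >= 0))

  again <- generateGroundTruthNetwork(100, density = 0.02,
                                      frac_inhibitor = 0.03, seed = 1)
  expect_identical(edgeWeights(again), W)

  expect_error(generateGroundTruthNetwork(10, density = 0.0001),
               "infeasible")
  expect_error(generateGroundTruthNetwork(100, density = 0.5), "density")
  expect_error(generateGroundTruthNetwork(5, density = 0.1), "n_genes")
})

test_that("cohort expression solves the linear dosage model exactly when noise-free", {
  # W = 0, noise 0: expression must equal beta * copy number exactly
  truth <- makeTinyTruth(n = 12, noise_sd = 0)
  truth@cn_coefficients[] <- seq(0.5, 1.6, length.out = 12)
  coh <- simulatePatientCohort(truth, n_patients = 20, cna_sd = 0.5,
                               seed = 3)
  expect_equal(coh$expression,
               truth@cn_coefficients * coh$copy_number,
               tolerance = 1e-12)
})

test_that("a chain edge propagates copy-number perturbations analytically", {
  # a -> b with weight w: perturbing c_a by delta shifts x_b by w*beta_a*delta
  n <- 12
  W <- matrix(0, n, n)
  w <- 0.6
  W[1, 2] <- w
  truth <- makeTinyTruth(n = n, W = W, noise_sd = 0)
  beta <- cnCoefficients(truth)
  g <- networkGenes(truth)
  a <- g[1]; b <- g[2]
  delta <- 0.8
  c0 <- matrix(0, n, 1, dimnames = list(g, "p1"))
  c1 <- c0; c1[a, 1] <- delta
  x0 <- radregnet:::solveExpression(truth, beta * c0)
  x1 <- radregnet:::solveExpression(truth, beta * c1)
  # oracle: analytic solve of the 2-gene linear system
  expect_equal(x1[b, 1] - x0[b, 1], w * beta[[a]] * delta,
               tolerance = 1e-12)
  expect_equal(x1[a, 1] - x0[a, 1], beta[[a]] * delta, tolerance = 1e-12)
})

test_that("cohort simulation is reproducible and refuses unsolvable systems", {
  net <- generateGroundTruthNetwork(50, density = 0.04, seed = 5)
  c1 <- simulatePatientCohort(net, n_patients = 30, seed = 7)
  c2 <- simulatePatientCohort(net, n_patients = 30, seed = 7)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$copy_number, c2$copy_number)
  expect_true(all(is.finite(c1$expression)))

  bad <- net
  bad@W <- bad@W * (1.2 / radregnet:::spectralRadius(bad@W))
  expect_error(radregnet:::solveExpression(bad, cbind(rep(0, 50))),
               "spectral radius")
})

test_that("cell-line pair plants recoverable alterations", {
  net <- generateGroundTruthNetwork(60, density = 0.03, seed = 11)
  rec <- makeTruthRecord(net, n_drivers = 3, n_markers = 3, seed = 12)
  pair <- simulateCellLinePair(net, rec, broad_frac = 0.2,
                               focal_count = 6, seed = 13)
  ann <- geneAnnotation(net)

  # SEG -> gene mapping recovers the planted per-gene values exactly
  mapped <- mapSegmentsToGenes(pair$segments, ann)
  expect_equal(mapped, pair$cn_genes, tolerance = 1e-12)
  calls <- callCopyNumberStates(mapped)
  expect_setequal(calls$gene_id[calls$state != "unchanged"],
                  pair$altered_genes)

  # drivers sit in altered segments with sign matching their direction
  drv <- trueDrivers(rec)
  cn_drv <- pair$cn_genes[drv$gene_id]
  expect_true(all(abs(cn_drv) > 0.1))
  expect_equal(unname(sign(cn_drv)),
               ifelse(drv$direction == "up", 1, -1))
  # planted driver expression shifts equal the configured effect
  expect_equal(unname(pair$expression_shift[drv$gene_id]),
               ifelse(drv$direction == "up", 1, -1) * 2.85,
               tolerance = 1e-8)

  # seeded rerun is byte-identical
  pair2 <- simulateCellLinePair(net, rec, broad_frac = 0.2,
                                focal_count = 6, seed = 13)
  expect_identical(pair$segments, pair2$segments)
  expect_identical(pair$resistant, pair2$resistant)

  expect_error(simulateCellLinePair(net, rec, focal_count = 1000),
               "exceeds")
  expect_error(simulateCellLinePair(net, rec, focal_count = 1),
               "drivers")
})

test_that("a null cell-line pair has no alterations at all", {
  net <- generateGroundTruthNetwork(40, density = 0.03, seed = 21)
  rec0 <- makeTruthRecord(net, n_drivers = 0, n_markers = 2, seed = 22)
  pair <- simulateCellLinePair(net, rec0, broad_frac = 0,
                               focal_count = 0, seed = 23)
  expect_true(all(pair$segments$log2_ratio == 0))
  mapped <- mapSegmentsToGenes(pair$segments, geneAnnotation(net))
  calls <- callCopyNumberStates(mapped)
  expect_equal(sum(calls$state != "unchanged"), 0)
})

test_that("relapse times follow the planted hazard structure", {
  net <- generateGroundTruthNetwork(40, density = 0.03, seed = 31)
  rec <- makeTruthRecord(net, n_drivers = 2, n_markers = 2,
                         hazard_effect = 1.5, seed = 32)
  coh <- simulatePatientCohort(net, n_patients = 200, seed = 33)

  # null case: no hazard link -> no association with event times
  rec0 <- rec
  rec0@hazard_coefficients[] <- 0
  clin0 <- simulateRelapseTimes(coh$expression, rec0, censor_frac = 0,
                                seed = 34)
  expect_true(all(clin0$event))
  for (g in trueDrivers(rec)$gene_id) {
    tau <- cor(coh$expression[g, ], clin0$months, method = "kendall")
    expect_lt(abs(tau), 0.15)
  }

  # positive hazard coefficient shortens relapse above the median
  rec_up <- rec
  rec_up@drivers$direction <- c("up", "up")
  rec_up@hazard_coefficients[] <- 1.5
  clin <- simulateRelapseTimes(coh$expression, rec_up, censor_frac = 0,
                               seed = 35)
  d <- trueDrivers(rec_up)$gene_id[1]
  hi <- coh$expression[d, ] > median(coh$expression[d, ])
  expect_lt(median(clin$months[hi]), median(clin$months[!hi]))

  # administrative censoring hits the requested fraction
  clin_c <- simulateRelapseTimes(coh$expression, rec, censor_frac = 0.6,
                                 seed = 36)
  expect_equal(mean(!clin_c$event), 0.6, tolerance = 0.05)
  expect_error(simulateRelapseTimes(coh$expression, rec,
                                    censor_frac = 1), "censor_frac")
})

test_that("truth records are valid and seeded", {
  net <- generateGroundTruthNetwork(60, density = 0.03, seed = 41)
  rec <- makeTruthRecord(net, n_drivers = 3, n_markers = 4, seed = 42)
  drv <- trueDrivers(rec)
  expect_equal(nrow(drv), 3)
  expect_length(markerGenes(rec), 4)
  expect_length(intersect(drv$gene_id, markerGenes(rec)), 0)
  # every driver directly regulates at least one marker
  W <- edgeWeights(net)
  for (d in drv$gene_id)
    expect_true(any(W[d, markerGenes(rec)] != 0))
  # hazard sign matches direction
  hz <- rec@hazard_coefficients
  expect_equal(unname(sign(hz)), ifelse(drv$direction == "up", 1, -1))
  expect_identical(makeTruthRecord(net, n_drivers = 3, n_markers = 4,
                                   seed = 42)@drivers, drv)
})
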