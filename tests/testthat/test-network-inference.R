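test_that("expression filtering drops silent and constant genes", {
  m <- rbind(silent = rep(0, 10),
             boundary = rep(1, 10),      # mean exactly 1 but constant
             low = rep(0.5, 10) + c(0.1, rep(0, 9)),
             kept = 2 + rexp(10))
  out <- filterExpressedGenes(m, min_mean = 1)
  expect_false("silent" %in% out)
  expect_false("boundary" %in% out)  # zero variance
  expect_false("low" %in% out)       # mean below 1
  expect_true("kept" %in% out)

  # boundary mean exactly 1 with variation is retained (>= rule)
  m2 <- rbind(edge = c(0.5, 1.5, 1, 1, 1, 1, 1, 1, 1, 1))
  expect_true("edge" %in% filterExpressedGenes(m2, min_mean = 1))

  # synthetic cohort with 10% silent genes: exactly those dropped
  set.seed(8)
  mm <- matrix(rexp(50 * 20, rate = 0.2), 50, 20,
               dimnames = list(paste0("g", 1:50), NULL))
  mm[1:5, ] <- 0
  expect_setequal(filterExpressedGenes(mm, 1), paste0("g", 6:50))

  expect_error(filterExpressedGenes(-m), "nonnegative")
})

test_that("a strong pairwise dependence is selected with a calibrated coefficient", {
  set.seed(21)
  n <- 400
  genes <- paste0("g", sprintf("%02d", 1:12))
  expr <- matrix(rnorm(12 * n), 12, n, dimnames = list(genes, NULL))
  expr["g02", ] <- 0.8 * expr["g01", ] + rnorm(n, 0, 0.2)
  cn <- matrix(0, 12, n, dimnames = dimnames(expr))
  m <- fitGeneModel("g02", expr, cn)
  expect_true("g01" %in% m$predictors$regulator)
  co <- m$predictors$coefficient[m$predictors$regulator == "g01"]
  expect_gt(co, 0.6); expect_lt(co, 1.0)
  expect_lt(m$predictors$p_value[m$predictors$regulator == "g01"], 1e-3)
})

test_that("pure-noise targets yield empty predictor lists", {
  n <- 400
  genes <- paste0("g", sprintf("%02d", 1:15))
  empty <- vapply(1:5, function(r) {
    set.seed(100 + r)
    expr <- matrix(rnorm(15 * n), 15, n, dimnames = list(genes, NULL))
    cn <- matrix(rnorm(15 * n, 0, 0.3), 15, n, dimnames = list(genes, NULL))
    nrow(fitGeneModel("g01", expr, cn)$predictors) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.8)
})

test_that("copy-number dosage coefficients recover the planted sign", {
  st <- syntheticStudy("strong", seed = 5, n_patients = 200)
  g <- networkGenes(st$truth)[1:8]
  for (tg in g) {
    m <- fitGeneModel(tg, st$cohort$expression, st$cohort$copy_number)
    if (m$cn_coefficient != 0) expect_gt(m$cn_coefficient, 0)
  }
})

test_that("local regulators are pruned by gene-order distance", {
  ann <- data.frame(
    gene_id = paste0("g", sprintf("%03d", 1:120)),
    chrom = c(rep("chr1", 80), rep("chr2", 40)),
    start = c(seq(1e4, by = 1e5, length.out = 80),
              seq(1e4, by = 1e5, length.out = 40)),
    end = c(seq(1e4, by = 1e5, length.out = 80),
            seq(1e4, by = 1e5, length.out = 40)) + 5e3,
    stringsAsFactors = FALSE)
  model <- structure(list(
    target = "g001", intercept = 0, cn_coefficient = 0.4,
    cn_p_value = NA_real_,
    predictors = data.frame(
      regulator = c("g011", "g051", "g052", "g081"),
      coefficient = c(0.5, 0.5, 0.5, 0.5), p_value = 0,
      stringsAsFactors = FALSE),
    cv_lambda = 0.1, sigma2 = 1), class = "GeneModel")
  pr <- pruneLocalRegulators(model, ann, local_gene_cutoff = 50)
  kept <- pr$predictors$regulator
  expect_false("g011" %in% kept)  # 10 away, same chromosome
  expect_false("g051" %in% kept)  # exactly 50 away: removed (<= rule)
  expect_true("g052" %in% kept)   # 51 away: kept
  expect_true("g081" %in% kept)   # different chromosome
  expect_equal(pr$cn_coefficient, 0.4)
})

test_that("network assembly builds consistent signed edge and degree tables", {
  expect_equal(nrow(networkEdges(assembleNetwork(list()))), 0)

  m1 <- structure(list(target = "b", intercept = 0, cn_coefficient = 0,
                       cn_p_value = NA_real_,
                       predictors = data.frame(regulator = c("a", "c"),
                                               coefficient = c(0.5, -0.2),
                                               p_value = c(0, 0)),
                       cv_lambda = 0.1, sigma2 = 1), class = "GeneModel")
  net <- assembleNetwork(list(m1), genes = c("a", "b", "c"))
  ed <- networkEdges(net)
  expect_equal(ed$sign, c("activator", "inhibitor"))
  expect_true(all(ed$coefficient[ed$sign == "inhibitor"] < 0))
  dt <- degreeTable(net)
  expect_equal(sum(dt$in_degree), nrow(ed))
  expect_equal(sum(dt$out_degree), nrow(ed))

  # self-loops are rejected by the class validity
  bad <- data.frame(regulator = "a", target = "a", coefficient = 1,
                    sign = "activator", p_value = 0)
  expect_error(new("RegulatoryNetwork", genes = "a", edges = bad,
                   models = list()), "self-loops")
})

test_that("predictive power is a correlation weight with sane degenerate cases", {
  # noise-free linear system: applying the true models to the training
  # draw must give correlations ~ 1
  net <- makeNetwork(data.frame(regulator = "a", target = "b",
                                coefficient = 0.7))
  net@models <- list(
    b = structure(list(target = "b", intercept = 0, cn_coefficient = 0,
                       cn_p_value = NA_real_,
                       predictors = data.frame(regulator = "a",
                                               coefficient = 0.7,
                                               p_value = 0),
                       cv_lambda = 0.1, sigma2 = 1), class = "GeneModel"))
  set.seed(31)
  expr <- rbind(a = rnorm(50), b = 0)
  expr["b", ] <- 0.7 * expr["a", ]
  cn <- expr * 0
  w <- evaluatePredictivePower(net, expr, cn)
  expect_equal(unname(w["b"]), 1, tolerance = 1e-12)
  expect_equal(unname(w["a"]), 0)  # no model -> weight 0
})

test_that("inferred networks beat their own degree-preserving permutations", {
  st <- syntheticStudy("strong", seed = 3, n_patients = 120)
  # perfect-knowledge network stands in for the fit: the property under
  # test is the validation logic, not the lasso
  net <- truthAsNetwork(st$truth)
  models <- lapply(networkGenes(st$truth), function(tg) {
    ed <- networkEdges(net)
    pr <- ed[ed$target == tg, c("regulator", "coefficient", "p_value")]
    structure(list(target = tg, intercept = 0,
                   cn_coefficient = cnCoefficients(st$truth)[[tg]],
                   cn_p_value = 0,
                   predictors = data.frame(regulator = pr$regulator,
                                           coefficient = pr$coefficient,
                                           p_value = pr$p_value),
                   cv_lambda = 0.1, sigma2 = 1), class = "GeneModel")
  })
  names(models) <- networkGenes(st$truth)
  net@models <- models
  hold <- simulatePatientCohort(st$truth, n_patients = 80, cna_sd = 0.8,
                                p_segment = 0.8, seg_genes = c(2, 6),
                                seed = 99)
  w_true <- evaluatePredictivePower(net, hold$expression, hold$copy_number)
  wins <- vapply(1:10, function(k) {
    pn <- permuteNetworkDegreePreserving(net, seed = k)
    pn@models <- lapply(names(models), function(tg) {
      ed <- networkEdges(pn)
      pr <- ed[ed$target == tg, ]
      structure(list(target = tg, intercept = 0,
                     cn_coefficient = cnCoefficients(st$truth)[[tg]],
                     cn_p_value = 0,
                     predictors = data.frame(regulator = pr$regulator,
                                             coefficient = pr$coefficient,
                                             p_value = pr$p_value),
                     cv_lambda = 0.1, sigma2 = 1), class = "GeneModel")
    })
    names(pn@models) <- names(models)
    w_perm <- evaluatePredictivePower(pn, hold$expression,
                                      hold$copy_number)
    mean(w_true) > mean(w_perm)
  }, logical(1))
  expect_true(all(wins))
})
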