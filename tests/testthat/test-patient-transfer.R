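makeCohort <- function(expr, months, event, irradiated = TRUE) {
  n <- ncol(expr)
  PatientCohort(expr, data.frame(
    months = months, event = event,
    irradiated = rep_len(irradiated, n),
    age = 65, t_stage = 2L, gleason = 7L, psa = 10))
}

test_that("consistency filter applies the direction-correlation rule strictly", {
  n <- 12
  months <- seq(2, 40, length.out = n)
  # upcand: expression decreasing in relapse time (consistent for "up")
  # downcand: increasing (consistent for "down"); flat: zero correlation
  expr <- rbind(upcand = rev(seq_len(n)) + 0.01 * rnorm(n),
                downcand = seq_len(n) + 0.01 * rnorm(n),
                flat = rep(5, n))
  colnames(expr) <- paste0("p", seq_len(n))
  set.seed(1)
  coh <- makeCohort(expr, months, event = TRUE)
  cand <- data.frame(gene_id = c("upcand", "downcand", "flat"),
                     direction = c("up", "down", "up"),
                     stringsAsFactors = FALSE)
  kept <- consistencyFilter(cand, coh)
  expect_setequal(kept$gene_id, c("upcand", "downcand"))
  expect_lt(kept$correlation[kept$gene_id == "upcand"], 0)
  expect_gt(kept$correlation[kept$gene_id == "downcand"], 0)
  # zero correlation is dropped (strict inequality)
  expect_false("flat" %in% kept$gene_id)

  # direction flipped: nothing survives
  cand2 <- data.frame(gene_id = c("upcand", "downcand"),
                      direction = c("down", "up"))
  expect_equal(nrow(consistencyFilter(cand2, coh)), 0)

  few <- makeCohort(expr[, 1:4], months[1:4], event = c(TRUE, TRUE, FALSE,
                                                        FALSE))
  expect_error(consistencyFilter(cand, few), "at least 3")
})

test_that("hazard-linked planted drivers pass the consistency filter", {
  # strong planted effect at the scale of 12 relapsed patients
  kept <- vapply(1:10, function(r) {
    set.seed(300 + r)
    n <- 12
    expr <- rbind(drv = rnorm(n))
    colnames(expr) <- paste0("p", 1:n)
    months <- rexp(n, rate = 0.05 * exp(2 * expr["drv", ]))
    coh <- makeCohort(expr, months, event = TRUE)
    nrow(consistencyFilter(data.frame(gene_id = "drv", direction = "up"),
                           coh)) == 1
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("optimal cutoff recovers planted survival groups under the size constraint", {
  fx <- makeSurvivalFixture(n_per_group = 8)
  expr <- ifelse(fx$group_low, 1, 3) # perfectly separating expression
  sp <- optimalCutoffLogrank(expr, fx$months, fx$event, min_group_size = 8)
  expect_true(sp$feasible)
  expect_equal(sp$cutoff, 2)
  expect_equal(sort(which(sp$low)), which(fx$group_low))
  expect_equal(sp$n_low, 8); expect_equal(sp$n_high, 8)
  expect_lt(sp$p_approx, 0.001)

  # constant expression cannot satisfy the constraint
  sp0 <- optimalCutoffLogrank(rep(1, 16), fx$months, fx$event)
  expect_false(sp0$feasible)

  # n = 20 with min 8 per group: at most 5 cutoffs examined
  set.seed(2)
  e20 <- rnorm(20)
  sp20 <- optimalCutoffLogrank(e20, rexp(20), rep(TRUE, 20))
  expect_lte(sp20$cutoffs_tried, 5)

  # invariance to patient ordering
  set.seed(3)
  perm <- sample(16)
  sp_p <- optimalCutoffLogrank(expr[perm], fx$months[perm],
                               fx$event[perm])
  expect_equal(sp_p$cutoff, sp$cutoff)
  expect_equal(sp_p$p_approx, sp$p_approx)

  expect_error(optimalCutoffLogrank(expr[1:10], fx$months[1:10],
                                    fx$event[1:10]), "smaller")
})

test_that("the log-rank statistic matches survival::survdiff", {
  set.seed(4)
  for (r in 1:10) {
    n <- sample(10:30, 1)
    time <- rexp(n); event <- runif(n) < 0.7
    g <- runif(n) < 0.5
    if (length(unique(g)) < 2 || !any(event)) next
    ours <- logrankTest(time, event, g)
    ref <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(ours$chisq, ref$chisq, tolerance = 1e-8)
  }
})

test_that("exact permutational log-rank equals exhaustive enumeration", {
  set.seed(9)
  for (r in 1:6) {
    n <- sample(8:12, 1)
    time <- sample(seq_len(100), n)
    event <- runif(n) < 0.8
    if (!any(event)) event[1] <- TRUE
    grp <- logical(n); grp[sample(n, floor(n / 2))] <- TRUE
    p_pkg <- as.numeric(exactLogrankP(time, event, grp))
    p_oracle <- enumLogrankOracle(time, event, grp)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  }

  # exchangeable construction with a constant statistic: p = 1
  time <- rep(c(1, 2, 3, 4), 2)
  event <- rep(TRUE, 8)
  grp <- rep(c(TRUE, FALSE), 4)
  # no events -> statistic constant at 0
  p1 <- as.numeric(exactLogrankP(time, rep(FALSE, 8), grp))
  expect_equal(p1, 1)

  expect_error(exactLogrankP(time, event, rep(TRUE, 8)), "nonempty")
})

test_that("approximate p-values tend to overstate significance vs exact", {
  set.seed(12)
  ratio_dir <- replicate(60, {
    n <- 14
    time <- rexp(n); event <- runif(n) < 0.8
    g <- logical(n); g[sample(n, 7)] <- TRUE
    if (!any(event)) event[1] <- TRUE
    pa <- optimalCutoffLogrank(as.numeric(g) + rnorm(n, 0, 1e-6),
                               time, event, min_group_size = 7)$p_approx
    pe <- as.numeric(exactLogrankP(time, event, g))
    c(pe, pa)
  })
  # the statistical tendency, not a per-case guarantee
  expect_gte(median(ratio_dir[1, ]), median(ratio_dir[2, ]))
})

test_that("FDR estimators: BH step-up and Storey-scaled variants", {
  expect_equal(estimateFdr(rep(1, 5))$conservative, rep(1, 5))
  expect_equal(estimateFdr(rep(1, 5))$liberal, rep(1, 5))

  # hand step-up computation
  fdr <- estimateFdr(c(0.01, 0.02, 0.03, 0.8))
  expect_equal(fdr$conservative, c(0.04, 0.04, 0.04, 0.8))

  # liberal never exceeds conservative when pi0 < 1
  set.seed(6)
  p <- c(runif(40, 0, 0.01), runif(10))
  f <- estimateFdr(p)
  expect_lt(f$pi0, 1)
  expect_true(all(f$liberal <= f$conservative + 1e-12))
  expect_error(estimateFdr(c(-0.1, 0.5)))
})

test_that("random-gene baseline counts false-positive splits", {
  set.seed(15)
  n <- 40
  expr <- matrix(rnorm(30 * n), 30, n,
                 dimnames = list(paste0("g", 1:30), paste0("p", 1:n)))
  coh <- makeCohort(expr, rexp(n, 0.05), runif(n) < 0.7)
  # alpha = 1 counts every feasible gene
  b1 <- randomGeneBaseline(coh, rownames(expr), set_size = 5, n_draws = 2,
                           alpha = 1, seed = 1)
  expect_equal(b1$mean_count, 5)
  # seeded single draw is reproducible
  b2 <- randomGeneBaseline(coh, rownames(expr), set_size = 6, n_draws = 1,
                           alpha = 0.05, seed = 9)
  b3 <- randomGeneBaseline(coh, rownames(expr), set_size = 6, n_draws = 1,
                           alpha = 0.05, seed = 9)
  expect_equal(b2$counts, b3$counts)
  expect_lte(b2$ci[1], b2$mean_count)
  expect_gte(b2$ci[2], b2$mean_count)
})

test_that("Cox models quantify candidate groups against covariates", {
  set.seed(20)
  n <- 60
  expr <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("d", "x"), paste0("p", 1:n)))
  grp <- expr["d", ] > 0
  months <- rexp(n, 0.05 * exp(1.5 * grp))
  clin <- data.frame(months = months, event = TRUE, irradiated = TRUE,
                     age = round(rnorm(n, 65, 8)),
                     t_stage = sample(1:4, n, TRUE),
                     gleason = sample(6:10, n, TRUE),
                     psa = rlnorm(n, log(10), 0.5))
  coh <- PatientCohort(expr, clin)
  g <- setNames(grp, colnames(expr))
  fit <- coxCovariateModel(coh, g)
  p_grp <- fit$with_group$p_value[fit$with_group$term == "group_highTRUE"]
  p_cov <- fit$with_group$p_value[fit$with_group$term != "group_highTRUE"]
  expect_true(all(p_grp < p_cov))
  expect_equal(nrow(fit$without_group), 4)

  # tiny example against an independent Newton solve of the partial
  # likelihood (single binary covariate, no ties)
  set.seed(21)
  n2 <- 25
  x <- rep(c(0, 1), length.out = n2)
  tm <- rexp(n2, 0.1 * exp(0.8 * x)) + seq(0, 1e-4, length.out = n2)
  clin2 <- data.frame(months = tm, event = TRUE, irradiated = TRUE,
                      age = 65, t_stage = 2L, gleason = 7L, psa = 10)
  expr2 <- matrix(0, 1, n2, dimnames = list("g", paste0("q", 1:n2)))
  coh2 <- PatientCohort(expr2, clin2)
  fit2 <- coxCovariateModel(coh2, setNames(x == 1, colnames(expr2)),
                            covariates = "age")
  beta_pkg <- fit2$with_group$coef[fit2$with_group$term == "group_highTRUE"]
  beta_oracle <- newtonCoxOracle(tm, rep(TRUE, n2), x)
  expect_equal(beta_pkg, beta_oracle, tolerance = 1e-6)

  clin0 <- clin; clin0$event <- FALSE
  coh0 <- PatientCohort(expr, clin0)
  expect_error(coxCovariateModel(coh0, g), "zero-event")
})

test_that("transferCandidates assembles the marker table end to end", {
  set.seed(30)
  n <- 40
  expr <- matrix(rnorm(6 * n), 6, n,
                 dimnames = list(paste0("g", 1:6), paste0("p", 1:n)))
  # g1 is a strong "up" driver: high expression accelerates relapse
  months <- rexp(n, 0.04 * exp(1.8 * scale(expr["g1", ])[, 1]))
  horizon <- quantile(months, 0.7)
  coh <- makeCohort(expr, pmin(months, horizon), months <= horizon)
  cand <- data.frame(gene_id = c("g1", "g2"),
                     direction = c("up", "up"), stringsAsFactors = FALSE)
  tab <- transferCandidates(cand, coh, min_group_size = 8, seed = 1)
  expect_true(all(tab$n_low >= 8 & tab$n_high >= 8, na.rm = TRUE))
  expect_true("g1" %in% tab$gene_id[tab$selected])
  g1 <- tab[tab$gene_id == "g1", ]
  expect_false(is.na(g1$p_exact))
  expect_false(is.na(g1$q_conservative))
})
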