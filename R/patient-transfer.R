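#' Filter candidates for consistent behavior in irradiated relapsed patients
#'
#' A candidate overexpressed in the radioresistant cell line ("up") is
#' consistent when its pre-treatment expression correlates negatively with
#' months-to-relapse across irradiated patients who relapsed (high
#' expression, faster relapse); an underexpressed candidate ("down") is
#' consistent under a positive correlation. Correlations exactly zero are
#' inconsistent (strict inequalities).
#'
#' @param candidates data.frame with \code{gene_id} and \code{direction}
#'   ("up"/"down"), e.g. from [selectDirectCandidates()].
#' @param cohort a [PatientCohort-class].
#' @param method correlation type; Pearson by default, rank correlation
#'   available.
#' @return the candidate rows that pass, with a \code{correlation} column;
#'   the number of relapsed irradiated patients used is in attribute
#'   \code{"n_relapsed"}.
#' @export
consistencyFilter <- function(candidates, cohort,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(cohort, "PatientCohort"))
  cd <- colData(cohort)
  use <- cd$irradiated & cd$event
  if (sum(use) < 3)
    stop("need at least 3 relapsed irradiated patients; got ", sum(use))
  expr <- assay(cohort, "expression")[, use, drop = FALSE]
  months <- cd$months[use]
  genes <- candidates$gene_id
  if (!all(genes %in% rownames(expr)))
    stop("candidate genes missing from cohort expression: ",
         paste(setdiff(genes, rownames(expr)), collapse = ", "))
  rho <- vapply(genes, function(g) {
    x <- expr[g, ]
    if (sd(x) == 0) return(0)
    cor(x, months, method = method)
  }, numeric(1))
  keep <- (candidates$direction == "up" & rho < 0) |
    (candidates$direction == "down" & rho > 0)
  out <- candidates[keep, , drop = FALSE]
  out$correlation <- unname(rho[keep])
  rownames(out) <- NULL
  attr(out, "n_relapsed") <- sum(use)
  out
}

#' Conservative and liberal false-discovery-rate estimates
#'
#' Conservative q-values are Benjamini-Hochberg step-up values; liberal
#' q-values additionally estimate the null proportion pi0 from the p-value
#' distribution (Storey-type, pi0 = min(1, mean(p > lambda) / (1 - lambda)))
#' and scale the BH values by it. Both are monotone non-decreasing in p.
#'
#' @param p numeric p-values.
#' @param lambda tuning point for the pi0 estimate.
#' @return list with \code{conservative}, \code{liberal} and \code{pi0}.
#' @examples
#' estimateFdr(c(0.01, 0.02, 0.03, 0.8))$conservative  # 0.04 0.04 0.04 0.8
#' @export
estimateFdr <- function(p, lambda = 0.5) {
  stopifnot(all(p >= 0 & p <= 1), lambda > 0, lambda < 1)
  bh <- p.adjust(p, method = "BH")
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  list(conservative = bh, liberal = pmin(pi0 * bh, 1), pi0 = pi0)
}

#' Random-gene baseline for optimal-cutoff survival splitting
#'
#' Estimates how many of a random gene set would pass the optimal-cutoff
#' log-rank screen by chance: repeatedly draws \code{set_size} genes
#' uniformly from the universe, runs [optimalCutoffLogrank()] on each in
#' the irradiated patients, and counts genes with an approximate p below
#' \code{alpha}.
#'
#' @param cohort a [PatientCohort-class].
#' @param universe character, genes to draw from (must be cohort rows).
#' @param set_size genes per draw.
#' @param n_draws number of random draws.
#' @param alpha significance level counted against.
#' @param min_group_size per-group constraint for the splits.
#' @param seed RNG seed.
#' @return list with \code{mean_count}, normal-approximation \code{ci}
#'   (95%), and the per-draw \code{counts}.
#' @export
randomGeneBaseline <- function(cohort, universe, set_size, n_draws = 100,
                               alpha = 0.05, min_group_size = 8, seed = 1) {
  stopifnot(is(cohort, "PatientCohort"), set_size <= length(universe))
  cd <- colData(cohort)
  use <- cd$irradiated
  expr <- assay(cohort, "expression")[, use, drop = FALSE]
  months <- cd$months[use]
  event <- cd$event[use]
  if (!all(universe %in% rownames(expr)))
    stop("universe genes missing from cohort expression")
  withSeed(seed, {
    counts <- vapply(seq_len(n_draws), function(i) {
      genes <- sample(universe, set_size)
      sum(vapply(genes, function(g) {
        sp <- optimalCutoffLogrank(expr[g, ], months, event, min_group_size)
        isTRUE(sp$feasible) && sp$p_approx < alpha
      }, logical(1)))
    }, numeric(1))
    m <- mean(counts)
    se <- if (n_draws > 1) sd(counts) / sqrt(n_draws) else 0
    list(mean_count = m, ci = c(m - 1.96 * se, m + 1.96 * se),
         counts = counts)
  })
}

#' Cox proportional-hazards models with and without a candidate grouping
#'
#' Fits disease-free survival against the prognostic covariates (age,
#' T-stage, Gleason score, PSA) alone and together with the candidate-based
#' group assignment, to judge whether the candidate carries information
#' beyond the established factors.
#'
#' @param cohort a [PatientCohort-class] (or a subset of patients via
#'   \code{patients}).
#' @param group named logical vector (TRUE = high-expression group) over the
#'   analyzed patients.
#' @param patients optional character of patient ids to restrict to
#'   (default: patients named in \code{group}).
#' @param covariates covariate columns of the clinical table to adjust for.
#' @return list with \code{with_group} and \code{without_group} coefficient
#'   tables (coef, hazard ratio, se, z, p) and the fitted \code{coxph}
#'   objects.
#' @export
coxCovariateModel <- function(cohort, group, patients = names(group),
                              covariates = c("age", "t_stage", "gleason",
                                             "psa")) {
  stopifnot(is(cohort, "PatientCohort"))
  cd <- as.data.frame(colData(cohort))
  if (is.null(patients)) stop("'group' must be named by patient id")
  if (!all(patients %in% rownames(cd)))
    stop("unknown patient ids in 'group'")
  dat <- cd[patients, , drop = FALSE]
  dat$group_high <- as.logical(group[patients])
  if (!any(dat$event)) stop("zero-event cohort: Cox model unidentifiable")
  if (sum(dat$event) < length(covariates) + 1)
    stop("fewer events than model terms")
  f0 <- stats::as.formula(paste("Surv(months, event) ~",
                                paste(covariates, collapse = " + ")))
  f1 <- stats::as.formula(paste("Surv(months, event) ~ group_high +",
                                paste(covariates, collapse = " + ")))
  fit0 <- coxph(f0, data = dat)
  fit1 <- coxph(f1, data = dat)
  tab <- function(fit) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), coef = s[, "coef"],
               hazard_ratio = s[, "exp(coef)"], se = s[, "se(coef)"],
               z = s[, "z"], p_value = s[, "Pr(>|z|)"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(with_group = tab(fit1), without_group = tab(fit0),
       fit_with = fit1, fit_without = fit0)
}

#' Transfer driver candidates to a patient cohort
#'
#' Runs the full patient-transfer stage: consistency filtering on relapsed
#' irradiated patients, constrained optimal-cutoff log-rank splitting of
#' all irradiated patients per surviving candidate, selection at
#' \code{alpha}, exact permutational log-rank p-values for the selected
#' splits, and conservative/liberal FDR estimates over the selected set.
#'
#' @param candidates data.frame with \code{gene_id} and \code{direction}.
#' @param cohort a [PatientCohort-class].
#' @param min_group_size per-group constraint for the splits.
#' @param alpha approximate log-rank selection level.
#' @param exact compute exact permutational p-values for selected markers.
#' @param cor_method correlation type for the consistency filter.
#' @param seed RNG seed (Monte-Carlo exact p-values).
#' @return data.frame (one row per consistent candidate) with the split
#'   results: \code{gene_id}, \code{direction}, \code{correlation},
#'   \code{feasible}, \code{cutoff}, \code{n_low}, \code{n_high},
#'   \code{p_approx}, \code{selected}, \code{p_exact},
#'   \code{q_conservative}, \code{q_liberal}; the consistency-filter count
#'   is in attribute \code{"n_consistent"}.
#' @export
transferCandidates <- function(candidates, cohort, min_group_size = 8,
                               alpha = 0.05, exact = TRUE,
                               cor_method = "pearson", seed = 1) {
  consistent <- consistencyFilter(candidates, cohort, method = cor_method)
  cd <- colData(cohort)
  use <- cd$irradiated
  expr <- assay(cohort, "expression")[, use, drop = FALSE]
  months <- cd$months[use]
  event <- cd$event[use]
  rows <- lapply(seq_len(nrow(consistent)), function(i) {
    g <- consistent$gene_id[i]
    sp <- optimalCutoffLogrank(expr[g, ], months, event, min_group_size)
    data.frame(gene_id = g, direction = consistent$direction[i],
               correlation = consistent$correlation[i],
               feasible = sp$feasible, cutoff = sp$cutoff,
               n_low = sp$n_low, n_high = sp$n_high,
               p_approx = sp$p_approx, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), direction = character(),
               correlation = numeric(), feasible = logical(),
               cutoff = numeric(), n_low = integer(), n_high = integer(),
               p_approx = numeric(), selected = logical(),
               p_exact = numeric(), q_conservative = numeric(),
               q_liberal = numeric(), stringsAsFactors = FALSE)
  if (!nrow(out)) {
    attr(out, "n_consistent") <- 0L
    return(out)
  }
  out$selected <- !is.na(out$p_approx) & out$feasible & out$p_approx < alpha
  out$p_exact <- NA_real_
  if (exact && any(out$selected)) {
    for (i in which(out$selected)) {
      low <- expr[out$gene_id[i], ] <= out$cutoff[i]
      out$p_exact[i] <- as.numeric(
        exactLogrankP(months, event, low, seed = seed + i))
    }
  }
  out$q_conservative <- NA_real_
  out$q_liberal <- NA_real_
  if (any(out$selected)) {
    fdr <- estimateFdr(out$p_approx[out$selected])
    out$q_conservative[out$selected] <- fdr$conservative
    out$q_liberal[out$selected] <- fdr$liberal
  }
  attr(out, "n_consistent") <- nrow(consistent)
  out
}
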