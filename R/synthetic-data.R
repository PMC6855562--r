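#' Generate a ground-truth gene regulatory network
#'
#' Builds a sparse signed linear network at desk scale: genes are placed on
#' chromosomes with strictly increasing coordinates, a requested fraction of
#' off-diagonal regulator-to-target coefficients is drawn nonzero with a
#' requested activator/inhibitor sign mix, and the coefficient matrix is
#' rescaled to spectral radius below 1 so that the simultaneous linear
#' expression model is solvable (cycles are permitted).
#'
#' @param n_genes number of genes (>= 10).
#' @param n_chromosomes number of chromosomes genes are spread over.
#' @param density fraction of off-diagonal entries that are nonzero edges,
#'   in (0, 0.2).
#' @param frac_inhibitor fraction of edges with negative (inhibitory)
#'   coefficients; real tumor networks are dominated by activator links, so
#'   the default is small.
#' @param weight_range magnitude range edge coefficients are drawn from
#'   (uniform) before the spectral rescale.
#' @param cn_coef_range range of per-gene copy-number dosage coefficients;
#'   centered at 1 (a log2 copy-number change propagates roughly one-to-one
#'   into log2 expression).
#' @param noise_sd per-gene residual standard deviation (recycled).
#' @param seed integer RNG seed.
#' @return A [GroundTruthNetwork-class] object.
#' @examples
#' net <- generateGroundTruthNetwork(100, density = 0.02, seed = 1)
#' sum(edgeWeights(net) != 0)
#' @export
generateGroundTruthNetwork <- function(n_genes, n_chromosomes = 10,
                                       density = 0.02,
                                       frac_inhibitor = 0.03,
                                       weight_range = c(0.4, 0.9),
                                       cn_coef_range = c(0.8, 1.2),
                                       noise_sd = 0.25, seed = 1) {
  n_genes <- assertCount(n_genes, "n_genes", min = 10L)
  n_chromosomes <- assertCount(n_chromosomes, "n_chromosomes")
  assertFraction(density, "density", 0, 0.2, open_lo = TRUE, open_hi = TRUE)
  assertFraction(frac_inhibitor, "frac_inhibitor")
  n_edges <- round(density * n_genes * (n_genes - 1))
  if (n_edges < 1)
    stop("density ", density, " infeasible for ", n_genes,
         " genes: no edges would be drawn")

  withSeed(seed, {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    chrom <- paste0("chr", sort(rep_len(seq_len(n_chromosomes), n_genes)))
    # strictly increasing coordinates within each chromosome
    width <- sample(2000:20000, n_genes, replace = TRUE)
    gap <- sample(10000:100000, n_genes, replace = TRUE)
    start <- integer(n_genes)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      start[idx] <- cumsum(gap[idx]) +
        c(0, cumsum(width[idx[-length(idx)]]))
    }
    genes <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                        end = start + width, stringsAsFactors = FALSE)

    off <- which(row(diag(n_genes)) != col(diag(n_genes)))
    pos <- sample(off, n_edges)
    w <- runif(n_edges, weight_range[1], weight_range[2])
    n_neg <- round(frac_inhibitor * n_edges)
    if (n_neg > 0) w[sample.int(n_edges, n_neg)] <- -w[seq_len(n_neg)]
    W <- matrix(0, n_genes, n_genes, dimnames = list(gene_id, gene_id))
    W[pos] <- w
    rho <- spectralRadius(W)
    if (rho >= 0.9) W <- W * (0.85 / rho)

    new("GroundTruthNetwork",
        genes = genes, W = W,
        cn_coefficients = setNames(
          runif(n_genes, cn_coef_range[1], cn_coef_range[2]), gene_id),
        noise_sd = setNames(rep_len(noise_sd, n_genes), gene_id),
        density = density)
  })
}

#' Plant drivers, markers and hazard effects in a ground-truth network
#'
#' Drivers are sampled among genes with downstream reach (so their planted
#' alterations can propagate), markers among genes reachable from the
#' drivers within a few network steps (so marker impacts are nonzero by
#' construction); drivers and markers are disjoint. Each driver gets a
#' direction ("up": amplified and overexpressed in the resistant line;
#' "down": deleted and underexpressed) and a log-hazard coefficient whose
#' sign matches the direction (high expression of an "up" driver shortens
#' time to relapse).
#'
#' @param truth a [GroundTruthNetwork-class] object.
#' @param n_drivers number of planted drivers (0 allowed for null designs).
#' @param n_markers number of planted marker genes.
#' @param hazard_effect absolute log-hazard effect per standard deviation of
#'   driver expression.
#' @param reach number of network steps used to define "downstream".
#' @param seed integer RNG seed.
#' @return A [SyntheticTruthRecord-class] object.
#' @export
makeTruthRecord <- function(truth, n_drivers = 4, n_markers = 4,
                            hazard_effect = 1.0, reach = 3, seed = 1) {
  stopifnot(is(truth, "GroundTruthNetwork"))
  n_drivers <- assertCount(n_drivers, "n_drivers", min = 0L)
  n_markers <- assertCount(n_markers, "n_markers", min = 1L)
  g <- networkGenes(truth)
  A <- (edgeWeights(truth) != 0) * 1
  # k-step boolean reachability
  R <- A
  Ak <- A
  k <- 1
  while (k < reach) {
    Ak <- (Ak %*% A > 0) * 1
    R <- ((R + Ak) > 0) * 1
    k <- k + 1
  }
  withSeed(seed, {
    if (n_drivers > 0) {
      # drivers need a strong direct regulatory target so their planted
      # marker impact is recoverable; require an outgoing edge at least as
      # strong as the median edge magnitude
      Wabs <- abs(edgeWeights(truth))
      med_w <- median(Wabs[Wabs > 0])
      strongest_out <- apply(Wabs, 1L, max)
      eligible <- g[rowSums(R) >= 2 & strongest_out >= med_w]
      if (length(eligible) < n_drivers)
        stop("not enough genes with downstream reach to plant ", n_drivers,
             " drivers")
      drv <- sample(eligible, n_drivers)
      direction <- sample(c("up", "down"), n_drivers, replace = TRUE)
      downstream <- g[colSums(R[drv, , drop = FALSE]) > 0]
      downstream <- setdiff(downstream, drv)
    } else {
      drv <- character()
      direction <- character()
      downstream <- character()
    }
    # every driver must strongly impact at least one marker: pick each
    # driver's strongest direct regulatory target as a marker, so the
    # planted drivers' marker impacts stand out over the degree-preserving
    # null even on small, well-connected desk-scale graphs
    W <- edgeWeights(truth)
    markers <- character()
    for (d in drv) {
      tg <- setdiff(g[W[d, ] != 0], drv)
      if (!length(tg)) {
        tg <- setdiff(g[R[d, ] > 0], drv)
        if (!length(tg))
          stop("driver ", d, " has no downstream genes outside the driver set")
      }
      if (!any(tg %in% markers))
        markers <- c(markers, tg[which.max(abs(W[d, tg]))])
    }
    if (length(markers) > n_markers)
      stop("n_markers too small to give every driver a downstream marker")
    pool <- setdiff(if (length(downstream) >= n_markers) downstream
                    else unique(c(downstream, setdiff(g, drv))), markers)
    if (length(markers) < n_markers)
      markers <- c(markers, sample(pool, n_markers - length(markers)))
    hz <- setNames(as.numeric(ifelse(direction == "up", hazard_effect,
                                     -hazard_effect)), drv)
    new("SyntheticTruthRecord",
        drivers = data.frame(gene_id = drv, direction = direction,
                             stringsAsFactors = FALSE),
        markers = markers,
        hazard_coefficients = hz,
        seed = as.integer(seed))
  })
}

# Solve x = (I - W')^{-1} (b * c + e) column-wise for a matrix of inputs.
solveExpression <- function(truth, rhs) {
  W <- edgeWeights(truth)
  if (spectralRadius(W) >= 1)
    stop("spectral radius of W is >= 1; the linear system is not solvable")
  A <- diag(nrow(W)) - t(W)
  x <- solve(A, rhs)
  dimnames(x) <- dimnames(rhs)
  x
}

#' Simulate a patient cohort from a ground-truth network
#'
#' Per patient, copy-number log2-ratios are drawn as a mixture of zero and
#' segment-level shifts (contiguous runs of genes on a chromosome sharing
#' one Gaussian shift), and expression is solved from the simultaneous
#' linear model \code{x = (I - W')^{-1} (beta * c + eps)} with per-gene
#' Gaussian noise.
#'
#' @param truth a [GroundTruthNetwork-class] object.
#' @param n_patients cohort size.
#' @param cna_sd standard deviation of segment-level copy-number shifts
#'   (log2-ratio scale).
#' @param p_segment per-chromosome, per-patient probability of carrying an
#'   altered segment.
#' @param seg_genes range of segment lengths in genes.
#' @param seed integer RNG seed.
#' @return list with \code{expression} (genes x patients),
#'   \code{copy_number} (genes x patients) and a \code{clinical} table
#'   skeleton (patient ids only; see [simulateRelapseTimes()]).
#' @export
simulatePatientCohort <- function(truth, n_patients = 300, cna_sd = 0.5,
                                  p_segment = 0.4, seg_genes = c(3, 15),
                                  seed = 1) {
  stopifnot(is(truth, "GroundTruthNetwork"))
  n_patients <- assertCount(n_patients, "n_patients")
  ann <- geneAnnotation(truth)
  g <- ann$gene_id
  n <- length(g)
  withSeed(seed, {
    cn <- matrix(0, n, n_patients,
                 dimnames = list(g, sprintf("p%04d", seq_len(n_patients))))
    chr_idx <- split(seq_len(n), ann$chrom)
    for (j in seq_len(n_patients)) {
      for (idx in chr_idx) {
        if (runif(1) < p_segment) {
          len <- min(sample(seg_genes[1]:seg_genes[2], 1), length(idx))
          s <- sample.int(length(idx) - len + 1L, 1)
          cn[idx[s:(s + len - 1L)], j] <- rnorm(1, 0, cna_sd)
        }
      }
    }
    eps <- matrix(rnorm(n * n_patients, 0, truth@noise_sd), n, n_patients)
    expr <- solveExpression(truth, truth@cn_coefficients * cn + eps)
    list(expression = expr, copy_number = cn,
         clinical = data.frame(patient_id = colnames(cn),
                               stringsAsFactors = FALSE))
  })
}

#' Simulate a radioresistant vs radiosensitive cell-line pair
#'
#' Plants broad and focal copy-number segments on the ground-truth genome
#' (each planted driver receives a focal alteration whose sign matches its
#' direction), emits SEG records tiling every chromosome so that gene-level
#' mapping recovers the planted values exactly, shifts driver expression in
#' the alteration direction, propagates shifts downstream through the
#' network, and returns 3 vs 3 replicate expression matrices with replicate
#' noise.
#'
#' @param truth a [GroundTruthNetwork-class] object.
#' @param record a [SyntheticTruthRecord-class] object.
#' @param broad_frac fraction of the genome (in genes) covered by broad
#'   altered segments.
#' @param focal_count total number of focal (1-gene) alterations; must be at
#'   least the number of planted drivers and at most the gene count.
#' @param broad_magnitude magnitude range of broad segment log2-ratios
#'   (above the 0.1 calling cutoff by construction).
#' @param focal_magnitude magnitude range of focal log2-ratios.
#' @param driver_de_effect expression log2-ratio shift planted on each
#'   driver (signed by its direction); the default matches the scale of
#'   strong validated markers in real radioresistant lines (a log2
#'   difference near 2.9).
#' @param replicate_sd replicate noise standard deviation.
#' @param n_replicates replicates per condition.
#' @param seed integer RNG seed.
#' @return list with \code{segments} (SEG-style data.frame), \code{resistant}
#'   and \code{sensitive} replicate matrices, \code{cn_genes} (planted
#'   per-gene copy-number log2-ratios), \code{expression_shift} (planted
#'   mean log2-ratio profile) and \code{altered_genes}.
#' @export
simulateCellLinePair <- function(truth, record, broad_frac = 0.15,
                                 focal_count = 8,
                                 broad_magnitude = c(0.2, 0.5),
                                 focal_magnitude = c(0.25, 0.5),
                                 driver_de_effect = 2.85,
                                 replicate_sd = 0.25,
                                 n_replicates = 3, seed = 1) {
  stopifnot(is(truth, "GroundTruthNetwork"),
            is(record, "SyntheticTruthRecord"))
  ann <- geneAnnotation(truth)
  g <- ann$gene_id
  n <- length(g)
  drv <- trueDrivers(record)
  if (focal_count > n) stop("focal_count exceeds the gene count")
  if (focal_count < nrow(drv))
    stop("focal_count must cover the ", nrow(drv), " planted drivers")
  assertFraction(broad_frac, "broad_frac")

  withSeed(seed, {
    cn <- setNames(numeric(n), g)
    chr_idx <- split(seq_len(n), ann$chrom)
    # broad segments until requested genome coverage
    target_cov <- round(broad_frac * n)
    guard <- 0
    while (sum(cn != 0) < target_cov && guard < 10 * n) {
      guard <- guard + 1
      idx <- chr_idx[[sample.int(length(chr_idx), 1)]]
      len <- min(sample(5:15, 1), length(idx))
      s <- sample.int(length(idx) - len + 1L, 1)
      cn[idx[s:(s + len - 1L)]] <-
        sample(c(-1, 1), 1) * runif(1, broad_magnitude[1], broad_magnitude[2])
    }
    # focal alterations: drivers first (sign fixed by direction), then random
    for (k in seq_len(nrow(drv)))
      cn[drv$gene_id[k]] <- (if (drv$direction[k] == "up") 1 else -1) *
        runif(1, focal_magnitude[1], focal_magnitude[2])
    n_extra <- focal_count - nrow(drv)
    if (n_extra > 0) {
      free <- setdiff(g[cn == 0], drv$gene_id)
      pick <- sample(free, min(n_extra, length(free)))
      cn[pick] <- sample(c(-1, 1), length(pick), replace = TRUE) *
        runif(length(pick), focal_magnitude[1], focal_magnitude[2])
    }

    segments <- genesToSegments(ann, cn, sample_id = "RR_vs_RS")

    # planted expression shifts: strong direction-matched effect on drivers,
    # plain dosage effect on other altered genes, propagated through W.
    # Network feedback onto a driver could cancel its planted shift, so the
    # driver inputs are adjusted by fixed-point iteration until each
    # driver's realized shift equals its planted effect (contraction: the
    # feedback gain is bounded by the spectral radius < 1).
    s_vec <- truth@cn_coefficients * cn
    target_shift <- setNames(ifelse(drv$direction == "up", 1, -1) *
                               driver_de_effect, drv$gene_id)
    if (nrow(drv)) {
      s_vec[drv$gene_id] <- target_shift
      for (it in seq_len(50)) {
        delta <- drop(solveExpression(truth, cbind(s_vec)))
        gap <- target_shift - delta[drv$gene_id]
        if (max(abs(gap)) < 1e-10) break
        s_vec[drv$gene_id] <- s_vec[drv$gene_id] + gap
      }
    }
    delta <- drop(solveExpression(truth, cbind(s_vec)))

    # wide base-intensity spread (log2 microarray scale): shifted genes
    # must stay interior to the intensity distribution, or quantile
    # normalization of a small panel distorts the extreme quantiles
    base <- runif(n, 4, 12)
    mk <- function(shift) {
      m <- matrix(rnorm(n * n_replicates, 0, replicate_sd), n, n_replicates) +
        base + shift
      rownames(m) <- g
      m
    }
    resistant <- mk(delta)
    colnames(resistant) <- paste0("RR_", seq_len(n_replicates))
    sensitive <- mk(0)
    colnames(sensitive) <- paste0("RS_", seq_len(n_replicates))

    list(segments = segments, resistant = resistant, sensitive = sensitive,
         cn_genes = cn, expression_shift = setNames(delta, g),
         altered_genes = g[abs(cn) > 0.1])
  })
}

# Tile each chromosome with segments of constant value so that every gene
# lies fully inside one segment carrying its planted log2-ratio.
genesToSegments <- function(ann, cn_genes, sample_id = "sample") {
  out <- list()
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    vals <- cn_genes[idx]
    r <- rle(as.numeric(vals))
    stops <- cumsum(r$lengths)
    starts_run <- c(1L, head(stops, -1) + 1L)
    # segment boundaries at midpoints between adjacent genes
    seg_start <- seg_end <- integer(length(r$lengths))
    for (k in seq_along(r$lengths)) {
      i0 <- idx[starts_run[k]]
      i1 <- idx[stops[k]]
      seg_start[k] <- if (starts_run[k] == 1L) 1L else
        floor((ann$end[idx[starts_run[k] - 1L]] + ann$start[i0]) / 2)
      seg_end[k] <- if (stops[k] == length(idx)) ann$end[i1] + 1000L else
        floor((ann$end[i1] + ann$start[idx[stops[k] + 1L]]) / 2) - 1L
    }
    out[[ch]] <- data.frame(
      sample = sample_id, chrom = ch, start = seg_start, end = seg_end,
      n_probes = r$lengths * 10L, log2_ratio = r$values,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate relapse times for a patient cohort
#'
#' Disease-free survival times are drawn from an exponential
#' proportional-hazards model whose log-hazard is linear in the planted
#' drivers' standardized expression. Censoring is administrative: a single
#' follow-up horizon chosen so that the requested fraction of patients is
#' censored. Clinical covariates (age, T-stage, Gleason score, PSA) are
#' simulated independently of the drivers.
#'
#' @param expression genes x patients matrix (pre-treatment).
#' @param record a [SyntheticTruthRecord-class] object carrying the planted
#'   hazard coefficients.
#' @param baseline_hazard baseline event rate per month.
#' @param censor_frac fraction of patients administratively censored, in
#'   [0, 1).
#' @param radiation_frac fraction of patients flagged as irradiated
#'   (assigned at random, independent of outcome).
#' @param seed integer RNG seed.
#' @return clinical data.frame with columns \code{patient_id},
#'   \code{months}, \code{event}, \code{irradiated}, \code{age},
#'   \code{t_stage}, \code{gleason}, \code{psa}.
#' @export
simulateRelapseTimes <- function(expression, record, baseline_hazard = 0.02,
                                 censor_frac = 0.6, radiation_frac = 0.15,
                                 seed = 1) {
  stopifnot(is(record, "SyntheticTruthRecord"))
  assertFraction(censor_frac, "censor_frac", 0, 1, open_hi = TRUE)
  hz <- record@hazard_coefficients
  if (length(hz) && !all(names(hz) %in% rownames(expression)))
    stop("hazard coefficients refer to genes absent from the expression matrix")
  n <- ncol(expression)
  withSeed(seed, {
    eta <- numeric(n)
    for (d in names(hz)) {
      z <- expression[d, ]
      s <- sd(z)
      if (s > 0) eta <- eta + hz[[d]] * (z - mean(z)) / s
    }
    t_event <- rexp(n, rate = baseline_hazard * exp(eta))
    if (censor_frac > 0) {
      horizon <- quantile(t_event, 1 - censor_frac, names = FALSE)
      event <- t_event <= horizon
      months <- pmin(t_event, horizon)
    } else {
      event <- rep(TRUE, n)
      months <- t_event
    }
    data.frame(
      patient_id = colnames(expression),
      months = months,
      event = event,
      irradiated = runif(n) < radiation_frac,
      age = round(rnorm(n, 65, 8)),
      t_stage = sample(1:4, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1)),
      gleason = sample(6:10, n, replace = TRUE,
                       prob = c(0.25, 0.35, 0.2, 0.15, 0.05)),
      psa = rlnorm(n, log(10), 0.5),
      stringsAsFactors = FALSE)
  })
}
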