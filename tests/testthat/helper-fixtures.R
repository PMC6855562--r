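# Shared fixtures and independent oracles, all built in code.

# Minimal hand-built ground-truth network (no randomness).
makeTinyTruth <- function(n = 12, W = NULL, beta = NULL, noise_sd = 0) {
  gene_id <- sprintf("t%02d", seq_len(n))
  genes <- data.frame(
    gene_id = gene_id,
    chrom = paste0("chr", rep(1:2, length.out = n)),
    start = rep(seq(1000, by = 50000, length.out = ceiling(n / 2)),
                each = 2)[seq_len(n)],
    end = rep(seq(1000, by = 50000, length.out = ceiling(n / 2)),
              each = 2)[seq_len(n)] + 10000,
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), ]
  if (is.null(W)) W <- matrix(0, n, n)
  dimnames(W) <- list(gene_id, gene_id)
  if (is.null(beta)) beta <- rep(1, n)
  new("GroundTruthNetwork", genes = genes, W = W,
      cn_coefficients = setNames(beta, gene_id),
      noise_sd = setNames(rep(noise_sd, n), gene_id),
      density = sum(W != 0) / (n * (n - 1)))
}

# Regulatory network from an explicit edge table.
makeNetwork <- function(edges, genes = NULL) {
  edges$sign <- ifelse(edges$coefficient > 0, "activator", "inhibitor")
  if (!"p_value" %in% names(edges)) edges$p_value <- 0
  edges <- edges[, c("regulator", "target", "coefficient", "sign",
                     "p_value")]
  if (is.null(genes))
    genes <- sort(unique(c(edges$regulator, edges$target)))
  new("RegulatoryNetwork", genes = genes, edges = edges, models = list())
}

# Ground-truth network converted to a RegulatoryNetwork (perfect recovery).
truthAsNetwork <- function(truth) {
  W <- edgeWeights(truth)
  nz <- which(W != 0, arr.ind = TRUE)
  makeNetwork(data.frame(regulator = rownames(W)[nz[, 1]],
                         target = colnames(W)[nz[, 2]],
                         coefficient = W[nz], stringsAsFactors = FALSE),
              genes = rownames(W))
}

# Independent brute-force walk-sum oracle for network propagation:
# depth-first enumeration of all directed walks up to length L.
bruteForceImpact <- function(edges, node_weights, signal, target, L) {
  adj <- split(seq_len(nrow(edges)), edges$regulator)
  total <- 0
  walk <- function(node, prod, len) {
    if (len >= L) return(invisible())
    for (k in adj[[node]]) {
      nt <- edges$target[k]
      p2 <- prod * edges$coefficient[k] * node_weights[[nt]]
      if (nt == target) total <<- total + p2
      walk(nt, p2, len + 1)
    }
  }
  walk(names(signal), 1, 0)
  abs(signal * total)
}

# Independent exhaustive log-rank permutation oracle built on survdiff.
enumLogrankOracle <- function(time, event, group) {
  n <- length(time)
  nl <- sum(group)
  stat1 <- function(g) {
    if (length(unique(g)) < 2) return(0)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    sd$chisq
  }
  obs <- stat1(group)
  cc <- utils::combn(n, nl)
  stats <- apply(cc, 2, function(ix) {
    g <- logical(n); g[ix] <- TRUE; stat1(g)
  })
  mean(stats >= obs - 1e-8)
}

# Direct Newton-Raphson solve of the Cox partial likelihood for a single
# binary covariate with no tied event times (independent numeric oracle).
newtonCoxOracle <- function(time, event, x, iters = 50) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  beta <- 0
  for (i in seq_len(iters)) {
    U <- 0; I <- 0
    for (k in which(event)) {
      at_risk <- which(time >= time[k])
      w <- exp(beta * x[at_risk])
      xb <- sum(w * x[at_risk]) / sum(w)
      x2b <- sum(w * x[at_risk]^2) / sum(w)
      U <- U + x[k] - xb
      I <- I + (x2b - xb^2)
    }
    beta <- beta + U / I
  }
  beta
}

# Small survival fixture with two clearly separated hazard groups.
makeSurvivalFixture <- function(n_per_group = 8, gap = 20) {
  data.frame(
    months = c(seq(1, 2, length.out = n_per_group),
               seq(1, 2, length.out = n_per_group) + gap),
    event = TRUE,
    group_low = rep(c(TRUE, FALSE), each = n_per_group))
}
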