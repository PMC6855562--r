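#' Parameters for network propagation
#'
#' @param max_path_length maximum directed walk length over which impacts
#'   are accumulated. "All paths" is unbounded in cyclic graphs; truncation
#'   at a small length is the standard resolution, and with spectral radius
#'   below 1 the discarded tail decays geometrically (the diagnostic
#'   \code{tail_norm} reports the size of the last retained term).
#' @param weight_floor node weights below this are clipped to it; 0 keeps
#'   the convention that negatively predicted genes silence walks through
#'   them.
#' @return list of class \code{"PropagationParams"}.
#' @export
propagationParams <- function(max_path_length = 5, weight_floor = 0) {
  stopifnot(max_path_length >= 1)
  structure(list(max_path_length = as.integer(max_path_length),
                 weight_floor = weight_floor),
            class = "PropagationParams")
}

# Signed weighted step matrix: entry (g, t) = coefficient(g -> t) * w(t).
# Every step into a node applies that node's predictive-power weight.
stepMatrix <- function(network, node_weights) {
  g <- networkGenes(network)
  M <- matrix(0, length(g), length(g), dimnames = list(g, g))
  ed <- networkEdges(network)
  if (nrow(ed))
    M[cbind(match(ed$regulator, g), match(ed$target, g))] <-
      ed$coefficient * node_weights[ed$target]
  M
}

#' Compute the network-propagation impact matrix
#'
#' For each candidate gene \code{a}, the impact on every other gene
#' \code{b} is the magnitude of the candidate's observed expression
#' log2-ratio times the sum over all directed walks from \code{a} to
#' \code{b} of length up to \code{max_path_length} of the product of edge
#' coefficients along the walk, each traversed node down-weighted by its
#' predictive-power weight (clipped into [0, 1]). Walk sums are computed by
#' iterated products of the weighted adjacency matrix; the signed walk sum
#' is reduced to a magnitude, and self-impacts are excluded. Candidates
#' absent from the network are skipped with a warning.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param signals named numeric vector of candidate expression log2-ratios
#'   (the cell-line contrast); names define the candidate set.
#' @param node_weights named numeric per-gene predictive-power weights
#'   (e.g. [evaluatePredictivePower()] output); negative values are clipped
#'   at the weight floor, values above 1 at 1. Missing genes get weight 0.
#' @param params [propagationParams()].
#' @return an [ImpactMatrix-class]; rows = candidates, columns = genes.
#' @examples
#' # chain a -> b -> c with coefficients 0.5 and 0.4, unit weights:
#' m1 <- structure(list(target = "b", intercept = 0, cn_coefficient = 0,
#'   cn_p_value = NA, predictors = data.frame(regulator = "a",
#'   coefficient = 0.5, p_value = 0), cv_lambda = 0.1, sigma2 = 1),
#'   class = "GeneModel")
#' m2 <- structure(list(target = "c", intercept = 0, cn_coefficient = 0,
#'   cn_p_value = NA, predictors = data.frame(regulator = "b",
#'   coefficient = 0.4, p_value = 0), cv_lambda = 0.1, sigma2 = 1),
#'   class = "GeneModel")
#' net <- assembleNetwork(list(m1, m2), genes = c("a", "b", "c"))
#' im <- computeImpactMatrix(net, c(a = 2), c(a = 1, b = 1, c = 1))
#' impactValues(im)["a", "c"]  # 2 * 0.5 * 0.4 = 0.4
#' @export
computeImpactMatrix <- function(network, signals, node_weights,
                                params = propagationParams()) {
  g <- networkGenes(network)
  w <- setNames(numeric(length(g)), g)
  common <- intersect(names(node_weights), g)
  w[common] <- node_weights[common]
  w <- pmin(pmax(w, params$weight_floor), 1)

  cand <- names(signals)
  missing <- setdiff(cand, g)
  if (length(missing)) {
    warning(length(missing), " candidates not in the network skipped: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
    cand <- setdiff(cand, missing)
  }
  M <- stepMatrix(network, w)
  S <- matrix(0, length(g), length(g), dimnames = list(g, g))
  P <- diag(length(g))
  for (k in seq_len(params$max_path_length)) {
    P <- P %*% M
    S <- S + P
  }
  tail_norm <- max(abs(P))
  imp <- abs(signals[cand] * S[cand, , drop = FALSE])
  if (length(cand)) imp[cbind(seq_along(cand), match(cand, g))] <- 0
  new("ImpactMatrix", impacts = imp,
      node_weights = w,
      source_signals = signals[cand],
      params = c(unclass(params), list(tail_norm = tail_norm)))
}

#' Degree-preserving permutation of a regulatory network
#'
#' Randomizes the network while keeping every gene's exact in- and
#' out-degree: repeatedly picks two edges (a -> b) and (c -> d) and swaps
#' their regulators to (c -> b) and (a -> d), i.e. exchanges active
#' predictors between the two targets' linear models. Coefficients and
#' p-values travel with the moved predictor slot. Swaps that would create
#' self-loops or duplicate edges are rejected; 10x the edge count of swap
#' attempts are made.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param seed integer RNG seed.
#' @param n_attempts number of swap attempts (default 10x edge count).
#' @return a permuted [RegulatoryNetwork-class] (models slot reduced to the
#'   permuted edge structure).
#' @export
permuteNetworkDegreePreserving <- function(network, seed = 1,
                                           n_attempts = NULL) {
  ed <- networkEdges(network)
  m <- nrow(ed)
  if (m < 2) return(network)
  if (is.null(n_attempts)) n_attempts <- 10L * m
  withSeed(seed, {
    reg <- ed$regulator; tgt <- ed$target
    key <- function(r, t) paste(r, t, sep = "\r")
    existing <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(m)) assign(key(reg[i], tgt[i]), TRUE, existing)
    for (s in seq_len(n_attempts)) {
      ij <- sample.int(m, 2L)
      i <- ij[1L]; j <- ij[2L]
      r1 <- reg[i]; t1 <- tgt[i]; r2 <- reg[j]; t2 <- tgt[j]
      if (r1 == r2 || t1 == t2) next
      if (r2 == t1 || r1 == t2) next          # would create self-loop
      k1 <- key(r2, t1); k2 <- key(r1, t2)
      if (exists(k1, existing, inherits = FALSE) ||
          exists(k2, existing, inherits = FALSE)) next  # duplicate edge
      rm(list = c(key(r1, t1), key(r2, t2)), envir = existing)
      assign(k1, TRUE, existing); assign(k2, TRUE, existing)
      reg[i] <- r2; reg[j] <- r1
    }
    ed$regulator <- reg
    ed$target <- tgt
    new("RegulatoryNetwork", genes = networkGenes(network), edges = ed,
        models = list())
  })
}

#' Average impact of each candidate on a marker gene set
#'
#' @param impacts an [ImpactMatrix-class].
#' @param markers character vector of marker gene ids (nonempty, inside the
#'   network).
#' @return named numeric: per-candidate arithmetic mean of absolute impacts
#'   over the markers.
#' @export
scoreCandidateImpacts <- function(impacts, markers) {
  stopifnot(is(impacts, "ImpactMatrix"))
  if (!length(markers)) stop("marker set must be nonempty")
  imp <- impactValues(impacts)
  if (!all(markers %in% colnames(imp)))
    stop("markers outside the network: ",
         paste(setdiff(markers, colnames(imp)), collapse = ", "))
  rowMeans(imp[, markers, drop = FALSE])
}

#' Test candidate impacts against a degree-preserving permutation null
#'
#' For each candidate, forms the differences between its original mean
#' marker impact and the mean marker impact under each permuted network,
#' and applies a one-sided one-sample t-test of "differences greater than
#' zero". P-values are adjusted over the candidate set by
#' Benjamini-Hochberg; candidates with q below the cutoff are flagged
#' significant. Zero-variance difference vectors are degenerate: p is 0
#' when all differences are positive and 1 otherwise (with a warning).
#' The impact score reported per candidate is the log10 ratio of the
#' original impact to the mean permuted impact.
#'
#' @param original named numeric of original mean marker impacts
#'   ([scoreCandidateImpacts()]).
#' @param permuted list (length >= 2, typically 10) of equally named
#'   numerics: mean marker impacts under each permuted network.
#' @param q_cutoff significance cutoff on BH q-values.
#' @return data.frame with \code{gene_id}, \code{impact},
#'   \code{mean_permuted}, \code{impact_score}, \code{p_value},
#'   \code{q_value}, \code{significant}.
#' @export
testImpactSignificance <- function(original, permuted, q_cutoff = 0.01) {
  if (length(permuted) < 2)
    stop("need at least 2 permuted impact sets")
  if (!all(vapply(permuted, function(p)
    identical(names(p), names(original)), logical(1))))
    stop("all permuted sets must cover the same candidates as the original")
  perm_mat <- do.call(cbind, permuted)
  diffs <- original - perm_mat
  p <- apply(diffs, 1L, function(d) {
    if (sd(d) == 0) {
      warning("zero variance in impact differences; degenerate p assigned")
      return(if (all(d > 0)) 0 else 1)
    }
    tt <- t.test(d, alternative = "greater", mu = 0)
    tt$p.value
  })
  q <- p.adjust(p, method = "BH")
  mean_perm <- rowMeans(perm_mat)
  score <- ifelse(mean_perm > 0 & original > 0,
                  log10(original / mean_perm), NA_real_)
  data.frame(gene_id = names(original),
             impact = unname(original),
             mean_permuted = unname(mean_perm),
             impact_score = unname(score),
             p_value = unname(p),
             q_value = unname(q),
             significant = unname(q < q_cutoff),
             stringsAsFactors = FALSE)
}
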