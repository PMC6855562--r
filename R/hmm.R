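# Three-state Gaussian hidden Markov model for differential-expression
# calling on chromosomally ordered log2-ratio profiles. States: "under",
# "unchanged", "over". Chromosomes are independent sequences sharing one
# parameter set (positional dependence cannot span chromosome ends).

#' Construct three-state HMM parameters
#'
#' Defaults follow the standard initialization for expression log2-ratio
#' segmentation: state means at -1.25 (under), 0 (unchanged), +1.25 (over),
#' free state-specific variances initialized at 0.5^2, a sticky transition
#' matrix (0.9 self, 0.05 off-diagonal) and a uniform initial distribution.
#'
#' @param means numeric triple of state means (ascending).
#' @param variances positive numeric triple.
#' @param transition 3x3 row-stochastic matrix.
#' @param initial simplex 3-vector.
#' @return object of class \code{"HmmParams"} (list with the four
#'   components plus state labels).
#' @export
hmmParams <- function(means = c(-1.25, 0, 1.25),
                      variances = rep(0.5^2, 3),
                      transition = matrix(c(0.9, 0.05, 0.05,
                                            0.05, 0.9, 0.05,
                                            0.05, 0.05, 0.9), 3, 3,
                                          byrow = TRUE),
                      initial = rep(1 / 3, 3)) {
  stopifnot(length(means) == 3, length(variances) == 3,
            all(variances > 0), identical(dim(transition), c(3L, 3L)),
            length(initial) == 3)
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-9)
    stop("initial distribution must sum to 1")
  structure(list(states = c("under", "unchanged", "over"),
                 means = as.numeric(means),
                 variances = as.numeric(variances),
                 transition = unname(transition),
                 initial = as.numeric(initial)),
            class = "HmmParams")
}

#' @export
print.HmmParams <- function(x, ...) {
  cat("HmmParams (3-state Gaussian):\n  means:",
      signif(x$means, 4), "\n  sd:", signif(sqrt(x$variances), 4), "\n")
  if (!is.null(x$loglik))
    cat("  trained:", length(x$loglik), "iterations, final loglik",
        signif(x$loglik[length(x$loglik)], 8), "\n")
  invisible(x)
}

# Scaled forward-backward for one sequence. Returns scaled alpha/beta,
# per-position scaling constants, emission densities and log-likelihood.
hmmForwardBackward <- function(x, params) {
  K <- 3L
  Tn <- length(x)
  B <- vapply(seq_len(K), function(k)
    dnorm(x, params$means[k], sqrt(params$variances[k])), numeric(Tn))
  B <- matrix(B, Tn, K)
  B[B < 1e-300] <- 1e-300
  A <- params$transition
  alpha <- matrix(0, Tn, K)
  cc <- numeric(Tn)
  a <- params$initial * B[1, ]
  cc[1] <- sum(a)
  alpha[1, ] <- a / cc[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- drop(alpha[t - 1, ] %*% A) * B[t, ]
    cc[t] <- sum(a)
    alpha[t, ] <- a / cc[t]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    beta[t, ] <- drop(A %*% (B[t + 1, ] * beta[t + 1, ])) / cc[t + 1]
  list(alpha = alpha, beta = beta, scale = cc, B = B,
       loglik = sum(log(cc)))
}

asProfileList <- function(profiles) {
  if (is.numeric(profiles)) profiles <- list(profiles)
  if (!is.list(profiles) || !all(vapply(profiles, is.numeric, logical(1))))
    stop("profiles must be a numeric vector or a list of numeric vectors")
  profiles
}

#' Fit the differential-expression HMM by Baum-Welch
#'
#' Expectation-maximization on the pooled per-chromosome log2-ratio
#' sequences with a shared parameter set. The log-likelihood is
#' non-decreasing across iterations (asserted); training stops when its
#' change falls below \code{tol} or after \code{max_iter} iterations.
#' After training, states are relabeled so that means are ascending
#' (under < unchanged < over). Degenerate variances are floored at 1e-4
#' with a warning.
#'
#' @param profiles numeric vector or list of per-chromosome numeric vectors
#'   (chromosomally ordered average log2-ratios), e.g. the
#'   \code{profiles} element of [averageLogRatioProfile()].
#' @param init initial parameters from [hmmParams()].
#' @param max_iter maximum Baum-Welch iterations.
#' @param tol absolute log-likelihood convergence tolerance.
#' @return trained \code{"HmmParams"} with a \code{loglik} trace attached.
#' @export
fitDeHmm <- function(profiles, init = hmmParams(), max_iter = 100,
                     tol = 1e-4) {
  profiles <- asProfileList(profiles)
  if (sum(lengths(profiles)) < 30)
    stop("total sequence length must be >= 30 for a stable fit")
  params <- init
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g1 <- numeric(3)
    Anum <- matrix(0, 3, 3)
    gsum <- numeric(3)
    gx <- numeric(3)
    gxx <- numeric(3)
    gsum_trans <- numeric(3)
    for (x in profiles) {
      fb <- hmmForwardBackward(x, params)
      ll <- ll + fb$loglik
      gamma <- fb$alpha * fb$beta
      gamma <- gamma / rowSums(gamma)
      Tn <- length(x)
      g1 <- g1 + gamma[1, ]
      if (Tn > 1) {
        for (t in seq_len(Tn - 1)) {
          xi <- (fb$alpha[t, ] %o% (fb$B[t + 1, ] * fb$beta[t + 1, ])) *
            params$transition / fb$scale[t + 1]
          Anum <- Anum + xi
        }
        gsum_trans <- gsum_trans + colSums(gamma[seq_len(Tn - 1), ,
                                                 drop = FALSE])
      }
      gsum <- gsum + colSums(gamma)
      gx <- gx + colSums(gamma * x)
      gxx <- gxx + colSums(gamma * x^2)
    }
    ll_trace <- c(ll_trace, ll)
    if (length(ll_trace) > 1 &&
        ll < ll_trace[length(ll_trace) - 1] - 1e-6)
      warning("Baum-Welch log-likelihood decreased; numerical degeneracy")
    if (length(ll_trace) > 1 &&
        abs(diff(tail2(ll_trace))) < tol) break
    # M-step
    params$initial <- g1 / sum(g1)
    params$transition <- Anum / ifelse(gsum_trans > 0, gsum_trans, 1)
    params$transition <- params$transition / rowSums(params$transition)
    mu <- gx / gsum
    v <- gxx / gsum - mu^2
    if (any(v < 1e-4)) {
      warning("variance collapse; flooring state variances at 1e-4")
      v <- pmax(v, 1e-4)
    }
    params$means <- mu
    params$variances <- v
  }
  # relabel states by ascending means
  ord <- order(params$means)
  params$means <- params$means[ord]
  params$variances <- params$variances[ord]
  params$initial <- params$initial[ord]
  params$transition <- params$transition[ord, ord]
  params$loglik <- ll_trace
  params
}

tail2 <- function(x) x[c(length(x) - 1L, length(x))]

#' Posterior state decoding of differential-expression calls
#'
#' Computes forward-backward posterior state probabilities for every gene
#' position and assigns each gene the state with maximal posterior
#' (posterior decoding); exact posterior ties are broken toward
#' "unchanged".
#'
#' @param profiles numeric vector or list of per-chromosome named numeric
#'   vectors (names = gene ids).
#' @param params trained \code{"HmmParams"}.
#' @return data.frame with columns \code{gene_id}, \code{log2_ratio},
#'   \code{state} (factor under/unchanged/over) and posterior columns
#'   \code{post_under}, \code{post_unchanged}, \code{post_over}.
#' @export
decodeDeStates <- function(profiles, params) {
  profiles <- asProfileList(profiles)
  out <- lapply(profiles, function(x) {
    fb <- hmmForwardBackward(x, params)
    gamma <- fb$alpha * fb$beta
    gamma <- gamma / rowSums(gamma)
    state <- apply(gamma, 1L, function(p) {
      top <- which(p >= max(p) - 1e-12)
      if (2L %in% top) 2L else top[1L]
    })
    data.frame(
      gene_id = if (is.null(names(x))) NA_character_ else names(x),
      log2_ratio = as.numeric(x),
      state = factor(c("under", "unchanged", "over")[state],
                     levels = c("under", "unchanged", "over")),
      post_under = gamma[, 1], post_unchanged = gamma[, 2],
      post_over = gamma[, 3],
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (all(is.na(res$gene_id)))
    res$gene_id <- as.character(seq_len(nrow(res)))
  attr(res, "state_counts") <- table(res$state)
  res
}
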