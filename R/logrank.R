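# Log-rank machinery: a vectorized two-group log-rank chi-square statistic
# evaluated over many group-label assignments at once (columns of a 0/1
# membership matrix), the exact permutational log-rank p-value built on it,
# and the asymptotic p via survival::survdiff.

# Chi-square log-rank statistic for each column of Z (1 = "low" group).
# time/event define the survival data; rows of Z are patients.
logrankStatMatrix <- function(time, event, Z) {
  n <- length(time)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  Z <- Z[ord, , drop = FALSE]
  # at-risk count of group 1 at each row's time = reverse cumulative sum
  U <- upper.tri(matrix(0, n, n), diag = TRUE) * 1
  R1 <- U %*% Z                                  # n x B, row i: sum_{j>=i}
  dt <- unique(time[event])
  if (!length(dt)) return(rep(0, ncol(Z)))
  first <- match(dt, time)                       # first at-risk row per time
  d <- vapply(dt, function(t) sum(event & time == t), numeric(1))
  n_risk <- n - first + 1
  N1 <- R1[first, , drop = FALSE]                # group-1 at risk, m x B
  O <- drop(crossprod(Z, event))                 # observed group-1 deaths
  E <- colSums(N1 * (d / n_risk))
  a <- ifelse(n_risk > 1,
              d * (n_risk - d) / ((n_risk - 1) * n_risk^2), 0)
  V <- colSums((N1 * (n_risk - N1)) * a)
  ifelse(V > 0, (O - E)^2 / V, 0)
}

#' Two-group log-rank test statistic and asymptotic p-value
#'
#' @param time,event survival times and event indicators.
#' @param group logical (or 0/1) group membership.
#' @return list with \code{chisq} and \code{p_value} (chi-square with 1 df).
#' @export
logrankTest <- function(time, event, group) {
  chisq <- logrankStatMatrix(time, as.logical(event),
                             cbind(as.numeric(group)))
  list(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Exact permutational log-rank p-value
#'
#' Evaluates the log-rank chi-square statistic over group-label
#' reassignments that preserve the group sizes, and reports the fraction
#' of assignments whose statistic is at least the observed one. All
#' \code{choose(n, n_low)} assignments are enumerated exhaustively when
#' their number is at most \code{exhaustive_limit}; otherwise at least
#' \code{n_mc} seeded Monte-Carlo permutations are drawn (the observed
#' assignment is included in the Monte-Carlo denominator). A constant
#' statistic (exchangeable groups) yields p = 1.
#'
#' @param time,event survival data.
#' @param group logical, TRUE = "low" group.
#' @param exhaustive_limit maximum number of assignments for exhaustive
#'   enumeration.
#' @param n_mc Monte-Carlo permutation count for large problems.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return p-value in (0, 1], with attributes \code{mode}
#'   ("exhaustive"/"monte-carlo") and \code{n_assignments}.
#' @export
exactLogrankP <- function(time, event, group, exhaustive_limit = 1e7,
                          n_mc = 1e6, seed = 1) {
  group <- as.logical(group)
  event <- as.logical(event)
  n <- length(time)
  stopifnot(length(event) == n, length(group) == n)
  n_low <- sum(group)
  if (n_low == 0 || n_low == n)
    stop("both groups must be nonempty")
  obs <- logrankStatMatrix(time, event, cbind(as.numeric(group)))
  n_comb <- choose(n, n_low)
  chunkStats <- function(Z) logrankStatMatrix(time, event, Z)
  if (n_comb <= exhaustive_limit) {
    combs <- combn(n, n_low)
    hits <- 0
    chunk <- 100000L
    for (s in seq(1L, ncol(combs), by = chunk)) {
      e <- min(s + chunk - 1L, ncol(combs))
      Z <- matrix(0, n, e - s + 1L)
      Z[cbind(as.vector(combs[, s:e]),
              rep(seq_len(e - s + 1L), each = n_low))] <- 1
      hits <- hits + sum(chunkStats(Z) >= obs - 1e-12)
    }
    p <- hits / n_comb
    structure(p, mode = "exhaustive", n_assignments = n_comb)
  } else {
    withSeed(seed, {
      hits <- 0
      chunk <- 50000L
      done <- 0
      while (done < n_mc) {
        b <- min(chunk, n_mc - done)
        Z <- vapply(seq_len(b), function(i) {
          z <- numeric(n); z[sample.int(n, n_low)] <- 1; z
        }, numeric(n))
        hits <- hits + sum(chunkStats(Z) >= obs - 1e-12)
        done <- done + b
      }
      p <- (hits + 1) / (n_mc + 1)
      structure(p, mode = "monte-carlo", n_assignments = n_mc)
    })
  }
}

#' Optimal-cutoff survival split with a minimum group size
#'
#' Dichotomizes patients by a gene's expression at the cutoff that
#' minimizes the asymptotic log-rank p-value, under the constraint that
#' both groups keep at least \code{min_group_size} patients. Candidate
#' cutoffs are the midpoints between consecutive sorted unique expression
#' values (deterministic and invariant to patient order and to monotone
#' noise); the low group is \code{expression <= cutoff}; p-value ties are
#' broken toward the smaller cutoff. No selection-bias correction is
#' applied to the reported p-value.
#'
#' @param expression per-patient numeric expression of one gene.
#' @param months,event survival data aligned with \code{expression}.
#' @param min_group_size minimum patients per group.
#' @return list of class \code{"SurvivalSplit"}: \code{feasible},
#'   \code{cutoff}, \code{low} (logical membership), \code{n_low},
#'   \code{n_high}, \code{p_approx}, \code{chisq}, \code{cutoffs_tried};
#'   when no cutoff satisfies the constraint, \code{feasible = FALSE}.
#' @export
optimalCutoffLogrank <- function(expression, months, event,
                                 min_group_size = 8) {
  n <- length(expression)
  stopifnot(length(months) == n, length(event) == n)
  if (n < 2 * min_group_size)
    stop("cohort smaller than twice the minimum group size")
  u <- sort(unique(expression))
  cuts <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else numeric(0)
  feasible_cuts <- cuts[vapply(cuts, function(cv) {
    nl <- sum(expression <= cv)
    nl >= min_group_size && (n - nl) >= min_group_size
  }, logical(1))]
  if (!length(feasible_cuts))
    return(structure(list(feasible = FALSE, cutoff = NA_real_, low = NULL,
                          n_low = NA_integer_, n_high = NA_integer_,
                          p_approx = NA_real_, chisq = NA_real_,
                          cutoffs_tried = 0L),
                     class = "SurvivalSplit"))
  Z <- vapply(feasible_cuts, function(cv) as.numeric(expression <= cv),
              numeric(n))
  chisq <- logrankStatMatrix(months, as.logical(event), Z)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  best <- which(p <= min(p) + 1e-15)[1L]   # ties -> smaller cutoff
  low <- expression <= feasible_cuts[best]
  structure(list(feasible = TRUE, cutoff = feasible_cuts[best], low = low,
                 n_low = sum(low), n_high = sum(!low),
                 p_approx = p[best], chisq = chisq[best],
                 cutoffs_tried = length(feasible_cuts)),
            class = "SurvivalSplit")
}

#' @export
print.SurvivalSplit <- function(x, ...) {
  if (!x$feasible) cat("SurvivalSplit: infeasible (no cutoff satisfies the",
                       "group-size constraint)\n")
  else cat("SurvivalSplit: cutoff", signif(x$cutoff, 4), "->",
           x$n_low, "low /", x$n_high, "high, log-rank p",
           signif(x$p_approx, 3), "\n")
  invisible(x)
}
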