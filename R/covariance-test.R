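# Covariance test for predictors entering the lasso path.
#
# For a variable j entering the path at knot lambda_k with active set A
# (the variables already active before the entry), the statistic
#   T_j = ( <y, X b(lambda_{k+1})> - <y, X_A b_A(lambda_{k+1})> ) / sigma^2
# compares the fit of the full path solution at the next knot with the
# solution refit on A alone; under the null that all signal variables are
# already in A, T_j is asymptotically Exp(1), giving p = exp(-T_j).
# Knots are taken from a dense glmnet lambda grid (first index at which a
# coefficient becomes nonzero).

# sigma^2 estimate: OLS residual variance on the full design when n
# comfortably exceeds p, else the df-corrected residual variance of the
# cross-validated lasso fit itself.
estimateSigma2 <- function(X, y, beta_cv, df_cv) {
  n <- nrow(X)
  p <- ncol(X)
  if (n > p + 10) {
    fit <- stats::lm.fit(cbind(1, X), y)
    sum(fit$residuals^2) / (n - p - 1)
  } else {
    res <- y - beta_cv
    max(sum(res^2) / max(n - df_cv - 1, 1), 1e-12)
  }
}

# Named numeric coefficient vector (without intercept) from a glmnet fit.
coefVector <- function(fit, s) {
  m <- predict(fit, type = "coefficients", s = s, exact = FALSE)
  setNames(as.numeric(m), rownames(m))[-1]
}

# Covariance-test p-values for the variables active at lambda_cv.
# X: n x p numeric matrix with column names; y: numeric response.
# A tight convergence threshold is essential: solver noise above sigma^2
# inflates the statistic when residual variance is small.
covarianceTestP <- function(X, y, lambda_cv, sigma2, nlambda = 150,
                            thresh = 1e-9) {
  # the path only needs to extend slightly past the CV-selected lambda
  cr <- suppressWarnings(as.numeric(cor(X, y)))
  n <- length(y)
  lam_max <- max(abs(cr), na.rm = TRUE) * sd(y) * (n - 1) / n
  ratio <- max(min(1e-3, 0.5 * lambda_cv / lam_max), 1e-6)
  path <- glmnet(X, y, nlambda = nlambda, lambda.min.ratio = ratio,
                 standardize = TRUE, thresh = thresh)
  lam <- path$lambda
  B <- as.matrix(path$beta)  # p x n_lambda
  entry <- apply(B != 0, 1L, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  # variables with nonzero coefficient at lambda_cv
  b_cv <- coefVector(path, lambda_cv)
  sel <- names(b_cv)[b_cv != 0]
  pvals <- setNames(rep(NA_real_, length(sel)), sel)
  if (!length(sel)) return(pvals)

  entry_lam <- setNames(lam[entry], rownames(B))
  knots <- sort(unique(entry_lam[!is.na(entry_lam)]), decreasing = TRUE)
  yc <- y - mean(y)
  for (j in sel) {
    lam_k <- entry_lam[[j]]
    if (is.na(lam_k)) { pvals[j] <- 1; next }
    nxt <- knots[knots < lam_k]
    lam_next <- if (length(nxt)) nxt[1L] else min(lam)
    full <- as.numeric(predict(path, newx = X, s = lam_next,
                               exact = FALSE))
    # restricted set includes variables entering at the same grid knot:
    # with a discrete lambda grid, simultaneous entrants must not each be
    # credited the whole group's improvement
    A <- names(entry_lam)[!is.na(entry_lam) & entry_lam >= lam_k]
    A <- setdiff(A, j)
    restricted <- if (length(A) >= 1) {
      # glmnet needs >= 2 columns; pad with a zero column if necessary
      XA <- X[, A, drop = FALSE]
      if (ncol(XA) == 1L) XA <- cbind(XA, .pad = 0)
      lam_seq <- sort(unique(c(lam_k, lam_next)), decreasing = TRUE)
      if (length(lam_seq) == 1L) lam_seq <- c(lam_seq, lam_seq / 2)
      fitA <- glmnet(XA, y, lambda = lam_seq, standardize = TRUE,
                     thresh = 1e-12)
      as.numeric(predict(fitA, newx = XA, s = lam_next, exact = FALSE))
    } else rep(mean(y), length(y))
    Tj <- (sum(yc * (full - mean(full))) -
             sum(yc * (restricted - mean(restricted)))) / sigma2
    pvals[j] <- exp(-max(Tj, 0))
  }
  pvals
}
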