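#' Parameters for regulatory-network inference
#'
#' @param cv_folds folds for cross-validated lasso (lambda at minimum CV
#'   error, favoring recall).
#' @param p_cutoff covariance-test selection p-value cutoff for predictors;
#'   1e-3 keeps only links whose significance is near zero while remaining
#'   attainable at desk-scale sample sizes.
#' @param local_gene_cutoff local-regulator pruning window: predictors on
#'   the target's chromosome within this many positions in the chromosomal
#'   gene order are discarded as likely copy-number co-passengers.
#' @param min_mean_expression minimum mean (count-like scale) for a gene to
#'   enter the model universe.
#' @return list of class \code{"NetworkInferenceParams"}.
#' @export
networkInferenceParams <- function(cv_folds = 10, p_cutoff = 1e-3,
                                   local_gene_cutoff = 50,
                                   min_mean_expression = 1) {
  stopifnot(cv_folds >= 3, p_cutoff > 0, p_cutoff <= 1,
            local_gene_cutoff >= 0, min_mean_expression >= 0)
  structure(list(cv_folds = as.integer(cv_folds), p_cutoff = p_cutoff,
                 local_gene_cutoff = as.integer(local_gene_cutoff),
                 min_mean_expression = min_mean_expression),
            class = "NetworkInferenceParams")
}

#' Filter genes by expression level and variability
#'
#' Keeps genes whose mean across patients is at least \code{min_mean}
#' (count-like scale, e.g. normalized RSEM counts) and drops rows with zero
#' variance (constant or nearly silent genes carry no signal for network
#' inference).
#'
#' @param mat nonnegative numeric matrix, genes x samples.
#' @param min_mean minimum row mean.
#' @return character vector of retained gene ids.
#' @export
filterExpressedGenes <- function(mat, min_mean = 1) {
  if (any(mat < 0, na.rm = TRUE))
    stop("expression for filtering must be on a nonnegative count-like scale")
  mu <- rowMeans(mat, na.rm = TRUE)
  v <- apply(mat, 1L, var, na.rm = TRUE)
  rownames(mat)[mu >= min_mean & v > 0]
}

#' Fit the sparse linear model of one gene
#'
#' Models a target gene's expression across a cohort as a linear
#' combination of its own copy number and the expression of all other
#' genes. The lasso (all predictors standardized; the copy-number predictor
#' penalized like any other) is tuned by cross-validation at minimum CV
#' error, and each selected predictor receives a significance p-value from
#' the covariance test on the lasso path; only expression predictors below
#' \code{p_cutoff} are kept.
#'
#' @param target gene id (must be a row of \code{expression}).
#' @param expression genes x samples numeric matrix.
#' @param copy_number genes x samples numeric matrix (log2-ratio scale),
#'   same dimnames.
#' @param params [networkInferenceParams()].
#' @param foldid optional integer vector of CV fold assignments (for
#'   deterministic, order-independent fits); defaults to a round-robin
#'   assignment.
#' @return list of class \code{"GeneModel"}: \code{target},
#'   \code{intercept}, \code{cn_coefficient}, \code{predictors} (data.frame
#'   regulator/coefficient/p_value), \code{cv_lambda}, \code{sigma2}.
#' @export
fitGeneModel <- function(target, expression, copy_number, params =
                           networkInferenceParams(), foldid = NULL) {
  if (!target %in% rownames(expression))
    stop("target gene not in expression matrix: ", target)
  n <- ncol(expression)
  if (n < max(30, params$cv_folds * 3))
    stop("need at least max(30, 3*cv_folds) samples; got ", n)
  y <- expression[target, ]
  if (sd(y) == 0)
    stop("degenerate input: target ", target, " has constant expression")
  others <- setdiff(rownames(expression), target)
  cn_col <- paste0("CN:", target)
  X <- cbind(copy_number[target, ], t(expression[others, , drop = FALSE]))
  colnames(X) <- c(cn_col, others)
  if (is.null(foldid)) foldid <- rep_len(seq_len(params$cv_folds), n)

  cv <- cv.glmnet(X, y, foldid = foldid, standardize = TRUE)
  lam <- cv$lambda.min
  bmat <- predict(cv$glmnet.fit, type = "coefficients", s = lam,
                  exact = FALSE)
  bfull <- setNames(as.numeric(bmat), rownames(bmat))
  intercept <- bfull[1]
  b <- bfull[-1]
  active <- names(b)[b != 0]
  pred_cv <- as.numeric(predict(cv$glmnet.fit, newx = X, s = lam,
                                exact = FALSE))
  sigma2 <- estimateSigma2(X, y, pred_cv, df_cv = length(active))
  pv <- if (length(active))
    covarianceTestP(X, y, lambda_cv = lam, sigma2 = sigma2) else
    setNames(numeric(0), character(0))

  cn_coef <- if (cn_col %in% active) unname(b[cn_col]) else 0
  keep <- setdiff(active, cn_col)
  keep <- keep[!is.na(pv[keep]) & pv[keep] < params$p_cutoff]
  structure(list(
    target = target,
    intercept = unname(intercept),
    cn_coefficient = cn_coef,
    cn_p_value = if (cn_col %in% names(pv)) unname(pv[cn_col]) else NA_real_,
    predictors = data.frame(regulator = keep,
                            coefficient = unname(b[keep]),
                            p_value = unname(pv[keep]),
                            stringsAsFactors = FALSE),
    cv_lambda = lam,
    sigma2 = sigma2), class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel for", x$target, ":", nrow(x$predictors),
      "predictors, cn coefficient", signif(x$cn_coefficient, 3),
      ", lambda", signif(x$cv_lambda, 3), "\n")
  invisible(x)
}

# 0-based position of each gene in the (chrom, start) sort.
geneOrderIndex <- function(annotation) {
  ord <- order(annotation$chrom, annotation$start)
  idx <- integer(nrow(annotation))
  idx[ord] <- seq_len(nrow(annotation)) - 1L
  setNames(idx, annotation$gene_id)
}

#' Prune local regulators from a gene model
#'
#' Predictors located on the same chromosome as the target and within
#' \code{local_gene_cutoff} positions in the chromosomal gene order are
#' removed: such links are typically driven by shared copy-number segments
#' rather than regulation. The copy-number coefficient is untouched;
#' predictors exactly at the cutoff distance are removed, one position
#' beyond is kept.
#'
#' @param model a \code{"GeneModel"} from [fitGeneModel()].
#' @param annotation data.frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} covering all genes in the model.
#' @param local_gene_cutoff window size in gene-order positions.
#' @return the pruned \code{"GeneModel"}.
#' @export
pruneLocalRegulators <- function(model, annotation, local_gene_cutoff = 50) {
  pr <- model$predictors
  if (!nrow(pr)) return(model)
  genes_needed <- c(model$target, pr$regulator)
  if (!all(genes_needed %in% annotation$gene_id))
    stop("annotation must cover the target and all predictors")
  chrom <- setNames(annotation$chrom, annotation$gene_id)
  idx <- geneOrderIndex(annotation)
  same_chr <- chrom[pr$regulator] == chrom[[model$target]]
  local <- same_chr &
    abs(idx[pr$regulator] - idx[[model$target]]) <= local_gene_cutoff
  model$predictors <- pr[!local, , drop = FALSE]
  rownames(model$predictors) <- NULL
  model
}

#' Assemble per-gene models into a signed regulatory network
#'
#' Creates a directed edge (regulator -> target) for every surviving
#' predictor of every model; the edge sign is "activator" for positive and
#' "inhibitor" for negative coefficients.
#'
#' @param models list of \code{"GeneModel"} objects.
#' @param genes optional gene universe (defaults to all targets and
#'   regulators seen).
#' @return a [RegulatoryNetwork-class] object.
#' @export
assembleNetwork <- function(models, genes = NULL) {
  if (length(models)) names(models) <-
    vapply(models, function(m) m$target, character(1))
  edge_list <- lapply(models, function(m) {
    if (!nrow(m$predictors)) return(NULL)
    data.frame(regulator = m$predictors$regulator, target = m$target,
               coefficient = m$predictors$coefficient,
               p_value = m$predictors$p_value, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edge_list)
  if (is.null(edges))
    edges <- data.frame(regulator = character(), target = character(),
                        coefficient = numeric(), p_value = numeric(),
                        stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$coefficient > 0, "activator", "inhibitor")
  edges <- edges[, c("regulator", "target", "coefficient", "sign",
                     "p_value")]
  rownames(edges) <- NULL
  if (is.null(genes))
    genes <- sort(unique(c(edges$regulator, edges$target,
                           names(models))))
  new("RegulatoryNetwork", genes = genes, edges = edges, models = models)
}

#' Infer a regulatory network for a whole gene universe
#'
#' Runs [fitGeneModel()] for every gene, prunes local regulators and
#' assembles the signed network. Per-target fits are independent; fold
#' assignments are derived deterministically from \code{seed} so results do
#' not depend on execution order.
#'
#' @param expression,copy_number genes x samples matrices on matching rows.
#' @param annotation gene annotation (for local-regulator pruning).
#' @param params [networkInferenceParams()].
#' @param seed integer seed controlling CV fold assignment.
#' @param verbose print a progress note every 50 genes.
#' @return a [RegulatoryNetwork-class] object.
#' @export
inferRegulatoryNetwork <- function(expression, copy_number, annotation,
                                   params = networkInferenceParams(),
                                   seed = 1, verbose = FALSE) {
  genes <- rownames(expression)
  n <- ncol(expression)
  foldid <- withSeed(seed, sample(rep_len(seq_len(params$cv_folds), n)))
  models <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    m <- fitGeneModel(genes[i], expression, copy_number, params,
                      foldid = foldid)
    models[[i]] <- pruneLocalRegulators(m, annotation,
                                        params$local_gene_cutoff)
    if (verbose && i %% 50 == 0)
      message("fitted ", i, "/", length(genes), " gene models")
  }
  assembleNetwork(models, genes = genes)
}

#' Evaluate a network's predictive power on held-out data
#'
#' Applies each gene's linear model to held-out expression and copy-number
#' matrices and scores it by the Pearson correlation between predicted and
#' observed expression across the held-out samples. Genes without a model
#' (or with degenerate predictions) get weight 0.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param expression,copy_number held-out genes x samples matrices
#'   (disjoint from the training cohort).
#' @return named numeric vector of per-gene correlation weights.
#' @export
evaluatePredictivePower <- function(network, expression, copy_number) {
  genes <- networkGenes(network)
  models <- geneModels(network)
  w <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    m <- models[[g]]
    if (is.null(m)) next
    if (!nrow(m$predictors) && m$cn_coefficient == 0) next
    pred <- rep(m$intercept, ncol(expression))
    if (m$cn_coefficient != 0 && g %in% rownames(copy_number))
      pred <- pred + m$cn_coefficient * copy_number[g, ]
    for (k in seq_len(nrow(m$predictors))) {
      reg <- m$predictors$regulator[k]
      if (reg %in% rownames(expression))
        pred <- pred + m$predictors$coefficient[k] * expression[reg, ]
    }
    if (sd(pred) > 0 && g %in% rownames(expression) &&
        sd(expression[g, ]) > 0)
      w[g] <- cor(pred, expression[g, ])
  }
  w
}
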