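#' Ground-truth gene regulatory network for simulation
#'
#' Container for a generative linear network model: genes with chromosomal
#' annotation, a signed regulator-to-target coefficient matrix \code{W}
#' (rows = regulators, columns = targets, zero diagonal, spectral radius
#' strictly below 1 so the simultaneous system is solvable), per-gene
#' copy-number dosage coefficients and per-gene noise standard deviations.
#' Expression is generated as \code{x = (I - W')^{-1} (beta * c + eps)}.
#'
#' @slot genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, sorted by (chrom, start).
#' @slot W numeric matrix of regulator-to-target linear coefficients.
#' @slot cn_coefficients named numeric, effect of a gene's own copy number
#'   (log2-ratio scale) on its own expression.
#' @slot noise_sd named numeric, per-gene residual standard deviation.
#' @slot density requested edge density (fraction of off-diagonal entries).
#'
#' @seealso [generateGroundTruthNetwork()]
#' @export
setClass("GroundTruthNetwork",
  representation(
    genes = "data.frame",
    W = "matrix",
    cn_coefficients = "numeric",
    noise_sd = "numeric",
    density = "numeric"
  )
)

setValidity("GroundTruthNetwork", function(object) {
  msg <- character()
  n <- nrow(object@genes)
  if (!all(c("gene_id", "chrom", "start", "end") %in% colnames(object@genes)))
    msg <- c(msg, "genes must have gene_id, chrom, start, end")
  if (!identical(dim(object@W), c(n, n)))
    msg <- c(msg, "W must be n_genes x n_genes")
  else {
    if (any(diag(object@W) != 0))
      msg <- c(msg, "diagonal of W must be zero")
    if (spectralRadius(object@W) >= 1)
      msg <- c(msg, "spectral radius of W must be strictly < 1")
  }
  if (length(object@cn_coefficients) != n || length(object@noise_sd) != n)
    msg <- c(msg, "cn_coefficients and noise_sd must match gene count")
  if (any(object@noise_sd < 0)) msg <- c(msg, "noise_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground-truth record of planted drivers, markers and hazard effects
#'
#' @slot drivers data.frame with columns \code{gene_id} and \code{direction}
#'   ("up" or "down"): the planted radioresistance driver genes.
#' @slot markers character, planted radioresistance marker genes (disjoint
#'   from the drivers).
#' @slot hazard_coefficients named numeric, per-driver log-hazard effect of
#'   one standard deviation of expression on relapse.
#' @slot seed integer seed the record was drawn with.
#'
#' @seealso [makeTruthRecord()]
#' @export
setClass("SyntheticTruthRecord",
  representation(
    drivers = "data.frame",
    markers = "character",
    hazard_coefficients = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticTruthRecord", function(object) {
  msg <- character()
  if (!all(c("gene_id", "direction") %in% colnames(object@drivers)))
    msg <- c(msg, "drivers must have gene_id and direction")
  else {
    if (!all(object@drivers$direction %in% c("up", "down")))
      msg <- c(msg, "driver direction must be 'up' or 'down'")
    if (any(object@drivers$gene_id %in% object@markers))
      msg <- c(msg, "drivers and markers must be disjoint")
    if (!all(names(object@hazard_coefficients) == object@drivers$gene_id))
      msg <- c(msg, "hazard_coefficients must be named by the driver genes")
  }
  if (length(msg)) msg else TRUE
})

#' Inferred signed gene regulatory network
#'
#' Directed signed network assembled from per-gene sparse linear models:
#' an edge (regulator -> target, coefficient) for every predictor surviving
#' the lasso significance filter and local-regulator pruning, plus the
#' per-target models themselves (intercept, own-copy-number coefficient,
#' selected expression predictors).
#'
#' @slot genes character, the modeled gene universe.
#' @slot edges data.frame with columns \code{regulator}, \code{target},
#'   \code{coefficient}, \code{sign} ("activator"/"inhibitor"),
#'   \code{p_value}.
#' @slot models named list of per-target gene models (see [fitGeneModel()]).
#'
#' @seealso [assembleNetwork()], [inferRegulatoryNetwork()]
#' @export
setClass("RegulatoryNetwork",
  representation(
    genes = "character",
    edges = "data.frame",
    models = "list"
  )
)

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("regulator", "target", "coefficient", "sign", "p_value")
  if (!all(need %in% colnames(ed)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  else if (nrow(ed)) {
    if (any(ed$regulator == ed$target))
      msg <- c(msg, "self-loops are not allowed")
    sgn <- ifelse(ed$coefficient > 0, "activator", "inhibitor")
    if (!all(ed$sign == sgn))
      msg <- c(msg, "edge sign must match coefficient sign")
    if (!all(c(ed$regulator, ed$target) %in% object@genes))
      msg <- c(msg, "edge endpoints must lie in the gene universe")
    if (any(ed$p_value < 0 | ed$p_value > 1, na.rm = TRUE))
      msg <- c(msg, "edge p-values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Network-propagation impact matrix
#'
#' For each candidate gene (row), the absolute impact its observed expression
#' alteration exerts on every network gene (column) through all directed
#' walks up to the configured maximum length, with every traversed node
#' down-weighted by its predictive-power weight.
#'
#' @slot impacts nonnegative numeric matrix, candidates x genes.
#' @slot node_weights named numeric in [0, 1], per-gene predictive-power
#'   weights applied at every node entered along a walk.
#' @slot source_signals named numeric, the candidates' observed cell-line
#'   expression log2-ratios.
#' @slot params list of propagation parameters (see [propagationParams()]),
#'   plus the convergence diagnostic \code{tail_norm} (max-norm of the
#'   longest retained walk term).
#'
#' @seealso [computeImpactMatrix()]
#' @export
setClass("ImpactMatrix",
  representation(
    impacts = "matrix",
    node_weights = "numeric",
    source_signals = "numeric",
    params = "list"
  )
)

setValidity("ImpactMatrix", function(object) {
  msg <- character()
  if (any(object@impacts < 0)) msg <- c(msg, "impacts must be >= 0")
  if (any(object@node_weights < 0 | object@node_weights > 1))
    msg <- c(msg, "node weights must lie in [0, 1]")
  if (nrow(object@impacts) != length(object@source_signals))
    msg <- c(msg, "one source signal per candidate row required")
  if (length(msg)) msg else TRUE
})

#' Patient cohort with pre-treatment expression and relapse follow-up
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay
#' \code{"expression"} (genes x patients) and clinical follow-up in
#' \code{colData}: \code{months} (disease-free survival time to relapse or
#' censoring), \code{event} (relapse observed), \code{irradiated}
#' (adjuvant radiation received), and the prognostic covariates \code{age},
#' \code{t_stage}, \code{gleason}, \code{psa}.
#'
#' @seealso [PatientCohort()], [simulatePatientCohort()]
#' @export
setClass("PatientCohort", contains = "SummarizedExperiment")

setValidity("PatientCohort", function(object) {
  msg <- character()
  need <- c("months", "event", "irradiated", "age", "t_stage", "gleason",
            "psa")
  cd <- colData(object)
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else {
    if (any(cd$months < 0, na.rm = TRUE))
      msg <- c(msg, "months must be >= 0")
    if (!is.logical(cd$event) || !is.logical(cd$irradiated))
      msg <- c(msg, "event and irradiated must be logical")
  }
  if (!"expression" %in% names(object@assays))
    msg <- c(msg, "assay 'expression' required")
  if (length(msg)) msg else TRUE
})

#' Construct a PatientCohort
#'
#' @param expression numeric matrix, genes x patients, with row and column
#'   names.
#' @param clinical data.frame with one row per patient (matching the
#'   expression columns) and columns \code{months}, \code{event},
#'   \code{irradiated}, \code{age}, \code{t_stage}, \code{gleason},
#'   \code{psa}.
#' @return A [PatientCohort-class] object.
#' @examples
#' expr <- matrix(rnorm(20), 4, 5,
#'                dimnames = list(paste0("g", 1:4), paste0("p", 1:5)))
#' clin <- data.frame(months = 1:5, event = c(TRUE, FALSE, TRUE, TRUE, FALSE),
#'                    irradiated = TRUE, age = 65, t_stage = 2L,
#'                    gleason = 7L, psa = 10)
#' PatientCohort(expr, clin)
#' @export
PatientCohort <- function(expression, clinical) {
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression matrix must carry gene and patient names")
  if (nrow(clinical) != ncol(expression))
    stop("clinical table must have one row per expression column")
  rownames(clinical) <- colnames(expression)
  se <- SummarizedExperiment(
    assays = list(expression = expression),
    colData = DataFrame(clinical)
  )
  new("PatientCohort", se)
}
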