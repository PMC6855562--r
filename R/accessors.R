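# Accessors and show methods for the core classes.

#' @describeIn RegulatoryNetwork-class modeled gene universe
#' @param object a radregnet S4 object
#' @export
setGeneric("networkGenes", function(object) standardGeneric("networkGenes"))

#' @describeIn RegulatoryNetwork-class signed edge table
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @describeIn RegulatoryNetwork-class named list of per-target gene models
#' @export
setGeneric("geneModels", function(object) standardGeneric("geneModels"))

#' @describeIn GroundTruthNetwork-class signed regulator-to-target
#'   coefficient matrix
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))

#' @describeIn GroundTruthNetwork-class per-gene copy-number dosage
#'   coefficients
#' @export
setGeneric("cnCoefficients", function(object) standardGeneric("cnCoefficients"))

#' @describeIn GroundTruthNetwork-class gene annotation table
#' @export
setGeneric("geneAnnotation", function(object) standardGeneric("geneAnnotation"))

#' @describeIn SyntheticTruthRecord-class planted drivers with direction
#' @export
setGeneric("trueDrivers", function(object) standardGeneric("trueDrivers"))

#' @describeIn SyntheticTruthRecord-class planted marker gene ids
#' @export
setGeneric("markerGenes", function(object) standardGeneric("markerGenes"))

#' @describeIn ImpactMatrix-class candidate-by-gene absolute impact matrix
#' @export
setGeneric("impactValues", function(object) standardGeneric("impactValues"))

#' @describeIn ImpactMatrix-class per-gene predictive-power node weights
#' @export
setGeneric("nodeWeights", function(object) standardGeneric("nodeWeights"))

#' @describeIn PatientCohort-class clinical follow-up table
#' @export
setGeneric("clinicalTable", function(object) standardGeneric("clinicalTable"))

#' @export
setMethod("networkGenes", "RegulatoryNetwork", function(object) object@genes)
#' @export
setMethod("networkGenes", "GroundTruthNetwork",
          function(object) object@genes$gene_id)
#' @export
setMethod("networkEdges", "RegulatoryNetwork", function(object) object@edges)
#' @export
setMethod("geneModels", "RegulatoryNetwork", function(object) object@models)
#' @export
setMethod("edgeWeights", "GroundTruthNetwork", function(object) object@W)
#' @export
setMethod("cnCoefficients", "GroundTruthNetwork",
          function(object) object@cn_coefficients)
#' @export
setMethod("geneAnnotation", "GroundTruthNetwork", function(object) object@genes)
#' @export
setMethod("trueDrivers", "SyntheticTruthRecord", function(object) object@drivers)
#' @export
setMethod("markerGenes", "SyntheticTruthRecord", function(object) object@markers)
#' @export
setMethod("impactValues", "ImpactMatrix", function(object) object@impacts)
#' @export
setMethod("nodeWeights", "ImpactMatrix", function(object) object@node_weights)
#' @export
setMethod("clinicalTable", "PatientCohort",
          function(object) as.data.frame(colData(object)))

setMethod("show", "GroundTruthNetwork", function(object) {
  n <- nrow(object@genes)
  m <- sum(object@W != 0)
  cat("GroundTruthNetwork:", n, "genes on",
      length(unique(object@genes$chrom)), "chromosomes,", m, "edges (",
      sum(object@W < 0), "inhibitory ), spectral radius",
      signif(spectralRadius(object@W), 3), "\n")
})

setMethod("show", "SyntheticTruthRecord", function(object) {
  cat("SyntheticTruthRecord:", nrow(object@drivers), "drivers (",
      sum(object@drivers$direction == "up"), "up /",
      sum(object@drivers$direction == "down"), "down ),",
      length(object@markers), "markers, seed", object@seed, "\n")
})

setMethod("show", "RegulatoryNetwork", function(object) {
  ed <- object@edges
  cat("RegulatoryNetwork:", length(object@genes), "genes,", nrow(ed),
      "edges (", sum(ed$sign == "activator"), "activator /",
      sum(ed$sign == "inhibitor"), "inhibitor ),",
      length(object@models), "gene models\n")
})

setMethod("show", "ImpactMatrix", function(object) {
  cat("ImpactMatrix:", nrow(object@impacts), "candidates x",
      ncol(object@impacts), "genes; max path length",
      object@params$max_path_length, "; tail norm",
      signif(object@params$tail_norm, 3), "\n")
})

#' In- and out-degree table of a regulatory network
#'
#' @param network a [RegulatoryNetwork-class] object.
#' @return data.frame with columns \code{gene_id}, \code{in_degree},
#'   \code{out_degree}; degrees sum to the edge count.
#' @export
degreeTable <- function(network) {
  stopifnot(is(network, "RegulatoryNetwork"))
  ed <- networkEdges(network)
  g <- networkGenes(network)
  data.frame(
    gene_id = g,
    in_degree = as.integer(table(factor(ed$target, levels = g))),
    out_degree = as.integer(table(factor(ed$regulator, levels = g))),
    stringsAsFactors = FALSE
  )
}
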