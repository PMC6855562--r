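#' Study-condition presets for the synthetic generator
#'
#' Two fixed parameter sets used throughout the package's validation:
#'
#' \describe{
#'   \item{strong}{A strong-signal study for recovery benchmarks: 100 genes
#'     on 10 chromosomes at 2% edge density, edge weights 0.4-0.9 (about
#'     4-9x the residual noise sd of 0.1), a CNA-rich cohort of 400
#'     patients (per-chromosome segment probability 0.8, segment shifts
#'     sd 0.8, 2-6 genes long).}
#'   \item{full}{The end-to-end study: the strong-signal conditions at the
#'     300-gene desk scale (enough genes for stable quantile normalization
#'     and HMM estimation), with strongly hazard-linked drivers.}
#'   \item{desk}{The default desk-scale study: 300 genes on 10 chromosomes
#'     at 2% density with the generator's default noise and CNA burden,
#'     300 patients.}
#' }
#'
#' @param preset "strong", "full" or "desk".
#' @param seed integer seed; the network, cohort and record seeds are
#'   derived from it.
#' @param n_patients override the preset's cohort size.
#' @return list with \code{truth} ([GroundTruthNetwork-class]),
#'   \code{record} ([SyntheticTruthRecord-class]) and \code{cohort} (the
#'   [simulatePatientCohort()] result).
#' @export
syntheticStudy <- function(preset = c("strong", "full", "desk"), seed = 1,
                           n_patients = NULL) {
  preset <- match.arg(preset)
  if (preset %in% c("strong", "full")) {
    # edge density is tied to edge strength: the spectral-radius rescale
    # divides all weights by roughly the mean degree, so keeping the
    # average out-degree near 2 keeps individual edges strong
    n_genes <- if (preset == "strong") 100 else 300
    truth <- generateGroundTruthNetwork(
      n_genes = n_genes, n_chromosomes = 10,
      density = 2 / (n_genes - 1),
      frac_inhibitor = 0.03, weight_range = c(0.4, 0.9),
      noise_sd = 0.1, seed = seed)
    cohort <- simulatePatientCohort(
      truth, n_patients = if (is.null(n_patients)) 400 else n_patients,
      cna_sd = 0.8, p_segment = 0.8, seg_genes = c(2, 6), seed = seed + 1)
  } else {
    truth <- generateGroundTruthNetwork(
      n_genes = 300, n_chromosomes = 10, density = 0.02, seed = seed)
    cohort <- simulatePatientCohort(
      truth, n_patients = if (is.null(n_patients)) 300 else n_patients,
      seed = seed + 1)
  }
  record <- makeTruthRecord(truth, n_drivers = 4, n_markers = 4,
                            hazard_effect = if (preset == "desk") 1 else 2,
                            seed = seed + 2)
  list(truth = truth, record = record, cohort = cohort)
}

#' Compare an inferred network to a planted ground truth
#'
#' @param network a [RegulatoryNetwork-class].
#' @param truth a [GroundTruthNetwork-class].
#' @return list with directed-edge \code{precision}, \code{recall},
#'   \code{sign_agreement} (on correctly recovered edges), \code{n_edges}
#'   and \code{n_true_edges}.
#' @export
edgeRecovery <- function(network, truth) {
  W <- edgeWeights(truth)
  te <- which(W != 0, arr.ind = TRUE)
  tk <- paste(rownames(W)[te[, 1]], colnames(W)[te[, 2]])
  ed <- networkEdges(network)
  fk <- paste(ed$regulator, ed$target)
  m <- match(fk, tk)
  ok <- !is.na(m)
  list(precision = if (nrow(ed)) mean(ok) else NA_real_,
       recall = mean(tk %in% fk),
       sign_agreement = if (any(ok))
         mean(sign(ed$coefficient[ok]) ==
                sign(W[te[m[ok], , drop = FALSE]])) else NA_real_,
       n_edges = nrow(ed), n_true_edges = length(tk))
}
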