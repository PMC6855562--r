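# Readers/writers for the interchange formats: SEG segments, BED-like gene
# annotation, expression/clinical TSV tables, the network edge list and the
# synthetic-truth JSON. All tabular files are tab-separated with a header
# row, decimal text, no locale formatting; SEG coordinates are 1-based
# inclusive.

#' Read a SEG file of segmented copy-number profiles
#'
#' Expected columns: \code{sample}, \code{chrom}, \code{start}, \code{end},
#' \code{n_probes}, \code{log2_ratio} (1-based inclusive coordinates).
#' Malformed rows (non-numeric coordinates, end < start) are reported with
#' their line numbers.
#'
#' @param path file path.
#' @return data.frame of segment records.
#' @export
readSeg <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "chrom", "start", "end", "n_probes", "log2_ratio")
  if (!all(need %in% colnames(df)))
    stop("SEG file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$end < df$start)
  if (length(bad))
    stop("malformed SEG records (end < start or non-numeric coordinates) ",
         "at line(s): ", paste(bad + 1L, collapse = ", "))
  df
}

#' Write a SEG file
#' @param segments data.frame as returned by [readSeg()].
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeSeg <- function(segments, path) {
  need <- c("sample", "chrom", "start", "end", "n_probes", "log2_ratio")
  stopifnot(all(need %in% colnames(segments)))
  out <- segments[, need]
  out$log2_ratio <- sprintf("%.17g", out$log2_ratio)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene annotation table
#'
#' Columns \code{chrom}, \code{start}, \code{end}, \code{gene_id}
#' (1-based inclusive, matching the SEG convention).
#' @param path file path.
#' @return data.frame with gene_id, chrom, start, end.
#' @export
readGeneAnnotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% colnames(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("annotation rows with start >= end at line(s): ",
         paste(bad + 1L, collapse = ", "))
  df[, c("gene_id", "chrom", "start", "end")]
}

#' Write a BED-like gene annotation table
#' @param annotation data.frame with gene_id, chrom, start, end.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  write.table(annotation[, c("chrom", "start", "end", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix as TSV
#'
#' Gene rows, sample columns, header row; the first column holds gene ids.
#' @param path file path.
#' @return numeric matrix with gene row names.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readExpressionMatrix
#' @param mat numeric matrix, genes x samples.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   apply(mat, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical follow-up table as TSV
#'
#' Columns: \code{patient_id}, \code{months}, \code{event},
#' \code{irradiated}, \code{age}, \code{t_stage}, \code{gleason},
#' \code{psa}.
#' @param path file path.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "months", "event", "irradiated", "age",
            "t_stage", "gleason", "psa")
  if (!all(need %in% colnames(df)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  df$event <- as.logical(df$event)
  df$irradiated <- as.logical(df$irradiated)
  df
}

#' @rdname readClinicalTable
#' @param clinical data.frame.
#' @export
writeClinicalTable <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a regulatory network as an edge-list TSV
#'
#' Columns \code{regulator}, \code{target}, \code{coefficient},
#' \code{sign}, \code{p_value}; coefficients and p-values are written as
#' decimal text at full double precision so a round trip is exact.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeRegulatoryNetwork <- function(network, path) {
  ed <- networkEdges(network)
  out <- data.frame(regulator = ed$regulator, target = ed$target,
                    coefficient = sprintf("%.17g", ed$coefficient),
                    sign = ed$sign,
                    p_value = sprintf("%.17g", ed$p_value),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulatory network edge-list TSV
#'
#' Validates that every edge's recorded sign matches its coefficient sign.
#' @param path file path.
#' @param genes optional gene universe (defaults to the genes seen in the
#'   edge list).
#' @return a [RegulatoryNetwork-class] (without per-gene models).
#' @export
readRegulatoryNetwork <- function(path, genes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(regulator = "character",
                                  target = "character",
                                  coefficient = "numeric",
                                  sign = "character",
                                  p_value = "numeric"))
  need <- c("regulator", "target", "coefficient", "sign", "p_value")
  if (!all(need %in% colnames(df)))
    stop("network file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df)) {
    expect_sign <- ifelse(df$coefficient > 0, "activator", "inhibitor")
    bad <- which(df$sign != expect_sign)
    if (length(bad))
      stop("sign column inconsistent with coefficient sign at line(s): ",
           paste(bad + 1L, collapse = ", "))
  }
  if (is.null(genes))
    genes <- sort(unique(c(df$regulator, df$target)))
  new("RegulatoryNetwork", genes = genes,
      edges = df[, need], models = list())
}

#' Write / read the synthetic ground truth as JSON
#'
#' Serializes the planted truth (drivers with direction and hazard
#' coefficients, markers, network edges) for test harnesses.
#' @param truth a [GroundTruthNetwork-class].
#' @param record a [SyntheticTruthRecord-class].
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeTruthJson <- function(truth, record, path) {
  W <- edgeWeights(truth)
  nz <- which(W != 0, arr.ind = TRUE)
  edges <- data.frame(regulator = rownames(W)[nz[, 1]],
                      target = colnames(W)[nz[, 2]],
                      weight = W[nz], stringsAsFactors = FALSE)
  write_json(list(
    genes = geneAnnotation(truth),
    edges = edges,
    cn_coefficients = as.list(cnCoefficients(truth)),
    drivers = trueDrivers(record),
    markers = markerGenes(record),
    hazard_coefficients = as.list(record@hazard_coefficients),
    seed = record@seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
  read_json(path, simplifyVector = TRUE)
}
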