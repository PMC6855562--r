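#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common distribution: each column's
#' sorted values are replaced by the row-wise mean of all sorted columns,
#' preserving within-column ranks. Delegates to
#' \code{limma::normalizeQuantiles}. Missing values are an error; impute
#' before normalizing (e.g. by row medians, see
#' [averageLogRatioProfile()]).
#'
#' @param mat numeric matrix, genes x samples (log2 intensities), >= 2
#'   columns.
#' @return normalized matrix with the input's dimnames.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantileNormalize(m)  # both columns become (2.5, 3.5, 4.5)
#' @export
quantileNormalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("'mat' must be a numeric matrix")
  if (ncol(mat) < 2L) stop("need at least 2 samples to quantile normalize")
  if (anyNA(mat))
    stop("missing values present; impute before quantile normalization")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Chromosomally ordered average expression log2-ratio profile
#'
#' Per gene, the mean over resistant replicates minus the mean over
#' sensitive replicates (both on log2 scale), ordered along the genome by
#' (chromosome, start) and split into one sequence per chromosome — the
#' input layout the differential-expression HMM expects. Genes absent from
#' the annotation are excluded with a warning. Missing replicate values are
#' imputed by the gene's row median within each condition before averaging.
#'
#' @param resistant,sensitive numeric matrices, genes x replicates, sharing
#'   row names (>= 1 replicate each).
#' @param annotation data.frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @return list with \code{profiles} (named list of per-chromosome named
#'   numeric vectors) and \code{table} (data.frame gene_id, chrom, start,
#'   log2_ratio in chromosomal order).
#' @export
averageLogRatioProfile <- function(resistant, sensitive, annotation) {
  if (is.null(rownames(resistant)) || is.null(rownames(sensitive)))
    stop("replicate matrices must carry gene row names")
  if (!identical(rownames(resistant), rownames(sensitive)))
    stop("replicate matrices must share the same gene rows")
  imputeRow <- function(m) {
    if (anyNA(m)) {
      med <- apply(m, 1L, median, na.rm = TRUE)
      idx <- which(is.na(m), arr.ind = TRUE)
      m[idx] <- med[idx[, 1L]]
    }
    m
  }
  resistant <- imputeRow(as.matrix(resistant))
  sensitive <- imputeRow(as.matrix(sensitive))
  ratio <- rowMeans(resistant) - rowMeans(sensitive)

  known <- names(ratio) %in% annotation$gene_id
  if (any(!known))
    warning(sum(!known), " genes absent from annotation excluded")
  ratio <- ratio[known]
  ann <- annotation[match(names(ratio), annotation$gene_id), ]
  ord <- order(ann$chrom, ann$start)
  ann <- ann[ord, ]
  ratio <- ratio[ord]
  tab <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                    start = ann$start, log2_ratio = as.numeric(ratio),
                    stringsAsFactors = FALSE)
  profiles <- lapply(split(seq_len(nrow(tab)), tab$chrom), function(i)
    setNames(tab$log2_ratio[i], tab$gene_id[i]))
  list(profiles = profiles, table = tab)
}

#' Select direct driver candidates from joint copy-number and expression calls
#'
#' A gene is a direct candidate when its copy-number and expression calls
#' agree in direction: reduced copy number with underexpression ("down") or
#' increased copy number with overexpression ("up"). Genes altered in both
#' layers but in opposite directions are counted and reported, not
#' returned.
#'
#' @param cn data.frame from [callCopyNumberStates()].
#' @param de data.frame from [decodeDeStates()].
#' @return data.frame with columns \code{gene_id}, \code{direction}
#'   ("up"/"down"), \code{cn_state}, \code{de_state}, \code{cn_log2_ratio},
#'   \code{de_log2_ratio}; counts of same- and opposite-direction genes in
#'   attributes \code{"n_same_direction"} and \code{"n_opposite_direction"}.
#' @export
selectDirectCandidates <- function(cn, de) {
  if (!all(c("gene_id", "state") %in% colnames(cn)) ||
      !all(c("gene_id", "state") %in% colnames(de)))
    stop("cn and de must carry gene_id and state columns")
  common <- intersect(cn$gene_id, de$gene_id)
  cn2 <- cn[match(common, cn$gene_id), ]
  de2 <- de[match(common, de$gene_id), ]
  up <- cn2$state == "increased" & de2$state == "over"
  down <- cn2$state == "reduced" & de2$state == "under"
  opposite <- (cn2$state == "increased" & de2$state == "under") |
    (cn2$state == "reduced" & de2$state == "over")
  keep <- up | down
  out <- data.frame(
    gene_id = common[keep],
    direction = ifelse(up[keep], "up", "down"),
    cn_state = as.character(cn2$state[keep]),
    de_state = as.character(de2$state[keep]),
    cn_log2_ratio = cn2$log2_ratio[keep],
    de_log2_ratio = de2$log2_ratio[keep],
    stringsAsFactors = FALSE)
  attr(out, "n_same_direction") <- sum(keep)
  attr(out, "n_opposite_direction") <- sum(opposite)
  out
}
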