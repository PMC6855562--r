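#' Map segmented copy-number profiles to genes
#'
#' Assigns each annotated gene a log2-ratio by overlapping its chromosomal
#' location with the segmented profile: the overlap-length-weighted mean of
#' all overlapping segments' log2-ratios. Genes without any overlapping
#' segment are returned as \code{NA}. Coordinates in both inputs are 1-based
#' inclusive (SEG convention); overlap arithmetic is delegated to
#' GenomicRanges.
#'
#' @param segments SEG-style data.frame with columns \code{sample},
#'   \code{chrom}, \code{start}, \code{end}, \code{log2_ratio} (see
#'   [readSeg()]). Segments must not overlap within a sample.
#' @param annotation data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @return If the segments carry one sample, a named numeric vector of
#'   per-gene log2-ratios; for several samples, a genes x samples matrix.
#' @examples
#' seg <- data.frame(sample = "s1", chrom = "chr1", start = 1, end = 1000,
#'                   n_probes = 10, log2_ratio = -0.5)
#' ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 100, end = 200)
#' mapSegmentsToGenes(seg, ann)
#' @export
mapSegmentsToGenes <- function(segments, annotation) {
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% colnames(segments)))
    stop("segments must have columns: ", paste(need, collapse = ", "))
  if (!all(c("gene_id", "chrom", "start", "end") %in% colnames(annotation)))
    stop("annotation must have gene_id, chrom, start, end")
  seg_chr <- unique(segments$chrom)
  ann_chr <- unique(annotation$chrom)
  missing_chr <- setdiff(ann_chr, seg_chr)
  if (length(missing_chr) && nrow(segments))
    warning("annotation chromosomes absent from segments: ",
            paste(missing_chr, collapse = ", "))

  genes_gr <- GRanges(annotation$chrom,
                      IRanges(annotation$start, annotation$end))
  samples <- unique(segments$sample)
  res <- matrix(NA_real_, nrow(annotation), length(samples),
                dimnames = list(annotation$gene_id, samples))
  for (s in samples) {
    seg_s <- segments[segments$sample == s, , drop = FALSE]
    if (!nrow(seg_s)) next
    seg_gr <- GRanges(seg_s$chrom, IRanges(seg_s$start, seg_s$end))
    hits <- findOverlaps(genes_gr, seg_gr)
    if (!length(hits)) next
    ov <- width(pintersect(genes_gr[queryHits(hits)],
                           seg_gr[subjectHits(hits)]))
    val <- seg_s$log2_ratio[subjectHits(hits)]
    wsum <- tapply(ov * val, queryHits(hits), sum)
    wtot <- tapply(ov, queryHits(hits), sum)
    res[as.integer(names(wsum)), s] <- as.numeric(wsum / wtot)
  }
  if (length(samples) == 1L) res[, 1L] else res
}

#' Call trinary gene copy-number states at a log2-ratio cutoff
#'
#' A gene is called \code{reduced} if its log2-ratio is strictly below
#' \code{-cutoff}, \code{increased} if strictly above \code{+cutoff}, and
#' \code{unchanged} otherwise (values exactly at the cutoff are unchanged).
#' Missing log2-ratios are called unchanged and reported.
#'
#' @param log2_ratio named numeric vector of per-gene log2-ratios (from
#'   [mapSegmentsToGenes()]).
#' @param cutoff positive absolute log2-ratio cutoff; 0.1 distinguishes even
#'   moderate subclonal dosage shifts in cell-line contrasts.
#' @return data.frame with columns \code{gene_id}, \code{log2_ratio},
#'   \code{state} (factor reduced/unchanged/increased), with state counts in
#'   attribute \code{"state_counts"}.
#' @examples
#' callCopyNumberStates(c(a = -0.5, b = 0, c = 0.3))
#' @export
callCopyNumberStates <- function(log2_ratio, cutoff = 0.1) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("'cutoff' must be a single positive number")
  n_missing <- sum(is.na(log2_ratio))
  if (n_missing)
    message(n_missing, " genes without copy-number value called 'unchanged'")
  state <- rep("unchanged", length(log2_ratio))
  state[!is.na(log2_ratio) & log2_ratio < -cutoff] <- "reduced"
  state[!is.na(log2_ratio) & log2_ratio > cutoff] <- "increased"
  state <- factor(state, levels = c("reduced", "unchanged", "increased"))
  out <- data.frame(
    gene_id = if (is.null(names(log2_ratio)))
      as.character(seq_along(log2_ratio)) else names(log2_ratio),
    log2_ratio = as.numeric(log2_ratio),
    state = state,
    stringsAsFactors = FALSE)
  attr(out, "state_counts") <- table(state)
  attr(out, "cutoff") <- cutoff
  out
}

#' Exact test for gene-set overlap
#'
#' Tests whether two gene sets drawn from a common universe overlap more
#' than expected by chance, by the exact hypergeometric tail
#' (\code{sided = "greater"}, the default: all enrichment uses in this
#' pipeline are over-representation tests) or the two-sided Fisher test on
#' the 2x2 table.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of
#'   \code{universe}.
#' @param universe character vector, the common gene universe.
#' @param sided "greater" or "two".
#' @return list with \code{overlap}, \code{odds_ratio}, \code{p_value} and
#'   the underlying 2x2 \code{table}.
#' @examples
#' u <- paste0("g", 1:100)
#' setOverlapFisher(u[1:20], u[11:40], u)
#' @export
setOverlapFisher <- function(set_a, set_b, universe,
                             sided = c("greater", "two")) {
  sided <- match.arg(sided)
  if (!length(universe)) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("set_a and set_b must be subsets of the universe")
  N <- length(unique(universe))
  a <- length(set_a); b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  tab <- matrix(c(k, a - k, b - k, N - a - b + k), 2, 2,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  p <- if (sided == "greater")
    phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  else
    fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], .Machine$double.eps)
  list(overlap = k, odds_ratio = or, p_value = min(p, 1), table = tab)
}

#' Hypergeometric overlap test from printed counts
#'
#' Convenience form of [setOverlapFisher()] for the case where only the
#' 2x2 counts are known (overlap, set sizes, universe size) rather than the
#' gene identities.
#'
#' @param overlap number of genes in both sets.
#' @param size_a,size_b set sizes.
#' @param universe_size universe size.
#' @param sided "greater" or "two".
#' @return p-value.
#' @examples
#' overlapFisherFromCounts(389, 6109, 765, 24625)
#' @export
overlapFisherFromCounts <- function(overlap, size_a, size_b, universe_size,
                                    sided = c("greater", "two")) {
  sided <- match.arg(sided)
  if (sided == "greater")
    phyper(overlap - 1, size_a, universe_size - size_a, size_b,
           lower.tail = FALSE)
  else
    fisher.test(matrix(c(overlap, size_a - overlap, size_b - overlap,
                         universe_size - size_a - size_b + overlap),
                       2, 2))$p.value
}
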