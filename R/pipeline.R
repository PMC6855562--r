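#' Build and validate a pipeline configuration
#'
#' Collects every stage parameter in one validated list. Unknown keys are
#' rejected; every parameter is echoed into the run log by [runPipeline()].
#' Input slots accept either in-memory objects or file paths (paths are
#' read with the package's own readers).
#'
#' @param annotation gene annotation (data.frame or TSV path).
#' @param segments SEG records for the cell-line contrast (data.frame or
#'   path).
#' @param resistant,sensitive replicate expression matrices (matrix or
#'   path).
#' @param cohort_expression,cohort_copy_number cohort matrices used for
#'   network inference (matrix or path); ignored when \code{network} is
#'   given.
#' @param network optional pre-built [RegulatoryNetwork-class] or edge-list
#'   TSV path; when present, network inference is skipped.
#' @param clinical optional clinical table (data.frame or path); when
#'   absent the pipeline stops after the impact stage.
#' @param marker_genes character vector of radioresistance marker gene ids.
#' @param cna_cutoff absolute log2-ratio cutoff for copy-number calls.
#' @param hmm_means initial HMM state means (under, unchanged, over).
#' @param cv_folds,p_cutoff,local_gene_cutoff network-inference parameters.
#' @param holdout_frac fraction of cohort patients held out to estimate
#'   predictive-power node weights.
#' @param max_path_length propagation walk-length truncation.
#' @param n_permutations degree-preserving permutation count for the null.
#' @param q_cutoff impact-significance q-value cutoff.
#' @param min_group_size survival-split group-size constraint.
#' @param alpha log-rank selection level.
#' @param seed single global seed; per-stage seeds are fanned out
#'   deterministically.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(annotation, segments, resistant, sensitive,
                           cohort_expression = NULL,
                           cohort_copy_number = NULL, network = NULL,
                           clinical = NULL, marker_genes,
                           cna_cutoff = 0.1,
                           hmm_means = c(-1.25, 0, 1.25),
                           cv_folds = 10, p_cutoff = 1e-3,
                           local_gene_cutoff = 50, holdout_frac = 0.2,
                           max_path_length = 5, n_permutations = 10,
                           q_cutoff = 0.01, min_group_size = 8,
                           alpha = 0.05, seed = 1) {
  cfg <- list(annotation = annotation, segments = segments,
              resistant = resistant, sensitive = sensitive,
              cohort_expression = cohort_expression,
              cohort_copy_number = cohort_copy_number, network = network,
              clinical = clinical, marker_genes = marker_genes,
              cna_cutoff = cna_cutoff, hmm_means = hmm_means,
              cv_folds = cv_folds, p_cutoff = p_cutoff,
              local_gene_cutoff = local_gene_cutoff,
              holdout_frac = holdout_frac,
              max_path_length = max_path_length,
              n_permutations = n_permutations, q_cutoff = q_cutoff,
              min_group_size = min_group_size, alpha = alpha, seed = seed)
  stopifnot(cfg$cna_cutoff > 0, length(cfg$hmm_means) == 3,
            cfg$n_permutations >= 2, cfg$q_cutoff > 0, cfg$alpha > 0,
            cfg$min_group_size >= 1, cfg$max_path_length >= 1)
  if (is.null(cfg$network) &&
      (is.null(cfg$cohort_expression) || is.null(cfg$cohort_copy_number)))
    stop("either a network or cohort matrices for inference are required")
  if (!is.null(cfg$clinical) && is.null(cfg$cohort_expression))
    stop("the transfer stage needs cohort_expression alongside clinical")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys are
#' rejected. Input slots hold file paths (resolved relative to the YAML
#' file's directory).
#'
#' @param path YAML file path.
#' @return list of class \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  raw <- read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  base <- dirname(normalizePath(path))
  path_keys <- c("annotation", "segments", "resistant", "sensitive",
                 "cohort_expression", "cohort_copy_number", "network",
                 "clinical")
  for (k in intersect(path_keys, names(raw)))
    if (is.character(raw[[k]]) && !file.exists(raw[[k]]))
      raw[[k]] <- file.path(base, raw[[k]])
  do.call(pipelineConfig, raw)
}

resolveInput <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full driver-nomination pipeline
#'
#' Chains the stages end to end: copy-number calling on the cell-line
#' contrast, quantile normalization and HMM differential-expression calling
#' on the replicate matrices, direct-candidate selection, regulatory
#' network inference (or loading), network-propagation impact scoring of
#' candidates on the marker genes against the degree-preserving permutation
#' null, and — when a clinical table is present — transfer to patient
#' relapse data via constrained optimal-cutoff survival splitting. Every
#' stage logs its input/output counts and every configured parameter is
#' echoed into the log; identical configuration and seed reproduce
#' identical outputs.
#'
#' @param config a \code{"PipelineConfig"} from [pipelineConfig()].
#' @param out_dir optional directory; when given, the result tables, the
#'   network and the run log are written there with the package's writers.
#' @return list with \code{cn_calls}, \code{de_calls}, \code{candidates},
#'   \code{network}, \code{node_weights}, \code{impact_table},
#'   \code{marker_table} (NULL when no clinical table), and \code{log}.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- character()
  note <- function(...) {
    line <- paste0(...)
    log <<- c(log, line)
    message(line)
  }
  scalar_keys <- c("cna_cutoff", "cv_folds", "p_cutoff",
                   "local_gene_cutoff", "holdout_frac", "max_path_length",
                   "n_permutations", "q_cutoff", "min_group_size", "alpha",
                   "seed")
  note("pipeline parameters: ",
       paste(vapply(scalar_keys, function(k)
         paste0(k, "=", paste(config[[k]], collapse = ",")),
         character(1)), collapse = "; "),
       "; hmm_means=", paste(config$hmm_means, collapse = ","),
       "; marker_genes=", paste(config$marker_genes, collapse = ","))

  ann <- resolveInput(config$annotation, readGeneAnnotation)
  segments <- resolveInput(config$segments, readSeg)
  resistant <- resolveInput(config$resistant, readExpressionMatrix)
  sensitive <- resolveInput(config$sensitive, readExpressionMatrix)

  # --- copy-number stage -------------------------------------------------
  cn_log2 <- mapSegmentsToGenes(segments, ann)
  cn_calls <- callCopyNumberStates(cn_log2, cutoff = config$cna_cutoff)
  cnt <- attr(cn_calls, "state_counts")
  note("cna: ", nrow(segments), " segments -> ", nrow(cn_calls),
       " genes (", cnt[["reduced"]], " reduced, ", cnt[["increased"]],
       " increased)")

  # --- differential-expression stage -------------------------------------
  norm <- quantileNormalize(cbind(resistant, sensitive))
  prof <- averageLogRatioProfile(norm[, colnames(resistant), drop = FALSE],
                                 norm[, colnames(sensitive), drop = FALSE],
                                 ann)
  params0 <- hmmParams(means = config$hmm_means)
  hmm <- fitDeHmm(prof$profiles, init = params0)
  de_calls <- decodeDeStates(prof$profiles, hmm)
  dcnt <- attr(de_calls, "state_counts")
  note("de: ", nrow(de_calls), " genes (", dcnt[["under"]], " under, ",
       dcnt[["over"]], " over); HMM iterations=", length(hmm$loglik))

  candidates <- selectDirectCandidates(cn_calls, de_calls)
  note("candidates: ", nrow(candidates), " same-direction (",
       attr(candidates, "n_opposite_direction"), " opposite-direction)")

  # --- network stage ------------------------------------------------------
  if (!is.null(config$network)) {
    network <- resolveInput(config$network, readRegulatoryNetwork)
    node_weights <- setNames(rep(1, length(networkGenes(network))),
                             networkGenes(network))
    note("network: loaded, ", nrow(networkEdges(network)), " edges")
  } else {
    expr <- resolveInput(config$cohort_expression, readExpressionMatrix)
    cn <- resolveInput(config$cohort_copy_number, readExpressionMatrix)
    n <- ncol(expr)
    holdout <- withSeed(stageSeed(config$seed, "holdout"),
                        sample.int(n, max(2, round(config$holdout_frac * n))))
    train <- setdiff(seq_len(n), holdout)
    network <- inferRegulatoryNetwork(
      expr[, train, drop = FALSE], cn[, train, drop = FALSE], ann,
      params = networkInferenceParams(
        cv_folds = config$cv_folds, p_cutoff = config$p_cutoff,
        local_gene_cutoff = config$local_gene_cutoff),
      seed = stageSeed(config$seed, "network"))
    node_weights <- evaluatePredictivePower(
      network, expr[, holdout, drop = FALSE], cn[, holdout, drop = FALSE])
    note("network: inferred on ", length(train), " patients, ",
         nrow(networkEdges(network)), " edges (",
         sum(networkEdges(network)$sign == "inhibitor"),
         " inhibitor); mean holdout correlation ",
         signif(mean(node_weights), 3))
  }

  # --- impact stage -------------------------------------------------------
  in_net <- candidates$gene_id %in% networkGenes(network)
  note("impact: ", sum(in_net), " of ", nrow(candidates),
       " candidates in the modeled universe")
  signals <- setNames(candidates$de_log2_ratio, candidates$gene_id)[in_net]
  prop_par <- propagationParams(max_path_length = config$max_path_length)
  markers <- intersect(config$marker_genes, networkGenes(network))
  if (!length(markers)) stop("impact stage: no marker genes in the network")
  impact_table <- NULL
  if (length(signals)) {
    impacts <- computeImpactMatrix(network, signals,
                                   pmax(node_weights, 0), prop_par)
    orig <- scoreCandidateImpacts(impacts, markers)
    permuted <- lapply(seq_len(config$n_permutations), function(k) {
      pnet <- permuteNetworkDegreePreserving(
        network, seed = stageSeed(config$seed, "permute") + k)
      pim <- computeImpactMatrix(pnet, signals, pmax(node_weights, 0),
                                 prop_par)
      scoreCandidateImpacts(pim, markers)
    })
    impact_table <- testImpactSignificance(orig, permuted,
                                           q_cutoff = config$q_cutoff)
    impact_table <- merge(candidates[, c("gene_id", "direction",
                                         "de_log2_ratio")],
                          impact_table, by = "gene_id", sort = FALSE)
    note("impact: ", sum(impact_table$significant), " candidates with q < ",
         config$q_cutoff, " against ", config$n_permutations,
         " permuted networks")
  } else note("impact: no candidates to propagate")

  # --- transfer stage -----------------------------------------------------
  marker_table <- NULL
  if (is.null(config$clinical)) {
    note("transfer: no clinical table configured; ",
         "pipeline stops after the impact stage")
  } else if (!is.null(impact_table) && any(impact_table$significant)) {
    clin <- resolveInput(config$clinical, readClinicalTable)
    expr_pat <- resolveInput(config$cohort_expression, readExpressionMatrix)
    rownames(clin) <- clin$patient_id
    cohort <- PatientCohort(
      expr_pat[, clin$patient_id, drop = FALSE],
      clin[, c("months", "event", "irradiated", "age", "t_stage",
               "gleason", "psa")])
    drivers <- impact_table[impact_table$significant,
                            c("gene_id", "direction")]
    marker_table <- transferCandidates(
      drivers, cohort, min_group_size = config$min_group_size,
      alpha = config$alpha, seed = stageSeed(config$seed, "transfer"))
    note("transfer: ", attr(marker_table, "n_consistent"),
         " consistent candidates, ", sum(marker_table$selected),
         " markers at approximate log-rank p < ", config$alpha)
  } else note("transfer: no significant impact candidates to transfer")

  result <- list(cn_calls = cn_calls, de_calls = de_calls,
                 candidates = candidates, network = network,
                 node_weights = node_weights, impact_table = impact_table,
                 marker_table = marker_table, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeTsv <- function(df, f)
      write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    writeTsv(cn_calls, "cn_calls.tsv")
    writeTsv(de_calls, "de_calls.tsv")
    writeTsv(candidates, "candidates.tsv")
    if (!is.null(impact_table)) writeTsv(impact_table, "impact_table.tsv")
    if (!is.null(marker_table)) writeTsv(marker_table, "marker_table.tsv")
    writeRegulatoryNetwork(network, file.path(out_dir, "network.tsv"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  result
}
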