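#' Run the full inference-to-perturbation workflow
#'
#' Orchestrates the pipeline on the three standard input files: binarize
#' the expression, fit the probabilistic rules, search for
#' pseudo-attractors from the discretized cluster means (plus optional
#' random restarts), assign attractors to clusters, scan all single-TF
#' perturbations, and classify master regulators/destabilizers. All
#' outputs are written under `outDir` together with a run manifest
#' (JSON) holding the seeds, configuration snapshot, input digests and
#' package version needed to reproduce the run bit-exactly.
#'
#' @param expressionPath,networkPath,labelsPath input files (see
#'   [loadInputs()]); `labelsPath` may be NULL, in which case attractor
#'   search uses random restarts only.
#' @param outDir output directory.
#' @param search a [SearchConfig-class].
#' @param walk a [WalkConfig-class].
#' @param seed master seed; expands to named sub-seeds (binarize,
#'   restarts, walks) recorded in the manifest. Overrides the config
#'   seeds.
#' @param randomRestarts also run [randomRestartSearch()] and merge the
#'   results (default TRUE when no labels are given).
#' @return invisibly, a list with all intermediate objects (`binarized`,
#'   `rules`, `attractors`, `scores`, `perCluster`, `masters`,
#'   `manifest`).
#' @export
runWorkflow <- function(expressionPath, networkPath, labelsPath = NULL,
                        outDir = ".", search = searchConfig(),
                        walk = walkConfig(), seed = 0L,
                        randomRestarts = is.null(labelsPath)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  seeds <- list(
    binarize = deriveSeed(seed, 11L),
    restarts = deriveSeed(seed, 12L),
    walks = deriveSeed(seed, 13L)
  )
  inputs <- loadInputs(expressionPath, networkPath, labelsPath)
  be <- binarizeExpression(inputs$expression, seed = seeds$binarize)
  ruleset <- fitRules(inputs$network, be)
  writeRules(ruleset, file.path(outDir, "rules"))
  writeMixtureParameters(be, file.path(outDir, "mixture_parameters.csv"))

  references <- NULL
  attractors <- NULL
  if (!is.null(inputs$labels)) {
    references <- discretizeClusterMeans(be, inputs$labels, inputs$network)
    found <- list()
    seen <- character(0)
    for (cl in names(references)) {
      aset <- findPseudoAttractors(ruleset, references[[cl]], search)
      for (a in aset@attractors) {
        key <- paste(a$members, collapse = "|")
        if (!key %in% seen) {
          seen <- c(seen, key)
          found[[length(found) + 1L]] <- a
        }
      }
    }
    attractors <- orderAttractors(new(
      "PseudoAttractorSet", nodes = networkNodes(inputs$network),
      attractors = found, threshold = search@threshold
    ))
  }
  if (randomRestarts) {
    rsearch <- search
    rsearch@seed <- seeds$restarts
    extra <- randomRestartSearch(ruleset, rsearch)
    if (is.null(attractors)) {
      attractors <- extra
    } else {
      seen <- vapply(attractors@attractors, function(a) {
        paste(a$members, collapse = "|")
      }, character(1))
      for (a in extra@attractors) {
        if (!paste(a$members, collapse = "|") %in% seen) {
          attractors@attractors[[length(attractors@attractors) + 1L]] <- a
        }
      }
      attractors <- orderAttractors(attractors)
    }
  }
  if (!is.null(references)) {
    attractors <- assignAttractors(attractors, references)
  }
  writeAttractors(attractors, file.path(outDir, "attractors.csv"))

  scores <- NULL; perCluster <- NULL; masters <- NULL
  if (nAttractors(attractors) > 0) {
    wcfg <- walk
    wcfg@seed <- seeds$walks
    scores <- scanPerturbations(ruleset, attractors, wcfg)
    writeScores(scores, file.path(outDir, "scores.csv"))
    perCluster <- clusterScores(scores)
    if (nrow(perCluster) > 0) {
      utils::write.csv(perCluster,
                       file.path(outDir, "cluster_scores.csv"),
                       row.names = FALSE)
      masters <- classifyMasters(perCluster)
    }
  }

  manifest <- list(
    command = "run-all",
    version = as.character(utils::packageVersion("booleabayes")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    seeds = seeds,
    config = list(
      radius = search@radius, threshold = search@threshold,
      nRandomStarts = search@nRandomStarts,
      escapeRadius = walk@escapeRadius, nWalks = walk@nWalks,
      maxSteps = walk@maxSteps
    ),
    inputs = manifestDigests(c(expressionPath, networkPath, labelsPath))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(binarized = be, rules = ruleset, attractors = attractors,
                 scores = scores, perCluster = perCluster,
                 masters = masters, manifest = manifest))
}

manifestDigests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  lapply(stats::setNames(paths, basename(unlist(paths))), function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
}

#' Write the three standard input files for a synthetic dataset
#'
#' Emits `expression.tsv`, `network.tsv` and `labels.csv` for a dataset
#' from [simulateDataset()], plus `truth.json` recording the generating
#' fixed points (the ground truth is synthetic and labelled as such).
#'
#' @param spec a [syntheticSpec()].
#' @param outDir output directory.
#' @return invisibly, the `simulateDataset()` result.
#' @export
writeSyntheticInputs <- function(spec = syntheticSpec(), outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulateDataset(spec)
  mat <- SummarizedExperiment::assay(ds$expression, "exprs")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, file.path(outDir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(networkEdges(ds$network),
                     file.path(outDir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(data.frame(sample = names(ds$labels),
                              cluster = unname(ds$labels)),
                   file.path(outDir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(synthetic = TRUE,
         fixed_points = ds$fixedPoints,
         cluster_states = lapply(ds$clusterStates, stateToString),
         spec = unclass(spec)),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(ds)
}
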