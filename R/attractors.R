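#' SearchConfig constructor
#'
#' @param radius Hamming radius of the bounded search (default 6).
#' @param threshold pruning threshold P_T (default 0.5).
#' @param nRandomStarts random restarts for [randomRestartSearch()]
#'   (default 200).
#' @param maxVertices STG memory guard (default 3e5 vertices).
#' @param seed integer seed (NA = current RNG).
#' @return a validated [SearchConfig-class].
#' @export
searchConfig <- function(radius = 6L, threshold = 0.5,
                         nRandomStarts = 200L, maxVertices = 300000L,
                         seed = NA_integer_) {
  new("SearchConfig", radius = as.integer(radius),
      threshold = as.numeric(threshold),
      nRandomStarts = as.integer(nRandomStarts),
      maxVertices = as.integer(maxVertices), seed = as.integer(seed))
}

#' Find pseudo-attractors by bounded search
#'
#' Builds the bounded state-transition graph around `initState`, prunes
#' every edge whose flip probability is strictly below the threshold
#' (an edge at exactly the threshold is retained), and returns the
#' strongly connected components that contain no out-of-bounds sink and
#' have no retained edge leaving them. A singleton result is a state where
#' every TF's flip probability is below the threshold — at least a 50%
#' chance (at the default 0.5) of remaining unchanged at every update.
#'
#' @param ruleset a [RuleSet-class].
#' @param initState named binary vector or bitstring.
#' @param config a [SearchConfig-class].
#' @return a [PseudoAttractorSet-class].
#' @examples
#' fx <- bbFixtures()$toggle_switch
#' findPseudoAttractors(fx$rules, c(A = 0L, B = 0L),
#'                      searchConfig(radius = 2))
#' @export
findPseudoAttractors <- function(ruleset, initState,
                                 config = searchConfig()) {
  tg <- buildBoundedSTG(ruleset, initState, config@radius,
                        maxVertices = config@maxVertices)
  gr <- tg@graph
  pruned <- igraph::delete_edges(
    gr, which(igraph::E(gr)$weight < config@threshold)
  )
  comps <- igraph::components(pruned, mode = "strong")
  memb <- comps$membership
  vnames <- names(memb)
  oobComp <- memb[[".oob"]]
  el <- igraph::as_edgelist(pruned, names = TRUE)
  crossing <- memb[el[, 1L]] != memb[el[, 2L]]
  leaky <- unique(memb[el[crossing, 1L]])
  attractors <- list()
  for (cid in seq_len(comps$no)) {
    if (cid == oobComp || cid %in% leaky) next
    members <- sort(vnames[memb == cid])
    attractors[[length(attractors) + 1L]] <- list(
      members = members, representative = members[1L]
    )
  }
  orderAttractors(new("PseudoAttractorSet", nodes = tg@nodes,
                      attractors = attractors,
                      threshold = config@threshold))
}

# Canonical order: by representative bitstring, so the attractor set is
# independent of exploration order.
orderAttractors <- function(aset) {
  if (length(aset@attractors) > 1L) {
    reps <- vapply(aset@attractors, `[[`, character(1), "representative")
    aset@attractors <- aset@attractors[order(reps)]
  }
  aset
}

#' Search from many random initial states
#'
#' Runs [findPseudoAttractors()] from `nRandomStarts` uniformly random
#' initial states and returns the union of the pseudo-attractors found,
#' deduplicated by member-state set. Per-start counts are attached as the
#' `"log"` attribute (start bitstring, attractors found).
#'
#' @param ruleset a [RuleSet-class].
#' @param config a [SearchConfig-class]; `config@seed` makes the restarts
#'   reproducible.
#' @return a [PseudoAttractorSet-class] with a `"log"` attribute.
#' @export
randomRestartSearch <- function(ruleset, config = searchConfig()) {
  nodes <- networkNodes(ruleset@network)
  g <- length(nodes)
  starts <- withSeed(config@seed, {
    matrix(sample(c(0L, 1L), config@nRandomStarts * g, replace = TRUE),
           nrow = config@nRandomStarts)
  })
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  attractors <- list()
  logRows <- vector("list", config@nRandomStarts)
  for (k in seq_len(config@nRandomStarts)) {
    st <- stats::setNames(starts[k, ], nodes)
    aset <- findPseudoAttractors(ruleset, st, config)
    for (a in aset@attractors) {
      key <- paste(a$members, collapse = "|")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        attractors[[length(attractors) + 1L]] <- a
      }
    }
    logRows[[k]] <- data.frame(
      start = stateToString(st),
      n_attractors = length(aset@attractors)
    )
  }
  out <- orderAttractors(new("PseudoAttractorSet", nodes = nodes,
                             attractors = attractors,
                             threshold = config@threshold))
  attr(out, "log") <- do.call(rbind, logRows)
  out
}

#' Discretize per-cluster mean ON-probabilities into initial states
#'
#' For each cluster and each network node, averages the node's per-sample
#' ON-probabilities over the cluster's samples and sets the state bit to 1
#' when the mean exceeds 0.5 (ties go to 0). These discretized cluster
#' means are the canonical initial states for the bounded attractor
#' search.
#'
#' @param be a [BinarizedExperiment-class].
#' @param labels named character vector mapping sample ids to cluster
#'   labels (every labeled sample must be a column of `be`).
#' @param network a [TFNetwork-class]; its nodes define the state order.
#' @return named list of binary state vectors, one per cluster.
#' @export
discretizeClusterMeans <- function(be, labels, network) {
  prob <- onProbabilities(be)
  nodes <- networkNodes(network)
  missing <- setdiff(nodes, rownames(prob))
  if (length(missing) > 0) {
    stop("unknown node: ", paste(missing, collapse = ", "))
  }
  missing <- setdiff(names(labels), colnames(prob))
  if (length(missing) > 0) {
    stop("labeled sample(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  clusters <- sort(unique(labels))
  out <- lapply(clusters, function(cl) {
    ids <- names(labels)[labels == cl]
    if (length(ids) == 0L) stop("empty cluster: ", cl)
    means <- rowMeans(prob[nodes, ids, drop = FALSE])
    stats::setNames(as.integer(means > 0.5), nodes)
  })
  names(out) <- clusters
  out
}

#' Assign pseudo-attractors to clusters by Hamming distance
#'
#' Each attractor's representative state is assigned to the cluster whose
#' reference state is nearest in Hamming distance; ties go to the
#' alphabetically first cluster and are flagged ambiguous. All pairwise
#' distances are stored per attractor for intra/inter-cluster distance
#' summaries.
#'
#' @param attractorSet a [PseudoAttractorSet-class].
#' @param references named list of binary reference states (e.g. from
#'   [discretizeClusterMeans()]).
#' @return the attractor set with `cluster`, `ambiguous` and `distances`
#'   filled in on every attractor.
#' @export
assignAttractors <- function(attractorSet, references) {
  nodes <- attractorSet@nodes
  clusters <- sort(names(references))
  refBits <- lapply(references[clusters], function(r) as.integer(r[nodes]))
  attractorSet@attractors <- lapply(attractorSet@attractors, function(a) {
    bits <- stateFromString(a$representative, nodes)
    d <- vapply(refBits, function(rb) sum(rb != bits), numeric(1))
    best <- which(d == min(d))
    a$cluster <- clusters[best[1L]]
    a$ambiguous <- length(best) > 1L
    a$distances <- as.list(stats::setNames(d, clusters))
    a
  })
  attractorSet
}

#' Deterministic baseline update rules from edge signs
#'
#' Builds deterministic rule vectors from the signed network under one of
#' the two standard coarse-grained update schemes: inhibitory-dominant
#' (the target turns ON only when at least one activator is ON and all
#' inhibitors are OFF) or majority (the target turns ON when strictly more
#' activators than inhibitors are ON). Every edge must carry a `+` or `-`
#' sign. The result is a [RuleSet-class] usable by all downstream
#' operations, for comparison against the fitted probabilistic rules.
#'
#' @param network a [TFNetwork-class] with signed edges.
#' @param scheme `"inhibitory_dominant"` or `"majority"`.
#' @return a [RuleSet-class] with all leaf confidences in `{0, 1}`.
#' @export
baselineRules <- function(network,
                          scheme = c("inhibitory_dominant", "majority")) {
  scheme <- match.arg(scheme)
  ed <- networkEdges(network)
  rules <- lapply(networkNodes(network), function(node) {
    regs <- regulatorsOf(network, node)
    signs <- vapply(regs, function(r) {
      ed$sign[ed$source == r & ed$target == node][1L]
    }, character(1))
    if (any(signs == "?")) {
      stop("unsigned edge into ", node,
           "; baseline schemes need +/- signs on every edge")
    }
    n <- length(regs)
    states <- allStatesMatrix(n)
    act <- signs == "+"
    inh <- signs == "-"
    nActOn <- if (n > 0) states[, act, drop = FALSE] %*% rep(1, sum(act))
              else matrix(0, 1, 1)
    nInhOn <- if (n > 0) states[, inh, drop = FALSE] %*% rep(1, sum(inh))
              else matrix(0, 1, 1)
    v <- if (scheme == "inhibitory_dominant") {
      as.numeric(nActOn >= 1 & nInhOn == 0)
    } else {
      as.numeric(nActOn > nInhOn)
    }
    new("BooleanRule", target = node, regulators = regs, V = v,
        W = matrix(numeric(0), 0L, 2L^n), U = rep(1, 2L^n))
  })
  names(rules) <- networkNodes(network)
  new("RuleSet", network = network, rules = rules)
}

#' Number of pseudo-attractors
#' @param attractorSet a [PseudoAttractorSet-class].
#' @return integer count.
#' @export
nAttractors <- function(attractorSet) length(attractorSet@attractors)

#' Representative states of the attractors
#' @param attractorSet a [PseudoAttractorSet-class].
#' @return character vector of bitstrings.
#' @export
attractorStates <- function(attractorSet) {
  vapply(attractorSet@attractors, `[[`, character(1), "representative")
}

setMethod("show", "PseudoAttractorSet", function(object) {
  cat(sprintf("PseudoAttractorSet: %d attractor(s) over %d TFs (P_T = %g)\n",
              length(object@attractors), length(object@nodes),
              object@threshold))
  for (i in seq_along(object@attractors)) {
    a <- object@attractors[[i]]
    cat(sprintf("  [%d] %s (%d state%s)%s\n", i, a$representative,
                length(a$members), if (length(a$members) > 1) "s" else "",
                if (!is.null(a$cluster)) paste0(" -> ", a$cluster) else ""))
  }
})
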