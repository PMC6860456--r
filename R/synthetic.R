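# Ground-truth generators: random Boolean networks with known fixed
# points, expression data realized from attractor states under bimodal
# Gaussian noise, and small canonical fixtures with analytically known
# behavior.

#' Synthetic-data specification
#'
#' Defaults define the standard recovery conditions: a 12-node network
#' whose fixed points are observed as 4 clusters of 12 samples each, with
#' OFF/ON expression means 1 and 6 and noise SD 0.5 (a 10-sigma
#' separation, so binarization is near-deterministic). A stress preset
#' with `sigma = 1.5` exercises the uncertain regime. The default
#' `maxInDegree = 5` keeps rule inference partially constrained (2^5 = 32
#' leaves per rule against 4 observed states) with in-degree well below
#' the node count, the regime the method is designed for.
#'
#' @param nNodes number of network nodes (>= 2).
#' @param maxInDegree maximum regulators per node.
#' @param nClusters number of attractor-clusters to realize.
#' @param samplesPerCluster samples drawn per cluster.
#' @param muOff,muOn expression means of the OFF and ON components
#'   (muOn > muOff).
#' @param sigma noise standard deviation (> 0).
#' @param seed integer seed.
#' @return validated list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nNodes = 12L, maxInDegree = 5L, nClusters = 4L,
                          samplesPerCluster = 12L, muOff = 1, muOn = 6,
                          sigma = 0.5, seed = 0L) {
  spec <- list(
    nNodes = as.integer(nNodes), maxInDegree = as.integer(maxInDegree),
    nClusters = as.integer(nClusters),
    samplesPerCluster = as.integer(samplesPerCluster),
    muOff = muOff, muOn = muOn, sigma = sigma, seed = as.integer(seed)
  )
  if (spec$nNodes < 2L) stop("nNodes must be >= 2")
  if (spec$muOn <= spec$muOff) stop("muOn must exceed muOff")
  if (spec$sigma <= 0) stop("sigma must be positive")
  if (spec$maxInDegree < 1L) stop("maxInDegree must be >= 1")
  class(spec) <- "SyntheticSpec"
  spec
}

#' Fixed points of a deterministic rule set
#'
#' Exhaustively enumerates all 2^g states and returns those where every
#' gene's rule output (rounded to a hard call) equals its current value,
#' i.e. the fixed points of the asynchronous dynamics.
#'
#' @param ruleset a [RuleSet-class] with (near-)deterministic leaf
#'   confidences; network size at most 20.
#' @return character vector of fixed-point bitstrings, in node order.
#' @export
deterministicFixedPoints <- function(ruleset) {
  nodes <- networkNodes(ruleset@network)
  g <- length(nodes)
  states <- allStatesMatrix(g)
  stable <- rep(TRUE, nrow(states))
  for (i in seq_len(g)) {
    rule <- ruleset@rules[[nodes[i]]]
    ri <- match(rule@regulators, nodes)
    leaf <- if (length(ri) == 0L) rep(1L, nrow(states)) else
      as.integer(states[, ri, drop = FALSE] %*%
                   leafBitWeights(length(ri))) + 1L
    out <- round(rule@V[leaf])
    stable <- stable & (out == states[, i])
  }
  apply(states[stable, , drop = FALSE], 1L, paste, collapse = "")
}

#' Generate a random Boolean network with known fixed points
#'
#' Draws a random directed graph with bounded in-degree and random
#' deterministic truth tables, resampling until the asynchronous dynamics
#' have at least `minFixedPoints` fixed points (verified by exhaustive
#' enumeration, so `nNodes` is capped at 12 unless `allowLarge`).
#'
#' @param spec a [syntheticSpec()].
#' @param minFixedPoints resample until this many fixed points exist
#'   (default 1).
#' @param maxTries resampling budget.
#' @param allowLarge permit nNodes > 12 (the exhaustive check then still
#'   runs, up to the hard limit of 20).
#' @return list with `network` ([TFNetwork-class]), `rules` (deterministic
#'   [RuleSet-class]) and `fixedPoints` (bitstrings).
#' @export
randomBooleanNetwork <- function(spec, minFixedPoints = 1L,
                                 maxTries = 5000L, allowLarge = FALSE) {
  if (spec$nNodes > 12L && !allowLarge) {
    stop("nNodes above the exhaustive-check bound (12); ",
         "set allowLarge = TRUE to override")
  }
  nodes <- sprintf("G%02d", seq_len(spec$nNodes))
  withSeed(spec$seed, {
    for (try in seq_len(maxTries)) {
      src <- list()
      for (nd in nodes) {
        k <- sample.int(spec$maxInDegree, 1L)
        src[[nd]] <- sample(nodes, k)
      }
      edges <- data.frame(
        source = unlist(src, use.names = FALSE),
        target = rep(nodes, vapply(src, length, integer(1))),
        sign = "?", stringsAsFactors = FALSE
      )
      network <- TFNetwork(nodes, edges)
      rules <- lapply(nodes, function(nd) {
        regs <- regulatorsOf(network, nd)
        nl <- 2L^length(regs)
        new("BooleanRule", target = nd, regulators = regs,
            V = as.numeric(sample(c(0L, 1L), nl, replace = TRUE)),
            W = matrix(numeric(0), 0L, nl), U = rep(1, nl))
      })
      names(rules) <- nodes
      ruleset <- new("RuleSet", network = network, rules = rules)
      fps <- deterministicFixedPoints(ruleset)
      if (length(fps) >= minFixedPoints) {
        return(list(network = network, rules = ruleset, fixedPoints = fps))
      }
    }
    stop("no network with ", minFixedPoints,
         " fixed point(s) found in ", maxTries, " tries")
  })
}

#' Realize attractor states as noisy expression data
#'
#' For each labeled state, draws `samplesPerCluster` samples; each gene's
#' value is Normal(muOn, sigma^2) where the state bit is 1 and
#' Normal(muOff, sigma^2) where it is 0, truncated at zero by redrawing
#' (the input contract is non-negative log-scale expression).
#'
#' @param states named list of binary state vectors (names = cluster
#'   labels), all over the same genes.
#' @param spec a [syntheticSpec()].
#' @return list with `expression` (a `SummarizedExperiment`, assay
#'   `exprs`) and `labels` (named character vector sample -> cluster).
#' @export
expressionFromStates <- function(states, spec) {
  genes <- names(states[[1L]])
  clusters <- names(states)
  if (is.null(clusters) || any(clusters == "")) {
    stop("states must be a named list (names = cluster labels)")
  }
  nPer <- spec$samplesPerCluster
  withSeed(spec$seed, {
    cols <- list()
    labels <- character(0)
    for (cl in clusters) {
      bits <- states[[cl]][genes]
      mu <- ifelse(bits == 1L, spec$muOn, spec$muOff)
      for (s in seq_len(nPer)) {
        x <- stats::rnorm(length(genes), mu, spec$sigma)
        while (any(x < 0)) {
          bad <- x < 0
          x[bad] <- stats::rnorm(sum(bad), mu[bad], spec$sigma)
        }
        id <- sprintf("%s_s%02d", cl, s)
        cols[[id]] <- x
        labels[id] <- cl
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- genes
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat)
    )
    list(expression = se, labels = labels)
  })
}

#' Generate a random Boolean network with planted fixed points
#'
#' Constructs a network guaranteed to have `nPlanted` prescribed fixed
#' points in which every gene takes both values (emulating a network of
#' differentially expressed TFs, bimodal across phenotypes). The planted
#' states are drawn first; each gene then receives random regulators and
#' a random truth table whose entries at the planted states' leaves are
#' pinned to the planted bits (regulator draws that would make two
#' planted states conflict on a shared leaf are rejected and redrawn).
#' All fixed points, planted or emergent, are enumerated exhaustively.
#'
#' @param spec a [syntheticSpec()]; `spec$nClusters` fixed points are
#'   planted.
#' @param maxTries resampling budget.
#' @return list with `network`, `rules` (deterministic [RuleSet-class]),
#'   `planted` (bitstrings of the planted states) and `fixedPoints` (all
#'   fixed points, a superset of `planted`).
#' @export
plantedBooleanNetwork <- function(spec, maxTries = 500L) {
  if (spec$nNodes > 12L) {
    stop("nNodes above the exhaustive-check bound (12)")
  }
  n <- spec$nNodes
  nP <- spec$nClusters
  if (2^n < nP) stop("more planted states than the state space holds")
  nodes <- sprintf("G%02d", seq_len(n))
  withSeed(spec$seed, {
    for (try in seq_len(maxTries)) {
      # planted states: distinct, every gene varying across them
      P <- matrix(sample(c(0L, 1L), nP * n, replace = TRUE), nP, n)
      if (anyDuplicated(apply(P, 1L, paste, collapse = ""))) next
      cs <- colSums(P)
      if (any(cs == 0L | cs == nP)) next
      src <- vector("list", n)
      Vs <- vector("list", n)
      ok <- TRUE
      for (i in seq_len(n)) {
        done <- FALSE
        for (rtry in 1:25) {
          k <- sample.int(spec$maxInDegree, 1L)
          regs <- sort(sample(nodes, k), method = "radix")
          ri <- match(regs, nodes)
          leaves <- as.integer(P[, ri, drop = FALSE] %*%
                                 leafBitWeights(k)) + 1L
          # a shared leaf must not demand two different outputs
          if (anyDuplicated(leaves) &&
              any(tapply(P[, i], leaves, function(x)
                length(unique(x))) > 1L)) next
          v <- sample(c(0L, 1L), 2L^k, replace = TRUE)
          v[leaves] <- P[, i]
          src[[i]] <- regs
          Vs[[i]] <- as.numeric(v)
          done <- TRUE
          break
        }
        if (!done) { ok <- FALSE; break }
      }
      if (!ok) next
      edges <- data.frame(
        source = unlist(src),
        target = rep(nodes, vapply(src, length, integer(1))),
        sign = "?", stringsAsFactors = FALSE
      )
      network <- TFNetwork(nodes, edges)
      rules <- lapply(seq_len(n), function(i) {
        new("BooleanRule", target = nodes[i], regulators = src[[i]],
            V = Vs[[i]], W = matrix(numeric(0), 0L, length(Vs[[i]])),
            U = rep(1, length(Vs[[i]])))
      })
      names(rules) <- nodes
      ruleset <- new("RuleSet", network = network, rules = rules)
      planted <- apply(P, 1L, paste, collapse = "")
      fps <- deterministicFixedPoints(ruleset)
      stopifnot(all(planted %in% fps))
      return(list(network = network, rules = ruleset,
                  planted = sort(planted), fixedPoints = fps))
    }
    stop("no conflict-free planted network found in ", maxTries, " tries")
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper around [plantedBooleanNetwork()] and
#' [expressionFromStates()]: draws a network with `nClusters` planted,
#' gene-varying fixed points and realizes those states as noisy
#' expression clusters. The ground truth (network, deterministic rules,
#' generating states) is returned alongside the observable data.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `network`, `rules`, `fixedPoints` (all fixed
#'   points), `clusterStates` (named list of the generating states),
#'   `expression`, `labels`.
#' @export
simulateDataset <- function(spec = syntheticSpec()) {
  net <- plantedBooleanNetwork(spec)
  nodes <- networkNodes(net$network)
  states <- lapply(net$planted, stateFromString, nodes = nodes)
  names(states) <- sprintf("C%d", seq_along(states))
  dataSpec <- spec
  dataSpec$seed <- deriveSeed(spec$seed, 999L)
  obs <- expressionFromStates(states, dataSpec)
  list(network = net$network, rules = net$rules,
       fixedPoints = net$fixedPoints, clusterStates = states,
       expression = obs$expression, labels = obs$labels)
}

#' Canonical small fixtures
#'
#' Four hand-built networks with analytically known behavior:
#' \describe{
#'   \item{toggle_switch}{two mutually inhibiting genes; exactly two
#'     singleton attractors, `10` and `01`.}
#'   \item{repressilator}{three genes in an inhibition cycle; no fixed
#'     points, one 6-state cyclic attractor.}
#'   \item{self_activator_hub}{a noisy self-sustaining hub driving four
#'     targets (hub rule 0.1/0.9, targets 0.2/0.8); the all-ON and
#'     all-OFF states are singleton pseudo-attractors, and knocking the
#'     hub down strictly shortens the expected escape time from all-ON.}
#'   \item{independent_coinflip}{five unconnected genes with constant rule
#'     0.5; every flip probability is exactly 0.5, so no edge is pruned at
#'     the 0.5 threshold and there are no pseudo-attractors.}
#' }
#'
#' @return named list of fixtures, each with `network`, `rules`, and
#'   `attractors` (known inventory of representative bitstrings; for the
#'   repressilator, the 6 members of the cyclic attractor are listed under
#'   `cycle`).
#' @export
bbFixtures <- function() {
  detRule <- function(target, regulator, v) {
    new("BooleanRule", target = target, regulators = regulator,
        V = v, W = matrix(numeric(0), 0L, length(v)),
        U = rep(1, length(v)))
  }

  # toggle switch: A -| B, B -| A
  tsNet <- TFNetwork(c("A", "B"), data.frame(
    source = c("A", "B"), target = c("B", "A"), sign = c("-", "-")
  ))
  tsRules <- new("RuleSet", network = tsNet, rules = list(
    A = detRule("A", "B", c(1, 0)),
    B = detRule("B", "A", c(1, 0))
  ))

  # repressilator: A -| B -| C -| A
  rpNet <- TFNetwork(c("A", "B", "C"), data.frame(
    source = c("A", "B", "C"), target = c("B", "C", "A"),
    sign = c("-", "-", "-")
  ))
  rpRules <- new("RuleSet", network = rpNet, rules = list(
    A = detRule("A", "C", c(1, 0)),
    B = detRule("B", "A", c(1, 0)),
    C = detRule("C", "B", c(1, 0))
  ))

  # self-activator hub: H -> H (0.1/0.9), H -> T1..T4 (0.2/0.8)
  hbNodes <- c("H", "T1", "T2", "T3", "T4")
  hbNet <- TFNetwork(hbNodes, data.frame(
    source = "H", target = hbNodes,
    sign = c("+", "+", "+", "+", "+")
  ))
  hbRules <- new("RuleSet", network = hbNet, rules = stats::setNames(c(
    list(detRule("H", "H", c(0.1, 0.9))),
    lapply(paste0("T", 1:4), function(t) detRule(t, "H", c(0.2, 0.8)))
  ), hbNodes))

  # independent coinflip: five regulator-free genes with constant 0.5
  cfNodes <- paste0("N", 1:5)
  cfNet <- TFNetwork(cfNodes, data.frame(
    source = character(0), target = character(0), sign = character(0)
  ))
  cfRules <- new("RuleSet", network = cfNet,
                 rules = stats::setNames(lapply(cfNodes, function(nd) {
                   new("BooleanRule", target = nd,
                       regulators = character(0), V = 0.5,
                       W = matrix(numeric(0), 0L, 1L), U = 1)
                 }), cfNodes))

  list(
    toggle_switch = list(
      network = tsNet, rules = tsRules, attractors = c("01", "10")
    ),
    repressilator = list(
      network = rpNet, rules = rpRules, attractors = character(0),
      cycle = c("001", "010", "011", "100", "101", "110")
    ),
    self_activator_hub = list(
      network = hbNet, rules = hbRules,
      attractors = c("00000", "11111")
    ),
    independent_coinflip = list(
      network = cfNet, rules = cfRules, attractors = character(0)
    )
  )
}
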