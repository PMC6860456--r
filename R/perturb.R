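#' WalkConfig constructor
#'
#' @param escapeRadius walk ends when Hamming distance from the start
#'   exceeds this (default 4).
#' @param nWalks walks per condition (default 1000).
#' @param maxSteps censoring cap on update events per walk (default 5000).
#' @param seed integer seed (NA = current RNG).
#' @return a validated [WalkConfig-class].
#' @export
walkConfig <- function(escapeRadius = 4L, nWalks = 1000L,
                       maxSteps = 5000L, seed = NA_integer_) {
  new("WalkConfig", escapeRadius = as.integer(escapeRadius),
      nWalks = as.integer(nWalks), maxSteps = as.integer(maxSteps),
      seed = as.integer(seed))
}

#' Construct a perturbation
#'
#' @param tf TF to perturb (ignored for mode `"none"`).
#' @param mode `"knockdown"` (held at 0), `"activation"` (held at 1) or
#'   `"none"` (unperturbed reference).
#' @return a list with elements `tf` and `mode`.
#' @export
perturbation <- function(tf = NA_character_,
                         mode = c("none", "knockdown", "activation")) {
  mode <- match.arg(mode)
  if (mode != "none" && (is.na(tf) || length(tf) != 1L)) {
    stop("a perturbed TF must be named")
  }
  list(tf = tf, mode = mode)
}

# Apply a perturbation to a start state: set the held TF to its clamped
# value. Distances are measured to this modified start, so the held TF
# contributes 0 by construction.
applyPerturbation <- function(state, pert, nodes) {
  if (pert$mode == "none") return(state)
  if (!pert$tf %in% nodes) stop("unknown node: ", pert$tf)
  state[[pert$tf]] <- if (pert$mode == "activation") 1L else 0L
  state
}

#' One random walk until escape from the start neighborhood
#'
#' Repeats general-asynchronous update steps (see [stepState()]) with the
#' perturbed TF held fixed until the Hamming distance from the
#' (perturbation-modified) start state exceeds `escapeRadius`, counting
#' every update event, including those that do not flip. Walks still
#' inside the neighborhood after `maxSteps` events are censored at the
#' cap.
#'
#' @param ruleset a [RuleSet-class].
#' @param start named binary vector or bitstring.
#' @param pert a [perturbation()] (default: none).
#' @param config a [WalkConfig-class]; `config@seed` (if not NA) seeds the
#'   walk.
#' @return integer number of update events.
#' @export
randomWalk <- function(ruleset, start, pert = perturbation(),
                       config = walkConfig()) {
  nodes <- networkNodes(ruleset@network)
  if (is.character(start) && length(start) == 1L) {
    start <- stateFromString(start, nodes)
  }
  start <- applyPerturbation(start, pert, nodes)
  fixed <- if (pert$mode == "none") character(0) else pert$tf
  nFree <- length(nodes) - length(fixed)
  if (config@escapeRadius >= nFree) {
    stop("escape impossible: escapeRadius must be smaller than the ",
         "number of free TFs")
  }
  withSeed(config@seed, {
    state <- start
    steps <- 0L
    while (hammingDistance(state, start) <= config@escapeRadius) {
      if (steps >= config@maxSteps) break
      steps <- steps + 1L
      state <- stepState(ruleset, state, fixed)
    }
    steps
  })
}

#' Ensemble of random walks for one condition
#'
#' Vectorized equivalent of repeating [randomWalk()] `nWalks` times: all
#' walks advance in lockstep, and per round each active walk picks one
#' free TF uniformly and flips a weighted coin with that TF's flip
#' probability at the walk's own state. Censored walks report `maxSteps`.
#'
#' @param ruleset a [RuleSet-class].
#' @param start named binary vector or bitstring.
#' @param pert a [perturbation()].
#' @param config a [WalkConfig-class].
#' @return integer vector of `nWalks` step counts.
#' @export
walkEnsemble <- function(ruleset, start, pert = perturbation(),
                         config = walkConfig()) {
  nodes <- networkNodes(ruleset@network)
  g <- length(nodes)
  if (is.character(start) && length(start) == 1L) {
    start <- stateFromString(start, nodes)
  }
  start <- applyPerturbation(start, pert, nodes)
  freeIdx <- if (pert$mode == "none") seq_len(g) else
    which(nodes != pert$tf)
  if (config@escapeRadius >= length(freeIdx)) {
    stop("escape impossible: escapeRadius must be smaller than the ",
         "number of free TFs")
  }
  rules <- ruleset@rules
  regIdx <- lapply(rules, function(r) match(r@regulators, nodes))
  bitW <- lapply(rules, function(r) leafBitWeights(length(r@regulators)))
  Vs <- lapply(rules, function(r) r@V)

  nW <- config@nWalks
  withSeed(config@seed, {
    states <- matrix(rep(as.integer(start), each = nW), nrow = nW)
    dist <- integer(nW)
    steps <- integer(nW)
    active <- rep(TRUE, nW)
    while (any(active)) {
      idx <- which(active)
      steps[idx] <- steps[idx] + 1L
      pick <- freeIdx[sample.int(length(freeIdx), length(idx),
                                 replace = TRUE)]
      u <- stats::runif(length(idx))
      for (tf in unique(pick)) {
        rows <- idx[pick == tf]
        ri <- regIdx[[tf]]
        leaf <- if (length(ri) == 0L) rep(1L, length(rows)) else
          as.integer(states[rows, ri, drop = FALSE] %*% bitW[[tf]]) + 1L
        pOn <- Vs[[tf]][leaf]
        cur <- states[rows, tf]
        pFlip <- ifelse(cur == 1L, 1 - pOn, pOn)
        doFlip <- u[match(rows, idx)] < pFlip
        if (any(doFlip)) {
          fr <- rows[doFlip]
          newBit <- 1L - states[fr, tf]
          states[fr, tf] <- newBit
          dist[fr] <- dist[fr] + ifelse(newBit == start[[tf]], -1L, 1L)
        }
      }
      escaped <- dist > config@escapeRadius
      capped <- steps >= config@maxSteps
      active <- active & !escaped & !capped
    }
    steps
  })
}

#' Stability of an attractor under one perturbation
#'
#' Runs an ensemble of random walks from the attractor's representative
#' state with the perturbation applied, and an unperturbed reference
#' ensemble from the same state, and scores the perturbation as the
#' fractional change in mean escape steps:
#' `score = (mean - reference_mean) / reference_mean`. Negative scores
#' mean the perturbation destabilizes the state (walks escape sooner).
#'
#' @param ruleset a [RuleSet-class].
#' @param start named binary vector or bitstring (typically an attractor
#'   representative).
#' @param pert a [perturbation()].
#' @param config a [WalkConfig-class]; the perturbed and reference
#'   ensembles use independent sub-seeds derived from `config@seed`.
#' @return list with `steps`, `referenceSteps` (integer vectors),
#'   `meanSteps`, `referenceMeanSteps`, `score`, `nCensored`, `seed`.
#' @export
stabilityScore <- function(ruleset, start, pert, config = walkConfig()) {
  refCfg <- config
  pertCfg <- config
  if (!is.na(config@seed)) {
    refCfg@seed <- deriveSeed(config@seed, 1L)
    pertCfg@seed <- deriveSeed(config@seed, 2L)
  }
  refSteps <- walkEnsemble(ruleset, start, perturbation(), refCfg)
  steps <- walkEnsemble(ruleset, start, pert, pertCfg)
  meanSteps <- mean(steps)
  refMean <- mean(refSteps)
  list(
    steps = steps, referenceSteps = refSteps,
    meanSteps = meanSteps, referenceMeanSteps = refMean,
    score = (meanSteps - refMean) / refMean,
    nCensored = sum(steps >= config@maxSteps),
    seed = config@seed
  )
}

#' Scan all single-TF perturbations over all attractors
#'
#' For every attractor and every TF, scores knockdown (held at 0) and
#' activation (held at 1) against one shared unperturbed reference
#' ensemble per attractor: 2 g conditions plus one reference per
#' attractor. Every condition runs `config@nWalks` walks under its own
#' derived sub-seed, so conditions are reproducible and order-independent.
#'
#' @param ruleset a [RuleSet-class].
#' @param attractorSet a [PseudoAttractorSet-class] (cluster labels, if
#'   assigned, are carried into the result).
#' @param config a [WalkConfig-class].
#' @return data.frame with columns `tf`, `mode`, `start_attractor`,
#'   `cluster`, `mean_steps`, `reference_mean_steps`, `score`, `n_walks`,
#'   `n_censored`, `seed`.
#' @export
scanPerturbations <- function(ruleset, attractorSet,
                              config = walkConfig()) {
  nodes <- networkNodes(ruleset@network)
  if (nAttractors(attractorSet) == 0L) stop("no attractors to scan")
  rows <- list()
  condIdx <- 0L
  for (ai in seq_along(attractorSet@attractors)) {
    a <- attractorSet@attractors[[ai]]
    start <- a$representative
    cluster <- if (!is.null(a$cluster)) a$cluster else NA_character_
    condIdx <- condIdx + 1L
    refCfg <- config
    if (!is.na(config@seed)) refCfg@seed <- deriveSeed(config@seed, condIdx)
    refSteps <- walkEnsemble(ruleset, start, perturbation(), refCfg)
    refMean <- mean(refSteps)
    rows[[length(rows) + 1L]] <- data.frame(
      tf = NA_character_, mode = "none", start_attractor = start,
      cluster = cluster, mean_steps = refMean,
      reference_mean_steps = refMean, score = 0,
      n_walks = config@nWalks,
      n_censored = sum(refSteps >= config@maxSteps),
      seed = refCfg@seed, stringsAsFactors = FALSE
    )
    for (tf in nodes) {
      for (mode in c("knockdown", "activation")) {
        condIdx <- condIdx + 1L
        cfg <- config
        if (!is.na(config@seed)) cfg@seed <- deriveSeed(config@seed, condIdx)
        steps <- walkEnsemble(ruleset, start, perturbation(tf, mode), cfg)
        m <- mean(steps)
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, mode = mode, start_attractor = start,
          cluster = cluster, mean_steps = m,
          reference_mean_steps = refMean,
          score = (m - refMean) / refMean,
          n_walks = config@nWalks,
          n_censored = sum(steps >= config@maxSteps),
          seed = cfg@seed, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate perturbation scores per cluster
#'
#' Unweighted mean of each (tf, mode) score over the attractors assigned
#' to each cluster.
#'
#' @param scores data.frame from [scanPerturbations()].
#' @return data.frame with columns `cluster`, `tf`, `mode`, `score`,
#'   `n_attractors`.
#' @export
clusterScores <- function(scores) {
  sub <- scores[scores$mode != "none" & !is.na(scores$cluster), ,
                drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(cluster = character(0), tf = character(0),
                      mode = character(0), score = numeric(0),
                      n_attractors = integer(0)))
  }
  agg <- stats::aggregate(score ~ cluster + tf + mode, data = sub,
                          FUN = mean)
  cnt <- stats::aggregate(score ~ cluster + tf + mode, data = sub,
                          FUN = length)
  agg$n_attractors <- cnt$score
  agg[order(agg$cluster, agg$tf, agg$mode), , drop = FALSE]
}

#' Classify master regulators and master destabilizers
#'
#' A TF whose knockdown destabilizes a cluster's attractors by at least
#' 20% (score at or below the threshold, default -0.2) is a master
#' regulator of that cluster; a TF whose forced activation does so is a
#' master destabilizer. A TF may qualify for several clusters.
#'
#' @param perCluster data.frame from [clusterScores()].
#' @param threshold classification cutoff on the score (default -0.2).
#' @return named list per cluster, each with `master_regulators` and
#'   `master_destabilizers` (character vectors).
#' @export
classifyMasters <- function(perCluster, threshold = -0.2) {
  clusters <- sort(unique(perCluster$cluster))
  out <- lapply(clusters, function(cl) {
    sub <- perCluster[perCluster$cluster == cl, , drop = FALSE]
    list(
      master_regulators = sort(sub$tf[sub$mode == "knockdown" &
                                        sub$score <= threshold]),
      master_destabilizers = sort(sub$tf[sub$mode == "activation" &
                                           sub$score <= threshold])
    )
  })
  names(out) <- clusters
  out
}

#' Exact expected escape steps by absorbing-Markov-chain solve
#'
#' Enumerates the full state space (feasible for small networks), makes
#' every state beyond the escape radius absorbing, and solves the linear
#' system t = (I - Q)^{-1} 1 over the transient states for the expected
#' number of update events until absorption. This is the analytic
#' counterpart of the Monte Carlo walk ensemble, counting non-flipping
#' updates exactly as the walk does.
#'
#' @param ruleset a [RuleSet-class] (network size at most 14).
#' @param start named binary vector or bitstring.
#' @param pert a [perturbation()].
#' @param escapeRadius escape radius as in [walkConfig()].
#' @return expected number of update events from the start state.
#' @export
expectedEscapeSteps <- function(ruleset, start, pert = perturbation(),
                                escapeRadius = 4L) {
  nodes <- networkNodes(ruleset@network)
  g <- length(nodes)
  if (g > 14L) stop("exact solve limited to networks of at most 14 nodes")
  if (is.character(start) && length(start) == 1L) {
    start <- stateFromString(start, nodes)
  }
  start <- applyPerturbation(start, pert, nodes)
  freeIdx <- if (pert$mode == "none") seq_len(g) else
    which(nodes != pert$tf)
  if (escapeRadius >= length(freeIdx)) {
    stop("escape impossible: escapeRadius must be smaller than the ",
         "number of free TFs")
  }
  states <- allStatesMatrix(g)
  # restrict to states consistent with the clamp (held TF never moves)
  if (pert$mode != "none") {
    hold <- which(nodes == pert$tf)
    states <- states[states[, hold] == start[[hold]], , drop = FALSE]
  }
  nS <- nrow(states)
  dist <- as.integer(states %*% rep(1, g) +
                       sum(start) - 2L * (states %*% as.integer(start)))
  transient <- which(dist <= escapeRadius)
  keyOf <- apply(states, 1L, paste, collapse = "")
  rowOf <- stats::setNames(seq_len(nS), keyOf)
  nT <- length(transient)
  tPos <- stats::setNames(seq_len(nT), keyOf[transient])
  Q <- matrix(0, nT, nT)
  nFree <- length(freeIdx)
  for (k in seq_len(nT)) {
    bits <- states[transient[k], ]
    st <- stats::setNames(bits, nodes)
    stay <- 0
    for (i in freeIdx) {
      pOn <- ruleOutputAtState(ruleset@rules[[nodes[i]]], st)
      pFlip <- if (bits[i] == 1L) 1 - pOn else pOn
      nb <- bits
      nb[i] <- 1L - nb[i]
      nbKey <- paste(nb, collapse = "")
      stay <- stay + (1 - pFlip) / nFree
      pos <- tPos[nbKey]
      if (!is.na(pos)) Q[k, pos] <- Q[k, pos] + pFlip / nFree
    }
    Q[k, k] <- Q[k, k] + stay
  }
  tvec <- solve(diag(nT) - Q, rep(1, nT))
  startKey <- stateToString(start)
  unname(tvec[tPos[startKey]])
}
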