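#' Leaf-membership probabilities of a regulator state
#'
#' For a vector of N regulator ON-probabilities, returns the probability
#' that the regulator configuration belongs to each of the 2^N leaves of
#' the rule's binary tree: the product over regulators of p (bit 1) or
#' 1 - p (bit 0), with the first regulator as the most significant bit of
#' the leaf index. The 2^N values always sum to 1.
#'
#' @param stateProbs numeric vector of N probabilities in `[0, 1]`, in the
#'   fixed regulator order.
#' @return numeric vector of length 2^N (leaf 0 first).
#' @examples
#' allLeafProbabilities(c(0.3, 0.8))  # leaf (!A & B) has mass 0.56
#' @export
allLeafProbabilities <- function(stateProbs) {
  if (any(!is.finite(stateProbs)) || any(stateProbs < 0 | stateProbs > 1)) {
    stop("state probabilities must lie in [0, 1]")
  }
  # successive outer products put each later regulator on a faster-varying
  # bit, so the first regulator ends up as the most significant bit
  out <- 1
  for (p in stateProbs) {
    out <- as.vector(outer(c(1 - p, p), out))
  }
  out
}

#' Probability that an observation falls in one leaf
#'
#' @param stateProbs numeric vector of N regulator ON-probabilities.
#' @param leafIndex 0-based leaf index in `[0, 2^N)`.
#' @return the leaf-membership probability.
#' @export
leafProbability <- function(stateProbs, leafIndex) {
  n <- length(stateProbs)
  if (leafIndex < 0 || leafIndex >= 2^n) {
    stop("leaf index out of range")
  }
  allLeafProbabilities(stateProbs)[leafIndex + 1L]
}

# M x 2^N weight matrix W: w[i, j] = leaf-membership of observation i.
leafWeightMatrix <- function(Rprime) {
  m <- nrow(Rprime)
  w <- matrix(1, m, 1)
  for (k in seq_len(ncol(Rprime))) {
    p <- Rprime[, k]
    nl <- ncol(w)
    wn <- matrix(0, m, 2L * nl)
    wn[, seq_len(nl) * 2L - 1L] <- w * (1 - p)
    wn[, seq_len(nl) * 2L] <- w * p
    w <- wn
  }
  w
}

#' Fit a probabilistic Boolean rule for one target
#'
#' The core inference step. Given the binarized regulator matrix R' (M
#' observations x N regulators) and the binarized target vector T', the
#' rule confidence at leaf j is the observation-weighted average of the
#' target, blended toward 0.5 by the leaf's uncertainty:
#' \deqn{w_{ij} = P_j(R'_i), \quad u_j = 1 - \max_i w_{ij}, \quad
#'       v_j = \frac{\sum_i t'_i w_{ij} + 0.5\,u_j}{\sum_i w_{ij} + u_j}}
#' With no observations every leaf is maximally uncertain (v = 0.5).
#'
#' @param Rprime numeric M x N matrix of regulator ON-probabilities,
#'   columns in the fixed (lexicographic) regulator order. M = 0 is
#'   allowed.
#' @param Tprime numeric vector of M target ON-probabilities.
#' @param regulators character vector of N regulator names (sorted).
#' @param target target gene name.
#' @return a [BooleanRule-class].
#' @examples
#' r <- fitRule(matrix(c(1, 0), 1, 2), 1, c("A", "B"), "X")
#' ruleV(r)  # leaf (A & !B) pinned to 1, untouched leaf (!A & !B) at 0.5
#' @export
fitRule <- function(Rprime, Tprime, regulators, target = "target") {
  Rprime <- as.matrix(Rprime)
  n <- length(regulators)
  if (nrow(Rprime) == 0L && length(Tprime) == 0L) {
    Rprime <- matrix(numeric(0), 0L, n)
  }
  if (ncol(Rprime) != n) {
    stop("Rprime must have one column per regulator")
  }
  if (nrow(Rprime) != length(Tprime)) {
    stop("Rprime and Tprime disagree on the number of observations")
  }
  if (is.unsorted(regulators)) {
    stop("regulators must be supplied in lexicographic order")
  }
  if (length(Tprime) > 0 &&
      (any(!is.finite(Tprime)) || any(Tprime < 0 | Tprime > 1))) {
    stop("Tprime entries must lie in [0, 1]")
  }
  if (length(Rprime) > 0 &&
      (any(!is.finite(Rprime)) || any(Rprime < 0 | Rprime > 1))) {
    stop("Rprime entries must lie in [0, 1]")
  }
  nl <- 2L^n
  w <- leafWeightMatrix(Rprime)
  if (nrow(w) == 0L) {
    u <- rep(1, nl) # max over the empty set is 0
    v <- rep(0.5, nl)
  } else {
    u <- 1 - apply(w, 2L, max)
    v <- (colSums(Tprime * w) + 0.5 * u) / (colSums(w) + u)
  }
  new("BooleanRule", target = target, regulators = as.character(regulators),
      V = v, W = w, U = u)
}

#' Fit rules for every node of a network
#'
#' Applies [fitRule()] to each network node, taking the node's regulators
#' (lexicographically ordered) as inputs and the node's own binarized
#' values as the target vector. Self-loops are ordinary inputs. A node with
#' zero regulators gets the single-leaf limit of the same formula: every
#' observation carries weight 1, so u = 0 and v0 is the plain mean of T'.
#'
#' @param network a [TFNetwork-class]; every node must be a gene of `be`.
#' @param be a [BinarizedExperiment-class] (or a plain probability matrix
#'   with gene rownames).
#' @return a [RuleSet-class].
#' @export
fitRules <- function(network, be) {
  prob <- if (is(be, "BinarizedExperiment")) onProbabilities(be) else
    as.matrix(be)
  missing <- setdiff(networkNodes(network), rownames(prob))
  if (length(missing) > 0) {
    stop("unknown node: ", paste(missing, collapse = ", "))
  }
  rules <- lapply(networkNodes(network), function(node) {
    regs <- regulatorsOf(network, node)
    Rp <- t(prob[regs, , drop = FALSE])
    fitRule(Rp, prob[node, ], regs, node)
  })
  names(rules) <- networkNodes(network)
  new("RuleSet", network = network, rules = rules)
}

#' Expected rule output for an uncertain regulator state
#'
#' The leaf-probability-weighted expectation of the rule vector:
#' `sum_j P_j(stateProbs) * v_j`. Used for cross-validation predictions.
#'
#' @param rule a [BooleanRule-class].
#' @param stateProbs numeric vector of N regulator ON-probabilities in the
#'   rule's regulator order.
#' @return a probability in `[0, 1]`.
#' @export
predictRule <- function(rule, stateProbs) {
  if (length(stateProbs) != length(rule@regulators)) {
    stop("stateProbs length must match the number of regulators")
  }
  sum(allLeafProbabilities(stateProbs) * rule@V)
}

#' Rule accessors
#'
#' `ruleV()`, `ruleU()`, `ruleW()` return the leaf confidences, leaf
#' uncertainties and observation-weight matrix; `ruleRegulators()` and
#' `ruleTarget()` the regulator order and target gene.
#'
#' @param rule a [BooleanRule-class].
#' @return the corresponding slot value.
#' @name rule-accessors
NULL

#' @rdname rule-accessors
#' @export
ruleV <- function(rule) rule@V

#' @rdname rule-accessors
#' @export
ruleU <- function(rule) rule@U

#' @rdname rule-accessors
#' @export
ruleW <- function(rule) rule@W

#' @rdname rule-accessors
#' @export
ruleRegulators <- function(rule) rule@regulators

#' @rdname rule-accessors
#' @export
ruleTarget <- function(rule) rule@target

#' Rules of a RuleSet
#' @param ruleset a [RuleSet-class].
#' @return named list of [BooleanRule-class] objects.
#' @export
rulesOf <- function(ruleset) ruleset@rules

#' Network of a RuleSet
#' @param ruleset a [RuleSet-class].
#' @return the [TFNetwork-class].
#' @export
rulesNetwork <- function(ruleset) ruleset@network

setMethod("show", "BooleanRule", function(object) {
  n <- length(object@regulators)
  cat(sprintf("BooleanRule for %s: %d regulator(s)%s, %d leaves\n",
              object@target, n,
              if (n > 0) paste0(" (", paste(object@regulators,
                                            collapse = ", "), ")") else "",
              2L^n))
  cat("  V:", paste(sprintf("%.3f", utils::head(object@V, 8)),
                    collapse = " "),
      if (length(object@V) > 8) "..." else "", "\n")
})

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet over", length(object@rules), "nodes\n")
  nreg <- vapply(object@rules, function(r) length(r@regulators), integer(1))
  cat("  in-degrees:", paste(nreg, collapse = " "), "\n")
})

#' Cross-validate rule fits by repeated random splits
#'
#' Repeatedly partitions the samples into a training fraction used to fit
#' all rules and a held-out test set, records per-gene mean squared error
#' of the expected rule output against the binarized truth on both
#' partitions, and keeps all (prediction, truth) pairs for
#' confidence-stratified correlation analysis (see
#' [confidenceCorrelation()]).
#'
#' @param network a [TFNetwork-class].
#' @param be a [BinarizedExperiment-class] covering the network nodes.
#' @param trainFraction fraction of samples in the training split
#'   (default 0.8; train size is the floor of fraction x M).
#' @param iterations number of random splits (default 70).
#' @param seed integer seed for the splits.
#' @return list with `mse` (data.frame: gene, iteration, train_mse,
#'   test_mse) and `pairs` (data.frame: gene, iteration, partition,
#'   prediction, truth).
#' @export
crossValidateRules <- function(network, be, trainFraction = 0.8,
                               iterations = 70L, seed = 0L) {
  prob <- if (is(be, "BinarizedExperiment")) onProbabilities(be) else
    as.matrix(be)
  m <- ncol(prob)
  if (m < 5L) stop("cross-validation needs at least 5 samples")
  nTrain <- floor(trainFraction * m)
  if (nTrain < 1L || nTrain >= m) stop("degenerate train/test split")
  nodes <- networkNodes(network)
  regsList <- lapply(nodes, function(nd) regulatorsOf(network, nd))
  names(regsList) <- nodes

  mseRows <- vector("list", iterations)
  pairRows <- vector("list", iterations)
  withSeed(as.integer(seed), {
    for (it in seq_len(iterations)) {
      trainIdx <- sort(sample.int(m, nTrain))
      testIdx <- setdiff(seq_len(m), trainIdx)
      ruleset <- fitRules(network, prob[, trainIdx, drop = FALSE])
      geneMse <- matrix(NA_real_, length(nodes), 2L,
                        dimnames = list(nodes, c("train", "test")))
      prs <- list()
      for (nd in nodes) {
        rule <- ruleset@rules[[nd]]
        regs <- regsList[[nd]]
        for (part in c("train", "test")) {
          idx <- if (part == "train") trainIdx else testIdx
          Rp <- t(prob[regs, idx, drop = FALSE])
          preds <- vapply(seq_along(idx), function(i) {
            predictRule(rule, Rp[i, ])
          }, numeric(1))
          truth <- prob[nd, idx]
          geneMse[nd, part] <- mean((preds - truth)^2)
          prs[[length(prs) + 1L]] <- data.frame(
            gene = nd, iteration = it, partition = part,
            prediction = preds, truth = truth
          )
        }
      }
      mseRows[[it]] <- data.frame(
        gene = nodes, iteration = it,
        train_mse = geneMse[, "train"], test_mse = geneMse[, "test"],
        row.names = NULL
      )
      pairRows[[it]] <- do.call(rbind, prs)
    }
  })
  list(mse = do.call(rbind, mseRows), pairs = do.call(rbind, pairRows))
}

#' Confidence-stratified prediction/truth correlation curve
#'
#' For each window half-width x in `grid`, computes the Pearson correlation
#' of prediction vs truth restricted to confident predictions
#' (prediction < x or prediction > 1 - x); x = 0.5 includes everything.
#' Windows with fewer than 3 pairs or zero variance give NA.
#'
#' @param pairs the `pairs` data.frame from [crossValidateRules()].
#' @param grid numeric vector of window half-widths in (0, 0.5].
#' @param partition which partition(s) to use (default `"test"`).
#' @return data.frame with columns `x`, `n`, `correlation`.
#' @export
confidenceCorrelation <- function(pairs, grid = seq(0.05, 0.5, by = 0.05),
                                  partition = "test") {
  pairs <- pairs[pairs$partition %in% partition, , drop = FALSE]
  out <- lapply(grid, function(x) {
    sel <- pairs$prediction < x | pairs$prediction > 1 - x
    sub <- pairs[sel, , drop = FALSE]
    r <- if (nrow(sub) >= 3L && stats::sd(sub$prediction) > 0 &&
             stats::sd(sub$truth) > 0) {
      stats::cor(sub$prediction, sub$truth)
    } else {
      NA_real_
    }
    data.frame(x = x, n = nrow(sub), correlation = r)
  })
  do.call(rbind, out)
}
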