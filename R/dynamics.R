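# General-asynchronous update semantics. A rule stores the ON-probability
# of its target per regulator configuration; the probability that an update
# of TF x actually changes the state ("flip probability") is that
# ON-probability if x is currently OFF, and its complement if x is ON. A
# state where every flip probability is below 0.5 therefore has at least a
# 50% chance per update of remaining unchanged for every choice of TF.

#' Rule output at a concrete binary state
#'
#' Looks up the single leaf selected by the regulators' binary values in
#' the given network state and returns its confidence v_j (the probability
#' the target turns ON when updated).
#'
#' @param rule a [BooleanRule-class].
#' @param state named binary vector over (at least) the rule's regulators.
#' @return the ON-probability in `[0, 1]`.
#' @export
ruleOutputAtState <- function(rule, state) {
  regs <- rule@regulators
  if (length(regs) == 0L) return(rule@V[1L])
  bits <- state[regs]
  if (any(is.na(bits))) {
    stop("state does not supply values for all regulators of ",
         rule@target)
  }
  j <- sum(bits * leafBitWeights(length(regs)))
  rule@V[j + 1L]
}

#' Probability that updating one TF flips its value
#'
#' @param ruleset a [RuleSet-class].
#' @param state named binary vector over the network nodes.
#' @param tf the TF to update.
#' @return flip probability in `[0, 1]`: the rule's ON-probability if the
#'   TF is OFF, its complement if ON.
#' @export
flipProbability <- function(ruleset, state, tf) {
  if (!tf %in% networkNodes(ruleset@network)) {
    stop("unknown node: ", tf)
  }
  pOn <- ruleOutputAtState(ruleset@rules[[tf]], state)
  if (state[[tf]] == 1L) 1 - pOn else pOn
}

# Flip probabilities of all TFs at a state, as a named vector.
flipProbabilities <- function(ruleset, state) {
  nodes <- networkNodes(ruleset@network)
  vapply(nodes, function(tf) flipProbability(ruleset, state, tf),
         numeric(1))
}

#' One general-asynchronous update step
#'
#' Chooses one non-fixed TF uniformly at random, flips a weighted coin with
#' its flip probability, and returns the (possibly identical) successor
#' state. Consumes exactly two random draws (TF index, uniform).
#'
#' @param ruleset a [RuleSet-class].
#' @param state named binary vector over the network nodes.
#' @param fixedTFs character vector of TFs held constant (excluded from the
#'   uniform choice); must leave at least one free TF.
#' @return the successor state (named binary vector).
#' @export
stepState <- function(ruleset, state, fixedTFs = character(0)) {
  nodes <- networkNodes(ruleset@network)
  free <- setdiff(nodes, fixedTFs)
  if (length(free) == 0L) stop("all TFs are fixed; no update possible")
  tf <- free[sample.int(length(free), 1L)]
  p <- flipProbability(ruleset, state, tf)
  if (stats::runif(1) < p) {
    state[[tf]] <- 1L - state[[tf]]
  }
  state
}

#' Build the bounded state-transition graph around an initial state
#'
#' Breadth-first exploration from `initState`: every state within Hamming
#' distance `radius` of the initial state receives one out-edge per TF,
#' weighted by that TF's flip probability (self-transitions are implicit);
#' states just beyond the radius receive a single weight-1 edge to the
#' out-of-bounds sink vertex and are not expanded, keeping the graph
#' finite.
#'
#' @param ruleset a [RuleSet-class].
#' @param initState named binary vector (or bitstring) over the nodes.
#' @param radius non-negative Hamming search radius.
#' @param maxVertices memory guard; exploration stops with an error if the
#'   vertex count would exceed it.
#' @return a [TransitionGraph-class].
#' @export
buildBoundedSTG <- function(ruleset, initState, radius,
                            maxVertices = 300000L) {
  nodes <- networkNodes(ruleset@network)
  g <- length(nodes)
  if (is.character(initState) && length(initState) == 1L) {
    initState <- stateFromString(initState, nodes)
  }
  if (radius < 0) stop("radius must be >= 0")
  initKey <- stateToString(initState)
  initBits <- as.integer(initState)

  visited <- new.env(parent = emptyenv(), hash = TRUE)
  assign(initKey, TRUE, envir = visited)
  pending <- list(initBits)
  nVertices <- 1L
  from <- list(); to <- list(); wt <- list(); tfl <- list()

  while (length(pending) > 0) {
    bits <- pending[[length(pending)]]
    pending[[length(pending)]] <- NULL
    key <- paste(bits, collapse = "")
    d <- sum(bits != initBits)
    if (d > radius) {
      from[[length(from) + 1L]] <- key
      to[[length(to) + 1L]] <- ".oob"
      wt[[length(wt) + 1L]] <- 1
      tfl[[length(tfl) + 1L]] <- NA_character_
      next
    }
    state <- stats::setNames(bits, nodes)
    fp <- flipProbabilities(ruleset, state)
    for (i in seq_len(g)) {
      nb <- bits
      nb[i] <- 1L - nb[i]
      nbKey <- paste(nb, collapse = "")
      if (!exists(nbKey, envir = visited, inherits = FALSE)) {
        assign(nbKey, TRUE, envir = visited)
        nVertices <- nVertices + 1L
        if (nVertices > maxVertices) {
          stop("bounded STG exceeds maxVertices (", maxVertices,
               "); reduce the radius or raise the guard")
        }
        pending[[length(pending) + 1L]] <- nb
      }
      from[[length(from) + 1L]] <- key
      to[[length(to) + 1L]] <- nbKey
      wt[[length(wt) + 1L]] <- fp[[i]]
      tfl[[length(tfl) + 1L]] <- nodes[i]
    }
  }

  edges <- data.frame(
    from = unlist(from), to = unlist(to),
    weight = unlist(wt), tf = unlist(tfl),
    stringsAsFactors = FALSE
  )
  vnames <- unique(c(initKey, edges$from, edges$to, ".oob"))
  gr <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = vnames)
  new("TransitionGraph", graph = gr, nodes = nodes, initState = initKey,
      radius = as.integer(radius))
}

#' Export a transition graph as an edge-list data.frame
#'
#' @param tg a [TransitionGraph-class].
#' @return data.frame with columns `from`, `to`, `tf`, `flip_probability`
#'   (sink edges have `tf = NA` and probability 1).
#' @export
transitionEdges <- function(tg) {
  el <- igraph::as_data_frame(tg@graph, what = "edges")
  data.frame(
    from = el$from, to = el$to, tf = el$tf,
    flip_probability = el$weight,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "TransitionGraph", function(object) {
  cat(sprintf(
    "TransitionGraph: %d vertices (incl. sink), %d edges, radius %d around %s\n",
    igraph::vcount(object@graph), igraph::ecount(object@graph),
    object@radius, object@initState
  ))
})
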