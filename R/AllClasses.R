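#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' TFNetwork: a directed transcription-factor regulatory network
#'
#' Holds the node set and signed edge list of a TF-to-TF regulatory
#' network. Edges carry a sign (`"+"` activating, `"-"` inhibiting, `"?"`
#' unknown) which is used only by the deterministic baseline update schemes
#' ([baselineRules()]); probabilistic rule inference is unsigned. Self-edges
#' are allowed. The regulators of each target are always ordered
#' lexicographically; this fixed order defines the bit order of rule leaf
#' indices throughout the package (first regulator = most significant bit).
#'
#' @slot nodes character vector of unique gene identifiers.
#' @slot edges data.frame with columns `source`, `target`, `sign`.
#' @slot inDegreeCap maximum allowed in-degree (the rule table for a target
#'   with N regulators has 2^N leaves, so this is a hard guard).
#'
#' @aliases TFNetwork-class
#' @export
setClass("TFNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    inDegreeCap = "integer"
  ),
  prototype(
    nodes = character(0),
    edges = data.frame(
      source = character(0), target = character(0), sign = character(0),
      stringsAsFactors = FALSE
    ),
    inDegreeCap = 20L
  )
)

setValidity("TFNetwork", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@nodes)) {
    msg <- c(msg, "duplicate node identifiers")
  }
  ed <- object@edges
  if (!all(c("source", "target", "sign") %in% names(ed))) {
    msg <- c(msg, "edges must have columns source, target, sign")
  } else {
    if (nrow(ed) > 0) {
      if (anyDuplicated(paste(ed$source, ed$target, sep = "\r"))) {
        msg <- c(msg, "duplicate (regulator, target) edges")
      }
      missing <- setdiff(unique(c(ed$source, ed$target)), object@nodes)
      if (length(missing) > 0) {
        msg <- c(msg, paste0(
          "edge endpoints absent from node set: ",
          paste(missing, collapse = ", ")
        ))
      }
      if (!all(ed$sign %in% c("+", "-", "?"))) {
        msg <- c(msg, "edge signs must be one of '+', '-', '?'")
      }
      indeg <- table(ed$target)
      over <- names(indeg)[indeg > object@inDegreeCap]
      if (length(over) > 0) {
        msg <- c(msg, paste0(
          "in-degree above cap (", object@inDegreeCap, ") for: ",
          paste(over, collapse = ", ")
        ))
      }
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' BooleanRule: a probabilistic Boolean rule for one target gene
#'
#' A rule assigns to each of the 2^N configurations (leaves) of its N
#' regulators a confidence `V[j]` in `[0, 1]` that the target turns ON.
#' `W[i, j]` records how strongly observation i constrains leaf j (the
#' leaf-membership probability of that observation's regulator state), and
#' `U[j] = 1 - max_i W[i, j]` is the residual uncertainty of the leaf;
#' leaves never touched by data have `V[j] = 0.5` exactly. Leaf `j`
#' (0-based) encodes the regulator states in the fixed lexicographic
#' regulator order with the first regulator as the most significant bit.
#'
#' @slot target gene identifier of the regulated gene.
#' @slot regulators ordered (lexicographic) character vector of regulators.
#' @slot V numeric vector of length 2^N, leaf confidences in `[0, 1]`.
#' @slot W numeric M x 2^N observation-weight matrix (may have 0 rows when
#'   the rule was built analytically or read back from disk).
#' @slot U numeric vector of length 2^N, per-leaf uncertainties.
#'
#' @aliases BooleanRule-class
#' @export
setClass("BooleanRule",
  representation(
    target = "character",
    regulators = "character",
    V = "numeric",
    W = "matrix",
    U = "numeric"
  )
)

setValidity("BooleanRule", function(object) {
  msg <- character(0)
  nl <- 2L^length(object@regulators)
  if (length(object@target) != 1L) msg <- c(msg, "target must be length 1")
  if (is.unsorted(object@regulators)) {
    msg <- c(msg, "regulators must be in lexicographic order")
  }
  if (length(object@V) != nl) {
    msg <- c(msg, sprintf("V must have length 2^N = %d", nl))
  }
  if (any(!is.finite(object@V)) || any(object@V < 0 | object@V > 1)) {
    msg <- c(msg, "V entries must lie in [0, 1]")
  }
  if (length(object@U) != nl) {
    msg <- c(msg, sprintf("U must have length 2^N = %d", nl))
  }
  if (nrow(object@W) > 0) {
    if (ncol(object@W) != nl) {
      msg <- c(msg, "W must have 2^N columns")
    } else {
      rs <- rowSums(object@W)
      if (any(abs(rs - 1) > 1e-8)) {
        msg <- c(msg, "rows of W must sum to 1")
      }
      u <- 1 - apply(object@W, 2, max)
      if (any(abs(u - object@U) > 1e-8)) {
        msg <- c(msg, "U must equal 1 - column maxima of W")
      }
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' RuleSet: one BooleanRule per network node
#'
#' A container binding a [TFNetwork-class] to a named list of fitted (or
#' constructed) [BooleanRule-class] objects, one per node, in node order.
#'
#' @slot network the [TFNetwork-class] the rules were fitted on.
#' @slot rules named list of [BooleanRule-class], names = network nodes.
#'
#' @aliases RuleSet-class
#' @export
setClass("RuleSet",
  representation(
    network = "TFNetwork",
    rules = "list"
  )
)

setValidity("RuleSet", function(object) {
  msg <- character(0)
  nd <- object@network@nodes
  if (!identical(names(object@rules), nd)) {
    msg <- c(msg, "rules must be named exactly by the network nodes, in order")
  }
  ok <- vapply(object@rules, function(r) is(r, "BooleanRule"), logical(1))
  if (!all(ok)) msg <- c(msg, "all elements must be BooleanRule objects")
  if (length(msg) > 0) msg else TRUE
})

#' BinarizedExperiment: expression with per-gene ON-probabilities
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `exprs` (the input log-scale expression) and `prob` (the posterior
#' probability that each gene is ON in each sample, from a per-gene
#' two-component tied-variance Gaussian mixture). The mixture parameters
#' are stored in `rowData`: `muOff`, `muOn`, `sigma`, `wOff`, `wOn`,
#' `degenerate`. Degenerate genes (no usable bimodality) have all
#' probabilities exactly 0.5.
#'
#' @aliases BinarizedExperiment-class
#' @export
setClass("BinarizedExperiment", contains = "SummarizedExperiment")

setValidity("BinarizedExperiment", function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("exprs", "prob") %in% an)) {
    msg <- c(msg, "assays 'exprs' and 'prob' are required")
  } else {
    p <- SummarizedExperiment::assay(object, "prob")
    if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
      msg <- c(msg, "ON-probabilities must lie in [0, 1]")
    }
  }
  need <- c("muOff", "muOn", "sigma", "wOff", "wOn", "degenerate")
  if (!all(need %in% names(SummarizedExperiment::rowData(object)))) {
    msg <- c(msg, paste0(
      "rowData must contain mixture parameters: ",
      paste(need, collapse = ", ")
    ))
  }
  if (length(msg) > 0) msg else TRUE
})

#' TransitionGraph: a bounded state-transition graph
#'
#' The STG explored around an initial state: every state within Hamming
#' radius `radius` of `initState` has exactly g out-edges, one per TF,
#' weighted by that TF's flip probability; states just beyond the radius
#' have a single weight-1 edge to the out-of-bounds sink vertex (named
#' `".oob"`), which has no out-edges. States are vertex names, written as
#' 0/1 bitstrings in node order.
#'
#' @slot graph an [igraph::igraph] with vertex names = state bitstrings
#'   plus the `".oob"` sink, and edge attributes `tf` and `weight`.
#' @slot nodes node (TF) order defining bitstring positions.
#' @slot initState bitstring of the initial state.
#' @slot radius Hamming search radius.
#'
#' @aliases TransitionGraph-class
#' @export
setClass("TransitionGraph",
  representation(
    graph = "ANY",
    nodes = "character",
    initState = "character",
    radius = "integer"
  )
)

#' PseudoAttractorSet: pseudo-attractors of a rule set
#'
#' Each pseudo-attractor is a terminal strongly connected component of the
#' pruned state-transition graph: after removing all edges with flip
#' probability below the threshold, the component contains no out-of-bounds
#' sink and no retained edge leaves it. A singleton pseudo-attractor is a
#' state where every TF's flip probability is below the threshold. The
#' representative state is the lexicographically smallest member bitstring.
#'
#' @slot nodes node (TF) order defining bitstring positions.
#' @slot attractors list; each element has `members` (sorted bitstrings),
#'   `representative`, and optionally `cluster`, `ambiguous`, `distances`
#'   after [assignAttractors()].
#' @slot threshold the pruning threshold used (P_T).
#'
#' @aliases PseudoAttractorSet-class
#' @export
setClass("PseudoAttractorSet",
  representation(
    nodes = "character",
    attractors = "list",
    threshold = "numeric"
  )
)

#' SearchConfig: parameters of the bounded pseudo-attractor search
#'
#' @slot radius Hamming radius of the bounded STG search (default 6 TF
#'   changes).
#' @slot threshold pruning threshold P_T in `[0, 1]` (default 0.5): edges
#'   with flip probability `< threshold` are pruned, and a singleton
#'   pseudo-attractor is a state whose flip probabilities are all below it.
#' @slot nRandomStarts number of random initial states for
#'   [randomRestartSearch()] (default 200).
#' @slot maxVertices memory guard on the number of explored STG vertices.
#' @slot seed integer seed for the random restarts (NA = use current RNG).
#'
#' @aliases SearchConfig-class
#' @export
setClass("SearchConfig",
  representation(
    radius = "integer",
    threshold = "numeric",
    nRandomStarts = "integer",
    maxVertices = "integer",
    seed = "integer"
  ),
  prototype(
    radius = 6L, threshold = 0.5, nRandomStarts = 200L,
    maxVertices = 300000L, seed = NA_integer_
  )
)

setValidity("SearchConfig", function(object) {
  msg <- character(0)
  if (object@radius < 0) msg <- c(msg, "radius must be >= 0")
  if (object@threshold < 0 || object@threshold > 1) {
    msg <- c(msg, "threshold must lie in [0, 1]")
  }
  if (object@nRandomStarts < 1) msg <- c(msg, "nRandomStarts must be >= 1")
  if (object@maxVertices < 2) msg <- c(msg, "maxVertices must be >= 2")
  if (length(msg) > 0) msg else TRUE
})

#' WalkConfig: parameters of the random-walk stability analysis
#'
#' @slot escapeRadius a walk ends when the Hamming distance from the start
#'   state exceeds this (default 4 TF changes).
#' @slot nWalks walks per condition (default 1000).
#' @slot maxSteps cap on update events per walk; walks still inside the
#'   neighborhood at the cap are censored at `maxSteps` (default 5000).
#' @slot seed integer seed; each (attractor, perturbation) condition gets
#'   its own derived sub-seed, recorded in the results.
#'
#' @aliases WalkConfig-class
#' @export
setClass("WalkConfig",
  representation(
    escapeRadius = "integer",
    nWalks = "integer",
    maxSteps = "integer",
    seed = "integer"
  ),
  prototype(
    escapeRadius = 4L, nWalks = 1000L, maxSteps = 5000L, seed = NA_integer_
  )
)

setValidity("WalkConfig", function(object) {
  msg <- character(0)
  if (object@escapeRadius < 0) msg <- c(msg, "escapeRadius must be >= 0")
  if (object@nWalks < 1) msg <- c(msg, "nWalks must be >= 1")
  if (object@maxSteps < 1) msg <- c(msg, "maxSteps must be >= 1")
  if (length(msg) > 0) msg else TRUE
})
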