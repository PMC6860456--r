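#' Construct a TFNetwork
#'
#' @param nodes character vector of gene identifiers.
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `sign` (`"+"`, `"-"`, `"?"`; missing sign defaults to `"?"`).
#'   Duplicate (source, target) rows are collapsed to one with a warning.
#' @param inDegreeCap hard cap on any node's in-degree (default 20); a
#'   target with N regulators needs a dense rule vector of length 2^N, so
#'   exceeding the cap is an error, not a slowdown.
#' @return a validated [TFNetwork-class].
#' @examples
#' net <- TFNetwork(c("A", "B"),
#'                  data.frame(source = c("A", "B"), target = c("B", "A"),
#'                             sign = c("-", "-")))
#' regulatorsOf(net, "A")
#' @export
TFNetwork <- function(nodes, edges, inDegreeCap = 20L) {
  nodes <- as.character(nodes)
  if (is.null(edges$sign)) edges$sign <- "?"
  edges <- data.frame(
    source = as.character(edges$source),
    target = as.character(edges$target),
    sign = as.character(edges$sign),
    stringsAsFactors = FALSE
  )
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (regulator, target) edges collapsed to one")
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("TFNetwork", nodes = nodes, edges = edges,
      inDegreeCap = as.integer(inDegreeCap))
}

#' Nodes of a TFNetwork
#' @param network a [TFNetwork-class].
#' @return character vector of node identifiers.
#' @export
networkNodes <- function(network) network@nodes

#' Edge table of a TFNetwork
#' @param network a [TFNetwork-class].
#' @return data.frame with columns `source`, `target`, `sign`.
#' @export
networkEdges <- function(network) network@edges

#' Number of genes in the network
#' @param network a [TFNetwork-class].
#' @return integer node count g.
#' @export
networkSize <- function(network) length(network@nodes)

#' Regulators of a target, in the fixed (lexicographic) order
#'
#' The returned order defines the rule's leaf indexing: the first regulator
#' is the most significant bit of the leaf index.
#'
#' @param network a [TFNetwork-class].
#' @param target a node identifier.
#' @return character vector of regulators (possibly empty), sorted.
#' @export
regulatorsOf <- function(network, target) {
  if (!target %in% network@nodes) {
    stop("unknown node: ", target)
  }
  regs <- network@edges$source[network@edges$target == target]
  sort(unique(regs), method = "radix")
}

setMethod("show", "TFNetwork", function(object) {
  cat("TFNetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  cat("  nodes:", paste(utils::head(object@nodes, 8), collapse = ", "),
      if (length(object@nodes) > 8) "..." else "", "\n")
  if (nrow(object@edges) > 0) {
    sgn <- table(factor(object@edges$sign, levels = c("+", "-", "?")))
    cat(sprintf("  signs: %d activating, %d inhibiting, %d unknown\n",
                sgn[["+"]], sgn[["-"]], sgn[["?"]]))
  }
})
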