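# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive everything from first principles (naive
# loops, exhaustive enumeration, direct linear solves) and share no code
# with the implementation paths they check.

# Naive rule fit: triple loop over observations, leaves and regulators,
# applying the defining formulas directly.
naiveFitRule <- function(Rprime, Tprime) {
  m <- nrow(Rprime)
  n <- ncol(Rprime)
  nl <- 2^n
  w <- matrix(0, m, nl)
  for (i in seq_len(m)) {
    for (j in seq_len(nl) - 1L) {
      p <- 1
      for (k in seq_len(n)) {
        bit <- bitwAnd(bitwShiftR(j, n - k), 1L)
        p <- p * if (bit == 1L) Rprime[i, k] else 1 - Rprime[i, k]
      }
      w[i, j + 1L] <- p
    }
  }
  u <- numeric(nl)
  v <- numeric(nl)
  for (j in seq_len(nl)) {
    u[j] <- 1 - if (m > 0) max(w[, j]) else 0
    num <- 0.5 * u[j]
    den <- u[j]
    for (i in seq_len(m)) {
      num <- num + Tprime[i] * w[i, j]
      den <- den + w[i, j]
    }
    v[j] <- num / den
  }
  list(W = w, U = u, V = v)
}

# Flip probability from raw slot access (no package lookup helpers).
oracleFlipProb <- function(ruleset, bits, nodes, i) {
  rule <- ruleset@rules[[nodes[i]]]
  regs <- rule@regulators
  if (length(regs) == 0L) {
    pOn <- rule@V[1L]
  } else {
    j <- 0L
    for (k in seq_along(regs)) {
      j <- j * 2L + bits[match(regs[k], nodes)]
    }
    pOn <- rule@V[j + 1L]
  }
  if (bits[i] == 1L) 1 - pOn else pOn
}

# Exhaustively build the full pruned STG over all 2^g states and return
# its terminal SCCs (as sorted lists of sorted bitstring vectors).
oracleTerminalSCCs <- function(ruleset, threshold = 0.5) {
  nodes <- ruleset@network@nodes
  g <- length(nodes)
  nS <- 2^g
  keys <- character(nS)
  edges <- list()
  for (s in seq_len(nS) - 1L) {
    bits <- integer(g)
    for (k in seq_len(g)) bits[k] <- bitwAnd(bitwShiftR(s, g - k), 1L)
    keys[s + 1L] <- paste(bits, collapse = "")
    for (i in seq_len(g)) {
      fp <- oracleFlipProb(ruleset, bits, nodes, i)
      if (fp >= threshold) {
        nb <- bits
        nb[i] <- 1L - nb[i]
        edges[[length(edges) + 1L]] <- c(keys[s + 1L],
                                         paste(nb, collapse = ""))
      }
    }
  }
  el <- if (length(edges) > 0) do.call(rbind, edges) else
    matrix(character(0), 0, 2)
  gr <- igraph::graph_from_data_frame(
    as.data.frame(el, stringsAsFactors = FALSE),
    directed = TRUE, vertices = keys
  )
  comps <- igraph::components(gr, mode = "strong")
  memb <- comps$membership
  out <- list()
  for (cid in seq_len(comps$no)) {
    members <- names(memb)[memb == cid]
    succ <- unique(unlist(lapply(members, function(v) {
      names(igraph::neighbors(gr, v, mode = "out"))
    })))
    if (length(setdiff(succ, members)) == 0L) {
      out[[length(out) + 1L]] <- sort(members)
    }
  }
  out[order(vapply(out, `[[`, character(1), 1L))]
}

# Random probabilistic rule set over a random sparse digraph.
randomRuleSet <- function(g, maxInDegree = 3L) {
  nodes <- sprintf("R%02d", seq_len(g))
  src <- lapply(nodes, function(nd) {
    sample(nodes, sample.int(maxInDegree, 1L))
  })
  edges <- data.frame(
    source = unlist(src),
    target = rep(nodes, vapply(src, length, integer(1))),
    sign = "?", stringsAsFactors = FALSE
  )
  network <- TFNetwork(nodes, edges)
  rules <- lapply(nodes, function(nd) {
    regs <- regulatorsOf(network, nd)
    nl <- 2L^length(regs)
    new("BooleanRule", target = nd, regulators = regs,
        V = stats::runif(nl), W = matrix(numeric(0), 0L, nl),
        U = rep(1, nl))
  })
  names(rules) <- nodes
  new("RuleSet", network = network, rules = rules)
}

# Expected escape steps for a birth-death chain on Hamming distance
# levels: nFree independent TFs all with constant flip probability
# pFlip, absorbed when distance > radius. Independent of the package's
# full-state-space solve.
birthDeathEscapeSteps <- function(nFree, pFlip, radius) {
  nT <- radius + 1L # transient levels d = 0..radius
  A <- diag(nT)
  b <- rep(1, nT)
  for (d in 0:radius) {
    up <- (nFree - d) / nFree * pFlip
    down <- d / nFree * pFlip
    i <- d + 1L
    A[i, i] <- A[i, i] - (1 - up - down)
    if (d > 0) A[i, i - 1L] <- -down
    if (d < radius) A[i, i + 1L] <- -up
  }
  solve(A, b)[1L]
}

# Tiny bimodal expression matrix with known generating states.
makeBimodalMatrix <- function(states, nPerCluster = 10, muOff = 1,
                              muOn = 6, sigma = 0.1) {
  genes <- names(states[[1L]])
  cols <- list()
  labels <- character(0)
  for (cl in names(states)) {
    mu <- ifelse(states[[cl]] == 1L, muOn, muOff)
    for (s in seq_len(nPerCluster)) {
      id <- paste0(cl, "_", s)
      cols[[id]] <- pmax(stats::rnorm(length(genes), mu, sigma), 0)
      labels[id] <- cl
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- genes
  list(mat = mat, labels = labels)
}
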