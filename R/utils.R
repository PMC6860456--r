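# Bitstring / state helpers. A NetworkState is a named integer vector of
# 0/1 over the network nodes, in node order; its bitstring form is the
# concatenation of those bits.

#' Convert a binary state vector to its bitstring key
#'
#' @param state integer/numeric vector of 0/1, in node order.
#' @return single character string of 0s and 1s.
#' @export
stateToString <- function(state) {
  paste(as.integer(state), collapse = "")
}

#' Convert a bitstring key back to a named binary state vector
#'
#' @param s bitstring of 0s and 1s.
#' @param nodes node names, one per character of `s`.
#' @return named integer vector of 0/1.
#' @export
stateFromString <- function(s, nodes) {
  bits <- as.integer(strsplit(s, "", fixed = TRUE)[[1]])
  if (length(bits) != length(nodes)) {
    stop("bitstring length does not match the number of nodes")
  }
  names(bits) <- nodes
  bits
}

#' Hamming distance between two binary states
#'
#' @param a,b binary vectors (or bitstrings) of equal length.
#' @return integer count of differing positions.
#' @export
hammingDistance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) {
    a <- as.integer(strsplit(a, "", fixed = TRUE)[[1]])
  }
  if (is.character(b) && length(b) == 1L) {
    b <- as.integer(strsplit(b, "", fixed = TRUE)[[1]])
  }
  if (length(a) != length(b)) stop("states must have equal length")
  sum(a != b)
}

# Matrix of all 2^n binary states (rows), first column = most significant
# bit. Row r (1-based) encodes the integer r - 1.
allStatesMatrix <- function(n) {
  if (n == 0L) {
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  if (n > 20L) stop("exhaustive state enumeration limited to 20 nodes")
  ints <- 0:(2L^n - 1L)
  m <- matrix(0L, nrow = length(ints), ncol = n)
  for (k in seq_len(n)) {
    m[, k] <- bitwAnd(ints %/% 2L^(n - k), 1L)
  }
  m
}

# Powers of two for leaf indexing: first regulator = most significant bit.
leafBitWeights <- function(n) {
  if (n == 0L) return(numeric(0))
  2^((n - 1L):0)
}

# Derive a reproducible 31-bit sub-seed from a base seed and a counter.
deriveSeed <- function(seed, counter) {
  if (is.na(seed)) return(NA_integer_)
  as.integer((as.double(seed) * 48271 + counter * 16807) %% 2147483647)
}

# Run expr under a locally-set seed when seed is not NA.
withSeed <- function(seed, expr) {
  if (is.na(seed)) {
    force(expr)
  } else {
    withr::with_seed(seed, expr)
  }
}
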