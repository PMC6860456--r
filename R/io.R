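#' Read a gene-by-sample expression matrix
#'
#' Expects TSV or CSV (sniffed from the header line, or forced with `sep`)
#' with the first column holding gene identifiers and the header row
#' holding sample identifiers. Values must be finite, non-negative,
#' log-scale expression (e.g. log1p TPM); no normalization is applied.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) sniffs `\t` vs `,`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`.
#' @export
readExpression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e))
  )
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validateExpressionMatrix(mat)
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = mat))
}

# Shared invariants of the expression input.
validateExpressionMatrix <- function(mat) {
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
  if (ncol(mat) < 2L) stop("expression matrix needs at least 2 samples")
  if (any(!is.finite(mat))) stop("expression values must be finite")
  if (any(mat < 0)) stop("expression values must be non-negative")
  invisible(mat)
}

#' Read a regulator-to-target edge list
#'
#' Expects TSV with header `source<TAB>target[<TAB>sign]`, sign in
#' `{+, -, ?}`. The node set is the union of endpoints unless `nodes` is
#' given.
#'
#' @param path file path.
#' @param nodes optional full node set (must cover all endpoints).
#' @param inDegreeCap passed to [TFNetwork()].
#' @return a [TFNetwork-class].
#' @export
readNetwork <- function(path, nodes = NULL, inDegreeCap = 20L) {
  if (!file.exists(path)) stop("network file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e))
  )
  if (ncol(df) < 2L) stop("network file needs source and target columns")
  names(df)[1:2] <- c("source", "target")
  if (ncol(df) >= 3L) names(df)[3L] <- "sign" else df$sign <- "?"
  bad <- which(!df$sign %in% c("+", "-", "?"))
  if (length(bad) > 0) {
    stop("malformed sign at line ", bad[1L] + 1L, " of ", path)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(df$source, df$target)))
  TFNetwork(nodes, df[, c("source", "target", "sign")],
            inDegreeCap = inDegreeCap)
}

#' Read sample-to-cluster labels
#'
#' CSV with header `sample,cluster`.
#'
#' @param path file path.
#' @return named character vector: labels named by sample id.
#' @export
readClusterLabels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs sample and cluster columns")
  if (anyDuplicated(df[[1L]])) stop("duplicate sample labels")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Load and cross-validate the three standard inputs
#'
#' Reads the expression matrix, the regulatory network, and (optionally)
#' sample cluster labels, and cross-references them: every network node
#' must be a gene in the matrix and every labeled sample must be a matrix
#' column.
#'
#' @param expressionPath,networkPath,labelsPath file paths; `labelsPath`
#'   may be `NULL`.
#' @param inDegreeCap passed to [readNetwork()].
#' @return list with elements `expression` (SummarizedExperiment),
#'   `network` ([TFNetwork-class]) and `labels` (named character or NULL).
#' @export
loadInputs <- function(expressionPath, networkPath, labelsPath = NULL,
                       inDegreeCap = 20L) {
  se <- readExpression(expressionPath)
  network <- readNetwork(networkPath, inDegreeCap = inDegreeCap)
  missing <- setdiff(networkNodes(network), rownames(se))
  if (length(missing) > 0) {
    stop("unknown node: network gene(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  labels <- NULL
  if (!is.null(labelsPath)) {
    labels <- readClusterLabels(labelsPath)
    missing <- setdiff(names(labels), colnames(se))
    if (length(missing) > 0) {
      stop("labeled sample(s) absent from the expression matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  list(expression = se, network = network, labels = labels)
}

# Decimal text that round-trips doubles exactly.
fmtExact <- function(x) sprintf("%.17g", x)

#' Write fitted rules to disk
#'
#' One TSV per target gene (`rule_<target>.tsv`): 2^N rows, one binary
#' column per regulator (in the fixed order), then `v`, `u` and
#' `n_effective` (the total observation weight on the leaf). Probabilities
#' are written as decimal text that reproduces the doubles exactly on
#' re-read.
#'
#' @param ruleset a [RuleSet-class].
#' @param outDir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeRules <- function(ruleset, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  paths <- character(0)
  for (rule in ruleset@rules) {
    n <- length(rule@regulators)
    states <- allStatesMatrix(n)
    neff <- if (nrow(rule@W) > 0) colSums(rule@W) else
      rep(NA_real_, 2L^n)
    df <- as.data.frame(states)
    names(df) <- if (n > 0) rule@regulators else character(0)
    df$v <- fmtExact(rule@V)
    df$u <- fmtExact(rule@U)
    df$n_effective <- ifelse(is.na(neff), "NA", fmtExact(neff))
    p <- file.path(outDir, paste0("rule_", rule@target, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read rules back from a directory written by [writeRules()]
#'
#' @param dir directory containing `rule_<target>.tsv` files.
#' @param network the [TFNetwork-class] the rules belong to.
#' @return a [RuleSet-class] (W matrices are empty: per-observation weights
#'   are not serialized).
#' @export
readRules <- function(dir, network) {
  rules <- vector("list", length(network@nodes))
  names(rules) <- network@nodes
  for (node in network@nodes) {
    p <- file.path(dir, paste0("rule_", node, ".tsv"))
    if (!file.exists(p)) stop("missing rule file for node ", node)
    df <- utils::read.table(p, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    regs <- setdiff(names(df), c("v", "u", "n_effective"))
    v <- as.numeric(df$v)
    u <- as.numeric(df$u)
    rules[[node]] <- new("BooleanRule", target = node,
                         regulators = sort(regs, method = "radix"),
                         V = v, W = matrix(numeric(0), 0, length(v)), U = u)
  }
  new("RuleSet", network = network, rules = rules)
}

#' Write a pseudo-attractor set as CSV
#'
#' One row per member state: binary TF columns, `attractor_id`, `scc_size`,
#' `representative`, and (when assigned) `cluster`, `ambiguous` and one
#' `dist_<cluster>` column per cluster reference state.
#'
#' @param attractorSet a [PseudoAttractorSet-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeAttractors <- function(attractorSet, path) {
  df <- attractorTable(attractorSet)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate a pseudo-attractor set
#'
#' @param attractorSet a [PseudoAttractorSet-class].
#' @return data.frame, one row per member state (see [writeAttractors()]).
#' @export
attractorTable <- function(attractorSet) {
  nodes <- attractorSet@nodes
  rows <- list()
  for (i in seq_along(attractorSet@attractors)) {
    a <- attractorSet@attractors[[i]]
    for (s in a$members) {
      bits <- as.list(stateFromString(s, nodes))
      row <- c(bits, list(
        attractor_id = i,
        scc_size = length(a$members),
        representative = a$representative
      ))
      if (!is.null(a$cluster)) {
        row$cluster <- a$cluster
        row$ambiguous <- a$ambiguous
        for (cl in names(a$distances)) {
          row[[paste0("dist_", cl)]] <- a$distances[[cl]]
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE)
    }
  }
  if (length(rows) == 0) {
    df <- as.data.frame(matrix(integer(0), 0, length(nodes)))
    names(df) <- nodes
    df$attractor_id <- integer(0)
    df$scc_size <- integer(0)
    df$representative <- character(0)
    return(df)
  }
  do.call(rbind, rows)
}

#' Read a pseudo-attractor CSV back
#'
#' @param path CSV written by [writeAttractors()].
#' @param nodes node order of the originating network.
#' @param threshold the pruning threshold the attractors were found at.
#' @return a [PseudoAttractorSet-class] (cluster annotations, if present,
#'   are restored).
#' @export
readAttractors <- function(path, nodes, threshold = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  attractors <- list()
  if (nrow(df) > 0) {
    for (id in sort(unique(df$attractor_id))) {
      sub <- df[df$attractor_id == id, , drop = FALSE]
      members <- sort(apply(sub[, nodes, drop = FALSE], 1L,
                            paste, collapse = ""))
      a <- list(members = unname(members), representative = members[1L])
      if ("cluster" %in% names(sub)) {
        a$cluster <- sub$cluster[1L]
        a$ambiguous <- as.logical(sub$ambiguous[1L])
        dcols <- grep("^dist_", names(sub), value = TRUE)
        a$distances <- as.list(sub[1L, dcols, drop = FALSE])
        names(a$distances) <- sub("^dist_", "", dcols)
      }
      attractors[[length(attractors) + 1L]] <- a
    }
  }
  new("PseudoAttractorSet", nodes = nodes, attractors = attractors,
      threshold = threshold)
}

#' Write perturbation stability scores as CSV
#'
#' Columns: `tf`, `mode`, `start_attractor`, `cluster`, `mean_steps`,
#' `reference_mean_steps`, `score`, `n_walks`, `seed`.
#'
#' @param scores data.frame from [scanPerturbations()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeScores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scores CSV back
#' @param path CSV written by [writeScores()].
#' @return data.frame.
#' @export
readScores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(start_attractor = "character"))
}

#' Read a `key: value` configuration file
#'
#' YAML-style flat key/value pairs for the search and walk parameters;
#' unknown keys are carried through. CLI flags override file values.
#'
#' @param path config file path.
#' @return named list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    val <- m[3L]
    num <- suppressWarnings(as.numeric(val))
    out[[m[2L]]] <- if (!is.na(num)) num else val
  }
  out
}
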