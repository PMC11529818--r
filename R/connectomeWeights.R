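## Resistor-circuit equivalent connection weights. Synapse counts are
## treated as conductances: a two-edge path through one intermediate neuron
## contributes the series weight W1*W2/(W1+W2), and parallel paths add.
## Only direct edges and paths with exactly one intermediate are considered.

#' Construct a connectome graph from edge and node tables
#'
#' Validates the tables, drops self-loops, and applies the synapse-count
#' cutoff before any path computation (as for all connectivity analysis).
#'
#' @param edges data.frame with columns `pre`, `post` (node ids), `count`
#'   and the six NT count columns [ntNames()] summing to `count` per edge.
#' @param nodes data.frame with columns `id`, `type`, `hemisphere`
#'   (`"left"`, `"right"` or `"left/right"`). Ids are handled as character
#'   (FlyWire-style 64-bit ids exceed R integers).
#' @param cutoff minimum synapse count for an edge to be retained
#'   (default 10).
#' @return a [ConnectomeGraph-class].
#' @export
connectomeGraph <- function(edges, nodes, cutoff = 10) {
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      hemisphere = as.character(nodes$hemisphere),
                      stringsAsFactors = FALSE)
  edges$pre <- as.character(edges$pre)
  edges$post <- as.character(edges$post)
  if (nrow(edges)) {
    if (!all(edges$pre %in% nodes$id) || !all(edges$post %in% nodes$id))
      stop("edge referencing unknown node")
    nt_sum <- rowSums(as.matrix(edges[, ntNames()]))
    if (any(abs(nt_sum - edges$count) > 1e-9))
      stop("inconsistent NT counts")
    edges <- edges[edges$count >= cutoff & edges$pre != edges$post, ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  methods::new("ConnectomeGraph", nodes = nodes,
               edges = edges[, c("pre", "post", "count", ntNames()),
                             drop = FALSE],
               synapseCutoff = cutoff)
}

#' Read a connectome from edge/node CSV files
#'
#' Edge CSV columns: `pre_id, post_id, syn_count, gaba, ach, glut, oct,
#' ser, da`. Node CSV columns: `id, type, hemisphere`.
#'
#' @param edgePath,nodePath CSV file paths.
#' @param cutoff synapse cutoff (default 10).
#' @return a [ConnectomeGraph-class].
#' @export
readConnectomeCsv <- function(edgePath, nodePath, cutoff = 10) {
  e <- utils::read.csv(edgePath, colClasses = c(pre_id = "character",
                                                post_id = "character"))
  nd <- utils::read.csv(nodePath, colClasses = c(id = "character"))
  names(e)[names(e) == "pre_id"] <- "pre"
  names(e)[names(e) == "post_id"] <- "post"
  names(e)[names(e) == "syn_count"] <- "count"
  connectomeGraph(e, nd, cutoff = cutoff)
}

#' Write a connectome to edge/node CSV files
#'
#' @param graph a [ConnectomeGraph-class].
#' @param edgePath,nodePath output CSV file paths.
#' @return invisibly, the two paths.
#' @export
writeConnectomeCsv <- function(graph, edgePath, nodePath) {
  e <- edgeTable(graph)
  names(e)[names(e) == "pre"] <- "pre_id"
  names(e)[names(e) == "post"] <- "post_id"
  names(e)[names(e) == "count"] <- "syn_count"
  utils::write.csv(e, edgePath, row.names = FALSE)
  utils::write.csv(nodeTable(graph), nodePath, row.names = FALSE)
  invisible(c(edgePath, nodePath))
}

#' Series weight of a two-edge path
#'
#' Resistor rule for conductances in series: the inverse of the sum of the
#' inverses, \eqn{W_1 W_2 / (W_1 + W_2)}. Always at most `min(W1, W2)`.
#'
#' @param w1,w2 positive edge weights (vectorised).
#' @return numeric.
#' @export
seriesWeight <- function(w1, w2) {
  if (any(w1 <= 0 | w2 <= 0)) stop("series weights require positive inputs")
  w1 * w2 / (w1 + w2)
}

## Internal: dense adjacency (and per-NT adjacency) over graph nodes.
adjacencyMatrices <- function(graph, nt = FALSE) {
  ids <- nodeTable(graph)$id
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- edgeTable(graph)
  i <- match(e$pre, ids); j <- match(e$post, ids)
  W[cbind(i, j)] <- e$count
  out <- list(W = W)
  if (nt) {
    out$NT <- lapply(ntNames(), function(ch) {
      M <- matrix(0, n, n, dimnames = list(ids, ids))
      M[cbind(i, j)] <- e[[ch]]
      M
    })
    names(out$NT) <- ntNames()
  }
  out
}

#' Equivalent weight between two neurons
#'
#' Direct edge weight (0 if absent) plus the sum over all intermediate
#' neurons `m` (any node other than source and target, unless excluded)
#' of the series weight of the two-edge path through `m`. Missing
#' connectivity contributes 0; directionality is strictly respected.
#'
#' @param graph a [ConnectomeGraph-class].
#' @param source,target node ids (source != target).
#' @param maxIntermediates 0 (direct only) or 1 (default).
#' @param excludeIntermediates node ids barred from serving as
#'   intermediates (e.g. to restrict to out-of-class relays).
#' @return scalar equivalent weight.
#' @export
equivalentWeight <- function(graph, source, target, maxIntermediates = 1,
                             excludeIntermediates = character()) {
  stopifnot(source != target, maxIntermediates %in% c(0, 1))
  A <- adjacencyMatrices(graph)$W
  if (!source %in% rownames(A) || !target %in% rownames(A))
    stop("unknown node id")
  w <- A[source, target]
  if (maxIntermediates == 1) {
    mids <- setdiff(rownames(A), c(source, target, excludeIntermediates))
    w1 <- A[source, mids]; w2 <- A[mids, target]
    ok <- w1 > 0 & w2 > 0
    if (any(ok)) w <- w + sum(w1[ok] * w2[ok] / (w1[ok] + w2[ok]))
  }
  w
}

#' Neurotransmitter-resolved equivalent weight
#'
#' Decomposes the equivalent weight between two neurons into the 36 NT
#' path types: each one-intermediate path adds
#' \eqn{W_1^i W_2^j / (W_1 + W_2)} to cell (i, j), where \eqn{W_1^i} is the
#' number of first-edge synapses assigned NT i and \eqn{W_2^j} the second-
#' edge count for NT j. A direct edge has a single NT per synapse and its
#' counts are placed on the diagonal cells (i, i). The matrix total equals
#' the scalar equivalent weight exactly, since
#' \eqn{(\sum_i W_1^i)(\sum_j W_2^j)/(W_1+W_2) = W_1 W_2/(W_1+W_2)}.
#'
#' @inheritParams equivalentWeight
#' @return 6 x 6 numeric matrix (first-edge NT x second-edge NT) with
#'   dimnames [ntNames()].
#' @seealso [ntPathwaySummary()] for the per-NT marginals.
#' @export
ntEquivalentWeight <- function(graph, source, target, maxIntermediates = 1,
                               excludeIntermediates = character()) {
  stopifnot(source != target, maxIntermediates %in% c(0, 1))
  adj <- adjacencyMatrices(graph, nt = TRUE)
  A <- adj$W
  if (!source %in% rownames(A) || !target %in% rownames(A))
    stop("unknown node id")
  M <- matrix(0, 6L, 6L, dimnames = list(ntNames(), ntNames()))
  if (A[source, target] > 0) {
    d <- vapply(adj$NT, function(N) N[source, target], 0)
    diag(M) <- diag(M) + d
  }
  if (maxIntermediates == 1) {
    mids <- setdiff(rownames(A), c(source, target, excludeIntermediates))
    w1 <- A[source, mids]; w2 <- A[mids, target]
    ok <- which(w1 > 0 & w2 > 0)
    for (k in ok) {
      m <- mids[k]
      nt1 <- vapply(adj$NT, function(N) N[source, m], 0)
      nt2 <- vapply(adj$NT, function(N) N[m, target], 0)
      M <- M + outer(nt1, nt2) / (w1[k] + w2[k])
    }
  }
  M
}

#' Equivalent-weight matrix between source and target sets
#'
#' Pairwise [equivalentWeight()] for all (source, target) pairs; pairs
#' where source equals target are 0. Optionally carries the full NT
#' path-type tensor.
#'
#' @param graph a [ConnectomeGraph-class].
#' @param sources,targets character vectors of node ids.
#' @param ntPaths also compute the 6 x 6 NT decomposition per pair.
#' @param maxIntermediates 0 or 1 (default 1).
#' @param excludeIntermediates node ids barred as intermediates.
#' @return an [EquivalentWeightMatrix-class].
#' @export
equivalentWeightMatrix <- function(graph, sources, targets, ntPaths = FALSE,
                                   maxIntermediates = 1,
                                   excludeIntermediates = character()) {
  stopifnot(length(sources) >= 1L, length(targets) >= 1L)
  adj <- adjacencyMatrices(graph, nt = ntPaths)
  A <- adj$W
  miss <- setdiff(c(sources, targets), rownames(A))
  if (length(miss)) stop("unknown node id: ", paste(miss, collapse = ", "))
  W <- matrix(0, length(sources), length(targets),
              dimnames = list(sources, targets))
  nt_arr <- if (ntPaths)
    array(0, c(length(sources), length(targets), 6L, 6L),
          dimnames = list(sources, targets, ntNames(), ntNames()))
  else array(numeric(0))
  ids <- rownames(A)
  ntStack <- if (ntPaths)
    vapply(adj$NT, identity, matrix(0, nrow(A), ncol(A)))  # ids x ids x 6
  for (s in sources) for (tg in targets) {
    if (s == tg) next
    w1 <- A[s, ]; w2 <- A[, tg]
    w1[intersect(c(s, tg, excludeIntermediates), ids)] <- 0
    ok <- which(w1 > 0 & w2 > 0 & maxIntermediates >= 1)
    tot <- w1[ok] + w2[ok]
    W[s, tg] <- A[s, tg] + sum(w1[ok] * w2[ok] / tot)
    if (ntPaths) {
      M <- matrix(0, 6L, 6L)
      if (A[s, tg] > 0) diag(M) <- ntStack[s, tg, ]
      if (length(ok)) {
        nt1 <- matrix(ntStack[s, ok, ], length(ok), 6L)
        nt2 <- matrix(ntStack[ok, tg, ], length(ok), 6L)
        M <- M + crossprod(nt1, nt2 / tot)
      }
      nt_arr[s, tg, , ] <- M
    }
  }
  methods::new("EquivalentWeightMatrix", weights = W, ntPaths = nt_arr)
}

#' Per-NT pathway marginals of an NT-resolved weight matrix
#'
#' Aggregates the 6 x 6 path-type tensor into single-NT pathway weights per
#' (source, target) pair, either by the NT of the path's terminal (second)
#' edge — e.g. "GABAergic input onto the target" sums cells (., gaba) — or
#' by the NT of the first edge. Both marginals are exposed because either
#' aggregation can be of interest.
#'
#' @param ewm an [EquivalentWeightMatrix-class] computed with
#'   `ntPaths = TRUE`.
#' @param by `"second"` (terminal-edge NT, default) or `"first"`.
#' @return numeric array (sources x targets x 6).
#' @export
ntPathwaySummary <- function(ewm, by = c("second", "first")) {
  by <- match.arg(by)
  arr <- ntPathArray(ewm)
  if (is.null(arr)) stop("NT path tensor not computed; use ntPaths = TRUE")
  apply(arr, if (by == "second") c(1, 2, 4) else c(1, 2, 3), sum)
}

#' Write an equivalent-weight matrix as CSV
#'
#' @param ewm an [EquivalentWeightMatrix-class].
#' @param path output path; rows are sources (first column `source`).
#' @return `path`, invisibly.
#' @export
writeWeightMatrixCsv <- function(ewm, path) {
  W <- eqWeights(ewm)
  df <- data.frame(source = rownames(W), W, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an equivalent-weight matrix from CSV
#'
#' @param path CSV written by [writeWeightMatrixCsv()].
#' @return an [EquivalentWeightMatrix-class] (without NT tensor).
#' @export
readWeightMatrixCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(source = "character"))
  W <- as.matrix(df[, -1L, drop = FALSE])
  rownames(W) <- df$source
  methods::new("EquivalentWeightMatrix", weights = W,
               ntPaths = array(numeric(0)))
}
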