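# Shared fixtures and independent oracles, built in code at test time.

# Random proper rigid motion (rotation + translation). Returns a function
# mapping an n x 3 matrix (or length-3 vector) to its transformed copy.
randomRigid <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tr <- rnorm(3, 0, 10)
  function(x) {
    if (is.null(dim(x))) as.numeric(Q %*% x + tr)
    else t(Q %*% t(x) + tr)
  }
}

# Rotation-only version (for free direction vectors).
rigidRotation <- function(rigid) {
  origin <- rigid(c(0, 0, 0))
  function(v) rigid(v) - origin
}

# Random directed synapse graph with random NT splits; edge weights span
# the cutoff so thresholding is exercised.
randomGraphTables <- function(n_nodes, p_edge, seed, w_max = 60) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- data.frame(id = ids, type = "generic", hemisphere = "left")
  rows <- list()
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (i == j || runif(1) >= p_edge) next
    w <- sample.int(w_max, 1)
    nt <- as.vector(stats::rmultinom(1, w, rep(1 / 6, 6)))
    rows[[length(rows) + 1L]] <-
      c(list(pre = ids[i], post = ids[j], count = w),
        stats::setNames(as.list(nt), ntNames()))
  }
  edges <- if (length(rows)) do.call(rbind, lapply(rows, as.data.frame))
  else cbind(data.frame(pre = character(), post = character(),
                        count = numeric()),
             stats::setNames(as.data.frame(matrix(numeric(0), 0, 6)),
                             ntNames()))
  list(edges = edges, nodes = nodes)
}

# Exhaustive enumeration oracle for equivalent weights: all length-1 and
# length-2 directed paths from s to t over the retained edges.
bruteForceEquivalent <- function(graph, s, t) {
  e <- edgeTable(graph)
  W <- function(a, b) {
    hit <- e$count[e$pre == a & e$post == b]
    if (length(hit)) hit[1] else 0
  }
  total <- W(s, t)
  for (m in setdiff(nodeTable(graph)$id, c(s, t))) {
    w1 <- W(s, m); w2 <- W(m, t)
    if (w1 > 0 && w2 > 0) total <- total + w1 * w2 / (w1 + w2)
  }
  total
}

# A tiny ObservableSeries with given constant signals.
constantObservables <- function(n, frameRate = 100, ...) {
  vals <- list(...)
  m <- do.call(cbind, lapply(vals, rep_len, n))
  colnames(m) <- names(vals)
  observableSeries(m, frameRate)
}

# Accuracy of a classified ethogram against ground truth, excluding frames
# within `edge` frames of any ground-truth transition.
frameAccuracy <- function(et, gt, edge = 1L) {
  lab <- actionFlags(et)
  glab <- actionFlags(gt)
  excl <- rep(FALSE, nrow(glab))
  for (a in colnames(glab)) {
    g <- glab[, a]
    g[is.na(g)] <- FALSE
    ch <- which(diff(g) != 0)
    for (k in ch)
      excl[max(1L, k - edge + 1L):min(nrow(glab), k + edge + 1L)] <- TRUE
  }
  ok <- !excl & !is.na(glab[, 1])
  vapply(colnames(glab),
         function(a) mean((lab[, a] == glab[, a])[ok], na.rm = TRUE),
         0)
}
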