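## Downstream structure of equivalent-weight matrices: similarity
## clustering of source neurons by their DN connectivity profiles,
## strong-connection binarization, PCA biplots and SVM separating planes.

#' Cosine similarity among source rows
#'
#' Each row of the weight matrix is Euclidean-normalised; the similarity of
#' two sources is the cosine of the angle between their rows (in [0, 1] for
#' nonnegative weights). Zero-norm rows cannot be normalised and are
#' dropped with a warning.
#'
#' @param weights an [EquivalentWeightMatrix-class] or numeric matrix
#'   (sources x targets).
#' @return symmetric similarity matrix over the retained sources.
#' @export
cosineSimilarityMatrix <- function(weights) {
  W <- if (methods::is(weights, "EquivalentWeightMatrix")) eqWeights(weights)
  else weights
  nrm <- sqrt(rowSums(W^2))
  if (all(nrm == 0)) stop("all-zero weight matrix")
  if (any(nrm == 0)) {
    warning("dropping ", sum(nrm == 0), " zero-norm row(s)")
    W <- W[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  Wn <- W / nrm
  S <- Wn %*% t(Wn)
  S[S > 1] <- 1; S[S < -1] <- -1
  S
}

#' Hierarchical clustering of sources by connectivity similarity
#'
#' Agglomerative clustering on the distance 1 - cosine similarity, cut at
#' `k` clusters. Average linkage by default (single/complete also
#' accepted).
#'
#' @param similarity square similarity matrix (e.g. from
#'   [cosineSimilarityMatrix()]).
#' @param k number of clusters (default 3).
#' @param linkage `hclust` agglomeration method (default "average").
#' @return a [ClusterResult-class].
#' @export
clusterSources <- function(similarity, k = 3, linkage = "average") {
  n <- nrow(similarity)
  if (k > n) stop("k exceeds the number of sources")
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = linkage)
  labels <- stats::cutree(hc, k = k)
  methods::new("ClusterResult", labels = labels, similarity = similarity,
               linkage = hc)
}

#' Cluster-to-DN connectivity profiles
#'
#' For each cluster, the mean equivalent weight of its member sources to
#' each target DN; a DN is strongly connected to a cluster when that mean
#' strictly exceeds `strongThreshold` (20 by default, an elbow point of the
#' weight distribution). Also reports, per DN, the number of clusters it is
#' strong for (multiplicity).
#'
#' @param weights an [EquivalentWeightMatrix-class] or matrix.
#' @param labels cluster labels aligned with the weight rows.
#' @param strongThreshold binarization threshold (default 20, strict `>`).
#' @return list with `profile` (clusters x targets mean-weight matrix),
#'   `strong` (logical matrix), `multiplicity` (integer per target).
#' @export
clusterDnProfile <- function(weights, labels, strongThreshold = 20) {
  W <- if (methods::is(weights, "EquivalentWeightMatrix")) eqWeights(weights)
  else weights
  stopifnot(length(labels) == nrow(W))
  ks <- sort(unique(labels))
  prof <- t(vapply(ks, function(k) {
    rows <- which(labels == k)
    if (length(rows) == 0L) stop("empty cluster")
    colMeans(W[rows, , drop = FALSE])
  }, numeric(ncol(W))))
  rownames(prof) <- paste0("cluster", ks)
  strong <- prof > strongThreshold
  list(profile = prof, strong = strong,
       multiplicity = colSums(strong))
}

#' PCA biplot of an equivalent-weight matrix
#'
#' Rows with total equivalent weight below `rowFilterMinTotal` are removed
#' (weakly DN-connected neurons carry little profile information), the
#' remaining rows are Euclidean-normalised, and PCA is performed (rows
#' mean-centred by default; an uncentred variant is available since
#' centring changes the variance fractions). The top-3 scores are rescaled
#' by (max loading radius)/(max |score|) so scores and loadings share a
#' plotting scale; loadings are left unscaled.
#'
#' @param weights an [EquivalentWeightMatrix-class] or matrix.
#' @param rowFilterMinTotal minimum row total (default 300).
#' @param center mean-centre the normalised rows before the
#'   eigendecomposition (default TRUE).
#' @return a [BiplotResult-class].
#' @export
pcaBiplot <- function(weights, rowFilterMinTotal = 300, center = TRUE) {
  W <- if (methods::is(weights, "EquivalentWeightMatrix")) eqWeights(weights)
  else weights
  totals <- rowSums(W)
  keep <- totals >= rowFilterMinTotal
  W <- W[keep, , drop = FALSE]
  if (nrow(W) < 4L) stop("insufficient rows after total-weight filtering")
  nrm <- sqrt(rowSums(W^2))
  if (any(nrm == 0)) {
    warning("dropping ", sum(nrm == 0), " zero-norm row(s)")
    W <- W[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
    if (nrow(W) < 4L) stop("insufficient rows after total-weight filtering")
  }
  Wn <- W / nrm
  X <- if (center) sweep(Wn, 2, colMeans(Wn)) else Wn
  sv <- svd(X)
  denom <- if (center) nrow(X) - 1L else nrow(X)
  var_all <- sv$d^2 / denom
  ve <- (var_all / sum(var_all))[1:3]
  scores <- sv$u[, 1:3, drop = FALSE] %*% diag(sv$d[1:3])
  loadings <- sv$v[, 1:3, drop = FALSE]
  rownames(scores) <- rownames(W)
  rownames(loadings) <- colnames(W)
  colnames(scores) <- colnames(loadings) <- paste0("PC", 1:3)
  max_load <- max(sqrt(rowSums(loadings^2)))
  max_score <- max(abs(scores))
  if (max_score > 0) scores <- scores * (max_load / max_score)
  methods::new("BiplotResult", scores = scores, loadings = loadings,
               varianceExplained = ve, rowTotals = rowSums(W),
               centered = center)
}

#' SVM separating planes in PC-score space
#'
#' Fits two linear maximum-margin separators in the 3D score space — one
#' for hemisphere, one for neuron class — reporting the unit plane normals,
#' 10-fold cross-validated misclassification losses and the angle between
#' the two plane normals. A hard margin is preferred (large penalty); when
#' the training data are inseparable the fit falls back to a soft margin
#' with penalty 1. Fold assignment is deterministic given the seed; folds
#' are reduced with a warning when a class has fewer members than folds.
#'
#' @param scores numeric matrix (n x 3) of PC scores.
#' @param hemisphereLabels,classLabels two-level factors/characters of
#'   length n.
#' @param cvFolds folds for cross-validation (default 10).
#' @param seed integer seed for fold assignment (default 1).
#' @return list with `normals` (2 x 3, rows `hemisphere` and `class`),
#'   `cvLosses` (length-2), `planeAngleDeg` (in [0, 90]).
#' @export
svmPlanes <- function(scores, hemisphereLabels, classLabels, cvFolds = 10,
                      seed = 1) {
  fits <- list(hemisphere = fitSvmPlane(scores, hemisphereLabels, cvFolds, seed),
               class = fitSvmPlane(scores, classLabels, cvFolds, seed + 1L))
  normals <- rbind(hemisphere = fits$hemisphere$normal,
                   class = fits$class$normal)
  ang <- angleBetweenDeg(normals[1, ], normals[2, ])
  if (ang > 90) ang <- 180 - ang
  list(normals = normals,
       cvLosses = c(hemisphere = fits$hemisphere$cvLoss,
                    class = fits$class$cvLoss),
       planeAngleDeg = ang)
}

fitSvmPlane <- function(scores, labels, cvFolds, seed) {
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labeling must have exactly two classes")
  min_class <- min(table(y))
  if (min_class < 2L) stop("each class needs at least 2 members")
  folds <- min(cvFolds, min_class)
  if (folds < cvFolds)
    warning("reducing cross-validation folds to ", folds)

  ## the hard-margin probe can hit libsvm's iteration cap on inseparable
  ## data before the soft-margin fallback takes over; that is expected
  ## (libsvm prints its iteration-cap notice directly to the console)
  fitOnce <- function(X, yy, cost) {
    suppressWarnings(e1071::svm(X, yy, kernel = "linear", cost = cost,
                                scale = FALSE))
  }
  trainFit <- function(X, yy) {
    f <- fitOnce(X, yy, cost = 1e5)  # hard margin preferred
    if (mean(stats::predict(f, X) != yy) > 0) f <- fitOnce(X, yy, cost = 1)
    f
  }

  fit <- trainFit(scores, y)
  w <- crossprod(fit$coefs, fit$SV)  # plane normal in score space
  normal <- unitize(as.numeric(w))

  ## deterministic stratified fold assignment
  set.seed(seed)
  fold_id <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  err <- 0L
  for (f in seq_len(folds)) {
    test <- fold_id == f
    m <- trainFit(scores[!test, , drop = FALSE], droplevels(y[!test]))
    pred <- stats::predict(m, scores[test, , drop = FALSE])
    err <- err + sum(as.character(pred) != as.character(y[test]))
  }
  list(normal = normal, cvLoss = err / length(y))
}

#' Rank targets by loading magnitude
#'
#' Targets sorted by the magnitude of their 3D loading vector; the profile
#' of strong DNs typically shows a sharp drop after the leading handful.
#' When cluster labels for the score rows are supplied, each target is
#' annotated with the source cluster whose centroid direction its loading
#' best aligns with (maximum cosine).
#'
#' @param biplot a [BiplotResult-class].
#' @param n number of targets to return (default 8; capped at the number
#'   of targets).
#' @param labels optional cluster labels aligned with the biplot score
#'   rows.
#' @return data.frame with `target`, `magnitude` and (when labels are
#'   given) `nearest_cluster`.
#' @export
topLoadings <- function(biplot, n = 8, labels = NULL) {
  L <- biplot@loadings
  mag <- sqrt(rowSums(L^2))
  ord <- order(mag, decreasing = TRUE)
  ord <- ord[seq_len(min(n, length(ord)))]
  out <- data.frame(target = rownames(L)[ord], magnitude = mag[ord],
                    row.names = NULL)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(biplot@scores))
    ks <- sort(unique(labels))
    cents <- t(vapply(ks, function(k)
      colMeans(biplot@scores[labels == k, , drop = FALSE]), numeric(3L)))
    cosTo <- function(v, c) sum(v * c) / (sqrt(sum(v^2)) * sqrt(sum(c^2)))
    out$nearest_cluster <- vapply(ord, function(i) {
      ks[which.max(vapply(seq_along(ks),
                          function(j) cosTo(L[i, ], cents[j, ]), 0))]
    }, ks[1])
  }
  out
}
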