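block_matrix <- function() {
  # two perfect blocks of rows over disjoint target support
  W <- rbind(c(10, 20, 0, 0), c(5, 10, 0, 0), c(20, 40, 0, 0),
             c(0, 0, 7, 7), c(0, 0, 14, 14))
  dimnames(W) <- list(paste0("s", 1:5), paste0("t", 1:4))
  W
}

test_that("cosine similarity matches the normalized dot-product oracle", {
  W <- block_matrix()
  S <- cosineSimilarityMatrix(W)
  expect_equal(S["s1", "s2"], 1)          # proportional rows
  expect_equal(S["s1", "s4"], 0)          # disjoint support
  expect_equal(diag(S), rep(1, 5), ignore_attr = TRUE)

  set.seed(81)
  R <- matrix(runif(40), 8, 5, dimnames = list(paste0("r", 1:8), NULL))
  S2 <- cosineSimilarityMatrix(R)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- sum(R[i, ] * R[j, ]) /
      sqrt(sum(R[i, ]^2) * sum(R[j, ]^2))
  expect_equal(unname(S2), oracle, tolerance = 1e-12)

  # per-row scale invariance
  R2 <- R; R2[3, ] <- R2[3, ] * 17
  expect_equal(cosineSimilarityMatrix(R2), S2, tolerance = 1e-12)

  # zero rows dropped with warning; all-zero is an error
  Rz <- R; Rz[2, ] <- 0
  expect_warning(Sz <- cosineSimilarityMatrix(Rz), "zero-norm")
  expect_equal(nrow(Sz), 7)
  expect_error(cosineSimilarityMatrix(matrix(0, 3, 3)), "all-zero")
})

test_that("hierarchical clustering recovers separable structure", {
  S <- cosineSimilarityMatrix(block_matrix())
  cl <- clusterSources(S, k = 2)
  lab <- clusterLabels(cl)
  expect_equal(adjustedRandIndex(lab, c(1, 1, 1, 2, 2)), 1)

  expect_equal(length(unique(clusterLabels(clusterSources(S, k = 5)))), 5)
  expect_error(clusterSources(S, k = 6), "exceeds")

  # permutation invariance: permuted rows give permuted labels
  p <- c(4, 2, 5, 1, 3)
  Sp <- S[p, p]
  lp <- clusterLabels(clusterSources(Sp, k = 2))
  expect_equal(adjustedRandIndex(lp, lab[p]), 1)
})

test_that("cluster-to-DN profiles binarize at a strict threshold", {
  W <- rbind(c(30, 0), c(10, 0), c(0, 50))
  dimnames(W) <- list(paste0("s", 1:3), c("d1", "d2"))
  labels <- c(1, 1, 2)
  pr <- clusterDnProfile(W, labels, strongThreshold = 20)
  expect_equal(pr$profile["cluster1", "d1"], 20)
  expect_false(pr$strong["cluster1", "d1"])   # strict >
  expect_true(pr$strong["cluster2", "d2"])
  expect_equal(unname(pr$multiplicity), c(0, 1))
  pr0 <- clusterDnProfile(W, labels, strongThreshold = 0)
  expect_true(all(pr0$strong[pr0$profile > 0]))
})

test_that("PCA biplot filters weak rows and obeys the score scaling", {
  set.seed(82)
  # planted rank-2 structure plus tiny noise, strong totals
  base <- rbind(c(100, 0, 0, 0, 0), c(0, 100, 0, 0, 0))
  W <- rbind(base[rep(1, 5), ] + matrix(runif(25, 0, 1), 5),
             base[rep(2, 5), ] + matrix(runif(25, 0, 1), 5))
  rownames(W) <- paste0("s", 1:10); colnames(W) <- paste0("t", 1:5)
  bp <- pcaBiplot(W, rowFilterMinTotal = 50)
  expect_s4_class(bp, "BiplotResult")
  # scaling: max scaled-score radius touches the max loading radius
  expect_equal(max(abs(bp@scores)),
               max(sqrt(rowSums(bp@loadings^2))), tolerance = 1e-9)
  expect_true(all(diff(bp@varianceExplained) <= 1e-12))

  # the row filter removes weak rows; too few rows is an error
  W2 <- W; W2[1:8, ] <- W2[1:8, ] * 0.01
  expect_error(pcaBiplot(W2, rowFilterMinTotal = 50), "insufficient rows")

  # rank-1 matrix: first PC explains ~100% (uncentred keeps exact rank)
  r1 <- outer(seq(1, 2, length.out = 6), c(3, 1, 2, 0.5))
  dimnames(r1) <- list(paste0("s", 1:6), paste0("t", 1:4))
  bu <- pcaBiplot(r1, rowFilterMinTotal = 0, center = FALSE)
  expect_gt(bu@varianceExplained[1], 0.9999)
})

test_that("PCA recovers a planted low-rank subspace", {
  set.seed(83)
  V <- qr.Q(qr(matrix(rnorm(6 * 3), 6, 3)))  # orthonormal target basis
  scores <- matrix(rnorm(12 * 3, sd = c(4, 2, 1)), 12, 3, byrow = TRUE)
  W <- abs(scores %*% t(V)) + 50   # positive, high totals
  dimnames(W) <- list(paste0("s", 1:12), paste0("t", 1:6))
  bp <- pcaBiplot(W, rowFilterMinTotal = 0)
  # reconstruction from top-3 scores+loadings explains almost everything
  expect_gt(sum(bp@varianceExplained), 0.99)
})

test_that("SVM planes separate planted geometry and report plane angles", {
  set.seed(84)
  n <- 40
  # two orthogonal planted separations: x-sign for hemisphere, y-sign for class
  x_side <- rep(c(-1, 1), each = n / 2)
  y_side <- rep(c(-1, 1), times = n / 2)
  scores <- cbind(x_side * 3, y_side * 3, rnorm(n, 0, 0.3)) +
    matrix(rnorm(3 * n, 0, 0.2), n, 3)
  hemi <- ifelse(x_side > 0, "left", "right")
  cls <- ifelse(y_side > 0, "A", "B")
  sv <- svmPlanes(scores, hemi, cls, cvFolds = 10, seed = 4)
  expect_equal(unname(sv$cvLosses), c(0, 0))
  expect_equal(sv$planeAngleDeg, 90, tolerance = 3)
  expect_equal(abs(sum(sv$normals["hemisphere", ] * c(1, 0, 0))), 1,
               tolerance = 0.02)

  # random labels: chance-level loss
  set.seed(85)
  perm <- sample(hemi)
  svp <- svmPlanes(scores, perm, cls, cvFolds = 10, seed = 4)
  expect_gt(svp$cvLosses[["hemisphere"]], 0.3)
  expect_lt(svp$cvLosses[["hemisphere"]], 0.7)

  expect_error(svmPlanes(scores, rep("left", n), cls), "two classes")
  idx <- c(1:3, (n / 2 + 1):(n / 2 + 3))  # 3 members per class: folds shrink
  # both labelings warn that the folds were reduced
  expect_warning(
    expect_warning(svmPlanes(scores[idx, ], hemi[idx], cls[idx],
                             cvFolds = 10, seed = 1), "reducing"),
    "reducing")
})

test_that("top loadings rank targets and annotate nearest clusters", {
  set.seed(86)
  L <- matrix(rnorm(20 * 3, 0, 0.1), 20, 3,
              dimnames = list(paste0("t", 1:20), paste0("PC", 1:3)))
  L[7, ] <- c(5, 0, 0)  # one dominant target
  bp <- new("BiplotResult",
            scores = matrix(rnorm(18), 6, 3,
                            dimnames = list(paste0("s", 1:6), NULL)),
            loadings = L, varianceExplained = c(0.5, 0.3, 0.1),
            rowTotals = rep(1, 6), centered = TRUE)
  top <- topLoadings(bp, n = 8)
  expect_equal(top$target[1], "t7")
  expect_equal(nrow(top), 8)
  expect_equal(nrow(topLoadings(bp, n = 100)), 20)  # capped at all targets

  labels <- rep(1:2, each = 3)
  bp@scores[labels == 1, ] <- matrix(rep(c(5, 0, 0), 3), 3, byrow = TRUE)
  bp@scores[labels == 2, ] <- matrix(rep(c(0, 5, 0), 3), 3, byrow = TRUE)
  top2 <- topLoadings(bp, n = 1, labels = labels)
  expect_equal(top2$nearest_cluster[1], 1)  # t7 points along cluster 1
})
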