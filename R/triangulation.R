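## DLT camera calibration and least-squares 3D reconstruction.
##
## Both rigs (the 2-view mirror chamber and the 3-camera head-fixed rig)
## are calibrated by moving a fluorescent microbead through a grid of known
## 3D positions and fitting the standard 11-parameter direct linear
## transformation per camera. 3D points are reconstructed from >= 2 views
## by stacking the DLT ray equations and solving in least squares; points
## seen by fewer than two cameras are flagged invalid, not an error.

#' Calibrate a camera by direct linear transformation
#'
#' Fits the 11 DLT coefficients from >= 6 non-coplanar 3D-2D
#' correspondences, minimising the linear (algebraic) reprojection residual.
#' Coordinates are Hartley-normalised before the homogeneous solve for
#' conditioning; coefficients are returned in the original units.
#'
#' @param calib a [CalibrationSet-class].
#' @param cameraId name of the camera within `calib@observations`.
#' @return a [CameraModel-class].
#' @export
dltCalibrate <- function(calib, cameraId) {
  stopifnot(methods::is(calib, "CalibrationSet"))
  ob <- calib@observations[[cameraId]]
  if (is.null(ob)) stop("unknown camera: ", cameraId)
  vis <- ob$visible
  X <- calib@points3d[vis, , drop = FALSE]
  uv <- ob$uv[vis, , drop = FALSE]
  if (nrow(X) < 6L) stop("degenerate calibration: fewer than 6 correspondences")

  ## similarity normalisations (centroid to origin, mean radius sqrt(d))
  c3 <- colMeans(X)
  s3 <- sqrt(3) / mean(sqrt(rowSums(sweep(X, 2, c3)^2)))
  if (!is.finite(s3)) stop("degenerate calibration: coincident points")
  Xn <- sweep(X, 2, c3) * s3
  c2 <- colMeans(uv)
  r2 <- mean(sqrt(rowSums(sweep(uv, 2, c2)^2)))
  s2 <- if (r2 > 0) sqrt(2) / r2 else 1
  uvn <- sweep(uv, 2, c2) * s2

  n <- nrow(Xn)
  A <- matrix(0, 2L * n, 12L)
  for (i in seq_len(n)) {
    x <- c(Xn[i, ], 1)
    u <- uvn[i, 1]; v <- uvn[i, 2]
    A[2L * i - 1L, ] <- c(x, rep(0, 4), -u * x)
    A[2L * i, ] <- c(rep(0, 4), x, -v * x)
  }
  sv <- svd(A)
  ## a coplanar (or otherwise degenerate) configuration leaves a >1-dim
  ## nullspace: two vanishing singular values
  if (sv$d[11] < 1e-8 * sv$d[1])
    stop("degenerate calibration: coplanar or deficient point configuration")
  Pn <- matrix(sv$v[, 12], 3L, 4L, byrow = TRUE)

  T3 <- rbind(cbind(diag(3) * s3, -s3 * c3), c(0, 0, 0, 1))
  T2 <- rbind(cbind(diag(2) * s2, -s2 * c2), c(0, 0, 1))
  P <- solve(T2) %*% Pn %*% T3
  if (abs(P[3, 4]) < 1e-12 * max(abs(P)))
    stop("degenerate calibration: camera centre at the origin scale")
  P <- P / P[3, 4]
  methods::new("CameraModel", coef = c(P[1, ], P[2, ], P[3, 1:3]),
               id = as.character(cameraId))
}

#' Project 3D points through a DLT camera
#'
#' @param model a [CameraModel-class].
#' @param xyz numeric matrix (n x 3) or length-3 vector.
#' @return numeric matrix (n x 2) of pixel coordinates; rows on the camera's
#'   singular plane come back non-finite.
#' @export
dltProject <- function(model, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  L <- model@coef
  den <- xyz %*% L[9:11] + 1
  u <- (xyz %*% L[1:3] + L[4]) / den
  v <- (xyz %*% L[5:7] + L[8]) / den
  cbind(u = as.numeric(u), v = as.numeric(v))
}

#' Triangulate one 3D point from multiple camera views
#'
#' Least-squares solution of the stacked DLT equations over the valid views.
#' Fewer than two valid views yields an invalid result (`NA`s), following
#' the rule that two views are necessary for triangulation.
#'
#' @param models list of [CameraModel-class] objects.
#' @param uv numeric matrix (cameras x 2) of observed pixel positions.
#' @param valid logical vector per camera; defaults to finite rows of `uv`.
#' @return length-3 numeric vector, or `NA`s when invalid.
#' @export
triangulatePoint <- function(models, uv, valid = NULL) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2L)
  if (is.null(valid)) valid <- apply(is.finite(uv), 1L, all)
  use <- which(valid)
  if (length(use) < 2L) return(c(NA_real_, NA_real_, NA_real_))
  A <- matrix(0, 2L * length(use), 3L)
  b <- numeric(2L * length(use))
  for (k in seq_along(use)) {
    L <- models[[use[k]]]@coef
    u <- uv[use[k], 1]; v <- uv[use[k], 2]
    A[2L * k - 1L, ] <- c(u * L[9] - L[1], u * L[10] - L[2], u * L[11] - L[3])
    b[2L * k - 1L] <- L[4] - u
    A[2L * k, ] <- c(v * L[9] - L[5], v * L[10] - L[6], v * L[11] - L[7])
    b[2L * k] <- L[8] - v
  }
  as.numeric(qr.solve(A, b))
}

#' Triangulate a series of points
#'
#' @param models list of [CameraModel-class] objects.
#' @param observations list (one per camera, same order as `models`) of lists
#'   with `uv` (n x 2) and `visible` (logical n).
#' @return list with `points` (n x 3 matrix, `NA` rows where invalid) and
#'   `valid` (logical n).
#' @export
triangulatePoints <- function(models, observations) {
  stopifnot(length(models) == length(observations))
  n <- nrow(observations[[1]]$uv)
  pts <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  ok <- logical(n)
  for (i in seq_len(n)) {
    uv <- t(vapply(observations, function(o) o$uv[i, ], numeric(2)))
    vis <- vapply(observations, function(o) isTRUE(o$visible[i]), logical(1))
    p <- triangulatePoint(models, uv, vis & apply(is.finite(uv), 1L, all))
    if (all(is.finite(p))) { pts[i, ] <- p; ok[i] <- TRUE }
  }
  list(points = pts, valid = ok)
}

#' Reconstruction RMSE of a calibrated rig
#'
#' Triangulates every reconstructable calibration point (visible in >= 2
#' cameras) and reports the root-mean-squared 3D error against the known
#' positions, in the calibration set's declared units.
#'
#' @param calib a [CalibrationSet-class].
#' @param models list of calibrated [CameraModel-class] objects matching
#'   `calib@observations` order.
#' @return scalar RMSE.
#' @export
reconstructionRmse <- function(calib, models) {
  obs <- calib@observations
  tri <- triangulatePoints(models, obs)
  if (!any(tri$valid)) stop("no reconstructable points")
  err <- tri$points[tri$valid, , drop = FALSE] -
    calib@points3d[tri$valid, , drop = FALSE]
  sqrt(mean(rowSums(err^2)))
}

#' Read / write calibration sets as CSV
#'
#' Layout: `point, x, y, z`, then per camera `<cam>_u, <cam>_v, <cam>_visible`.
#'
#' @param calib a [CalibrationSet-class].
#' @param path file path.
#' @param units declared length unit ("mm" or "um") when reading.
#' @return `readCalibrationCsv` returns a [CalibrationSet-class];
#'   `writeCalibrationCsv` returns `path` invisibly.
#' @export
writeCalibrationCsv <- function(calib, path) {
  df <- data.frame(point = seq_len(nrow(calib@points3d)),
                   x = calib@points3d[, 1], y = calib@points3d[, 2],
                   z = calib@points3d[, 3])
  for (cam in names(calib@observations)) {
    ob <- calib@observations[[cam]]
    df[[paste0(cam, "_u")]] <- ob$uv[, 1]
    df[[paste0(cam, "_v")]] <- ob$uv[, 2]
    df[[paste0(cam, "_visible")]] <- ob$visible
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibrationCsv
#' @export
readCalibrationCsv <- function(path, units = "mm") {
  df <- utils::read.csv(path)
  cams <- unique(sub("_u$", "", grep("_u$", names(df), value = TRUE)))
  obs <- lapply(cams, function(cam) {
    list(uv = cbind(df[[paste0(cam, "_u")]], df[[paste0(cam, "_v")]]),
         visible = as.logical(df[[paste0(cam, "_visible")]]))
  })
  names(obs) <- cams
  methods::new("CalibrationSet",
               points3d = as.matrix(df[, c("x", "y", "z")]),
               observations = obs, units = units)
}
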