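## Synthetic multi-camera rigs: pinhole cameras in general position around
## the arena, a 3D calibration grid with configurable visibility (emulating
## a microbead moved through a box of positions, not all visible in two or
## more views), and noisy 2D projections of arbitrary 3D tracks.

#' Generate a synthetic camera rig and calibration grid
#'
#' Places `nCameras` pinhole cameras on a ring around the working volume,
#' looking at its centre, and builds a cubic calibration grid
#' (`gridN`^3 positions). Each grid point is visible in each camera with
#' probability `visibility`; projections carry isotropic Gaussian pixel
#' noise of `pixelNoiseSd`.
#'
#' @param nCameras number of cameras (default 3).
#' @param center 3D centre of the working volume.
#' @param extent half-extent of the calibration box (same units as
#'   `center`).
#' @param distance camera distance from the centre (default `8 * extent`).
#' @param focalPx focal length in pixels (default 2000).
#' @param imageCenter principal point (default c(640, 512)).
#' @param gridN grid points per axis (default 5; 125 positions).
#' @param visibility per-point per-camera visibility probability
#'   (default 1).
#' @param pixelNoiseSd pixel noise standard deviation (default 0).
#' @param units declared length unit of the rig ("mm" or "um").
#' @param seed integer seed.
#' @return list with `models` (true [CameraModel-class] objects), `calib`
#'   (a [CalibrationSet-class]), `grid` (the true 3D positions).
#' @export
generateCameraRig <- function(nCameras = 3, center = c(0, 0, 0), extent = 5,
                              distance = 8 * extent, focalPx = 2000,
                              imageCenter = c(640, 512), gridN = 5,
                              visibility = 1, pixelNoiseSd = 0,
                              units = "mm", seed = 1) {
  set.seed(seed)
  ## cameras on a ring, alternating elevation, looking at the centre
  az <- seq(0, 2 * pi, length.out = nCameras + 1L)[-(nCameras + 1L)] + 0.3
  el <- rep(c(0.5, -0.35), length.out = nCameras)
  models <- vector("list", nCameras)
  for (k in seq_len(nCameras)) {
    pos <- center + distance * c(cos(el[k]) * cos(az[k]),
                                 cos(el[k]) * sin(az[k]), sin(el[k]))
    models[[k]] <- pinholeDlt(pos, center, focalPx, imageCenter,
                              id = paste0("cam", k))
  }
  ax <- seq(-extent, extent, length.out = gridN)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  grid <- sweep(grid, 2, -center)
  obs <- lapply(models, function(m) {
    uv <- dltProject(m, grid)
    if (pixelNoiseSd > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, pixelNoiseSd), ncol = 2L)
    list(uv = uv, visible = stats::runif(nrow(grid)) < visibility)
  })
  names(obs) <- vapply(models, function(m) m@id, "")
  calib <- methods::new("CalibrationSet", points3d = grid,
                        observations = obs, units = units)
  list(models = models, calib = calib, grid = grid)
}

## True DLT coefficients of a pinhole camera at `pos` looking at `target`.
pinholeDlt <- function(pos, target, focalPx, imageCenter, id = "cam",
                       worldUp = c(0, 0, 1)) {
  zc <- unitize(target - pos)
  if (abs(sum(zc * worldUp)) > 0.999) worldUp <- c(0, 1, 0)
  xc <- unitize(vcross(zc, worldUp))
  yc <- vcross(zc, xc)
  R <- rbind(xc, yc, zc)
  K <- rbind(c(focalPx, 0, imageCenter[1]),
             c(0, focalPx, imageCenter[2]),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% pos)
  P <- P / P[3, 4]
  methods::new("CameraModel", coef = c(P[1, ], P[2, ], P[3, 1:3]), id = id)
}

#' Project a 3D track through a camera rig
#'
#' @param models list of [CameraModel-class] objects.
#' @param xyz numeric matrix (n x 3).
#' @param pixelNoiseSd pixel noise sd (default 0).
#' @param visible optional logical matrix (n x cameras); defaults to all
#'   visible.
#' @param seed optional seed for the noise draw.
#' @return list (one per camera) of lists with `uv` and `visible`, the
#'   observation format of [triangulatePoints()].
#' @export
projectTrack <- function(models, xyz, pixelNoiseSd = 0, visible = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(visible)) visible <- matrix(TRUE, nrow(xyz), length(models))
  out <- lapply(seq_along(models), function(k) {
    uv <- dltProject(models[[k]], xyz)
    if (pixelNoiseSd > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, pixelNoiseSd), ncol = 2L)
    list(uv = uv, visible = visible[, k])
  })
  names(out) <- vapply(models, function(m) m@id, "")
  out
}
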