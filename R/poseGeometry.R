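## Geometric primitives turning triangulated body parts into the kinematic
## observables used for action classification. All angles are in degrees.

#' Body axis direction of a fly
#'
#' Direction of the first principal axis of the head, thorax and abdomen
#' points (total least squares line), oriented from the abdomen towards the
#' head, unit length.
#'
#' @param head,thorax,abdomen length-3 numeric vectors.
#' @return unit length-3 vector, or `NA`s when the points are coincident.
#' @export
bodyVector <- function(head, thorax, abdomen) {
  P <- rbind(head, thorax, abdomen)
  if (any(!is.finite(P))) return(rep(NA_real_, 3L))
  ctr <- sweep(P, 2, colMeans(P))
  if (max(abs(ctr)) < 1e-12) return(rep(NA_real_, 3L))
  v <- svd(ctr, nu = 0, nv = 3)$v[, 1]
  if (sum((head - abdomen) * v) < 0) v <- -v
  unitize(v)
}

#' Wing pitch angle
#'
#' Unsigned angle in [0, 180] degrees between the negative body vector and
#' the thorax-to-wingtip vector. On the head-fixed rig the role of the
#' negative body vector is played by the thorax-to-first-abdominal-stripe
#' vector; pass that direction (abdomen-ward) as `-bodyVec` equivalently via
#' [computeObservables()].
#'
#' @param bodyVec unit body vector (abdomen to head).
#' @param thorax,wingtip length-3 numeric vectors.
#' @return degrees in [0, 180], `NA` when the wing vector has zero length or
#'   any input is invalid.
#' @export
wingPitch <- function(bodyVec, thorax, wingtip) {
  u <- wingtip - thorax
  if (any(!is.finite(u)) || any(!is.finite(bodyVec))) return(NA_real_)
  if (sqrt(sum(u^2)) < 1e-12) return(NA_real_)
  angleBetweenDeg(-bodyVec, u)
}

#' Wing offset angle
#'
#' Absolute angular deviation of the (left pitch, right pitch) point from
#' the line of unity (left = right): `|45 - atan2(right, left)|` in degrees,
#' range [0, 45] for nonnegative pitches. Measures how much one wing is
#' extended more than the other. Defined as 0 when both pitches are 0.
#'
#' @param leftPitch,rightPitch pitch angles in degrees (vectorised).
#' @return degrees in [0, 45], `NA` propagated.
#' @export
wingOffsetAngle <- function(leftPitch, rightPitch) {
  out <- abs(45 - rad2deg(atan2(rightPitch, leftPitch)))
  out[!is.na(leftPitch) & !is.na(rightPitch) &
        leftPitch == 0 & rightPitch == 0] <- 0
  out
}

#' Unit normal of an arena wall
#'
#' Third right-singular vector of the zero-centred wall point set.
#'
#' @param wall numeric matrix (>= 3 x 3) of coplanar wall points.
#' @return unit length-3 vector.
#' @export
wallNormal <- function(wall) {
  ctr <- sweep(wall, 2, colMeans(wall))
  unitize(svd(ctr, nu = 0, nv = 3)$v[, 3])
}

#' Rectangular-box arena
#'
#' Convenience constructor for a closed rectangular arena: floor, ceiling
#' and the four side walls (in that tie-breaking order).
#'
#' @param xlim,ylim,zlim length-2 numeric ranges of the box (same length
#'   units as the tracks).
#' @return an [ArenaGeometry-class].
#' @examples
#' arenaBox(c(0, 20), c(0, 10), c(0, 10))  # the 20 x 10 x 10 mm chamber
#' @export
arenaBox <- function(xlim = c(0, 20), ylim = c(0, 10), zlim = c(0, 10)) {
  quad <- function(p1, p2, p3, p4) rbind(p1, p2, p3, p4)
  x0 <- xlim[1]; x1 <- xlim[2]; y0 <- ylim[1]; y1 <- ylim[2]
  z0 <- zlim[1]; z1 <- zlim[2]
  walls <- list(
    floor   = quad(c(x0, y0, z0), c(x1, y0, z0), c(x1, y1, z0), c(x0, y1, z0)),
    ceiling = quad(c(x0, y0, z1), c(x1, y0, z1), c(x1, y1, z1), c(x0, y1, z1)),
    wall_y0 = quad(c(x0, y0, z0), c(x1, y0, z0), c(x1, y0, z1), c(x0, y0, z1)),
    wall_y1 = quad(c(x0, y1, z0), c(x1, y1, z0), c(x1, y1, z1), c(x0, y1, z1)),
    wall_x0 = quad(c(x0, y0, z0), c(x0, y1, z0), c(x0, y1, z1), c(x0, y0, z1)),
    wall_x1 = quad(c(x1, y0, z0), c(x1, y1, z0), c(x1, y1, z1), c(x1, y0, z1)))
  methods::new("ArenaGeometry", walls = walls)
}

#' Body elevation angle relative to the nearest arena surface
#'
#' The nearest wall is chosen by the mean perpendicular distance from the
#' two body-axis endpoints (perpendicular projections of the head and
#' abdomen onto the body axis) to each wall plane; ties are broken by wall
#' order. The elevation is the unsigned angle in [0, 90] degrees between
#' the body vector and that wall's plane.
#'
#' @param head,abdomen length-3 numeric vectors.
#' @param bodyVec unit body vector (see [bodyVector()]).
#' @param arena an [ArenaGeometry-class].
#' @param thorax optional; when given, the body axis is anchored at the
#'   centroid of the three body points (the total-least-squares line),
#'   otherwise at the head/abdomen midpoint.
#' @return degrees in [0, 90]; `NA` propagated.
#' @export
elevationAngle <- function(head, abdomen, bodyVec, arena, thorax = NULL) {
  elevationAngleImpl(head, abdomen, bodyVec, arenaPlanes(arena), thorax)
}

## wall normals and anchor points, computed once per arena
arenaPlanes <- function(arena) {
  list(normals = lapply(arena@walls, wallNormal),
       origins = lapply(arena@walls, colMeans))
}

elevationAngleImpl <- function(head, abdomen, bodyVec, planes, thorax = NULL) {
  if (any(!is.finite(c(head, abdomen, bodyVec)))) return(NA_real_)
  anchor <- if (is.null(thorax)) (head + abdomen) / 2 else
    colMeans(rbind(head, thorax, abdomen))
  proj <- function(p) anchor + sum((p - anchor) * bodyVec) * bodyVec
  ends <- rbind(proj(head), proj(abdomen))
  dists <- vapply(seq_along(planes$normals), function(k) {
    n <- planes$normals[[k]]
    p0 <- planes$origins[[k]]
    mean(abs((ends - matrix(p0, 2L, 3L, byrow = TRUE)) %*% n))
  }, 0)
  n <- planes$normals[[which.min(dists)]]
  rad2deg(asin(min(1, abs(sum(bodyVec * n)))))
}

#' Wing elevation and azimuth angles from plane projections
#'
#' The frontal plane is spanned by the head, thorax and abdomen points,
#' with unit normal oriented towards the fly's left by the cross-product
#' order (head - thorax) x (abdomen - thorax). The medial plane is
#' perpendicular to the frontal plane and contains the body axis; its
#' normal faces upward in the canonical upright pose. Wing and abdomen
#' points are translated by the thorax and projected into each plane; each
#' wing's elevation (azimuth) is the planar angle between its frontal
#' (medial) projection and the projected abdomen direction.
#'
#' @param head,thorax,abdomen,leftTip,rightTip length-3 numeric vectors.
#' @return named numeric vector with `left_wing_elevation`,
#'   `right_wing_elevation`, `left_wing_azimuth`, `right_wing_azimuth` in
#'   degrees; all `NA` when the body points are collinear or inputs invalid.
#' @export
wingPlaneAngles <- function(head, thorax, abdomen, leftTip, rightTip) {
  out <- c(left_wing_elevation = NA_real_, right_wing_elevation = NA_real_,
           left_wing_azimuth = NA_real_, right_wing_azimuth = NA_real_)
  if (any(!is.finite(c(head, thorax, abdomen, leftTip, rightTip)))) return(out)
  nf_raw <- vcross(head - thorax, abdomen - thorax)
  if (sqrt(sum(nf_raw^2)) < 1e-12) return(out)  # collinear body points
  nf <- unitize(nf_raw)
  bv <- bodyVector(head, thorax, abdomen)
  nm <- unitize(vcross(bv, nf))

  planeAngle <- function(nrm, p, q) {
    pp <- p - sum(p * nrm) * nrm
    qq <- q - sum(q * nrm) * nrm
    if (sqrt(sum(pp^2)) < 1e-12 || sqrt(sum(qq^2)) < 1e-12) return(NA_real_)
    angleBetweenDeg(pp, qq)
  }
  a <- abdomen - thorax
  l <- leftTip - thorax
  r <- rightTip - thorax
  out["left_wing_elevation"] <- planeAngle(nf, l, a)
  out["right_wing_elevation"] <- planeAngle(nf, r, a)
  out["left_wing_azimuth"] <- planeAngle(nm, l, a)
  out["right_wing_azimuth"] <- planeAngle(nm, r, a)
  out
}

#' Per-frame speed of the thorax
#'
#' Euclidean displacement between consecutive frames times the frame rate.
#' Frame `i` holds the displacement from frame `i - 1`; the first frame and
#' frames adjacent to an invalid frame are `NA`.
#'
#' @param thorax numeric matrix (frames x 3), `NA` rows where invalid.
#' @param frameRate Hz.
#' @return numeric vector (same length units per second as the input).
#' @export
flySpeed <- function(thorax, frameRate) {
  n <- nrow(thorax)
  sp <- rep(NA_real_, n)
  if (n >= 2L) {
    d <- sqrt(rowSums((thorax[-1L, , drop = FALSE] -
                         thorax[-n, , drop = FALSE])^2))
    sp[-1L] <- d * frameRate
  }
  sp
}

#' Wingspan series
#'
#' Euclidean distance between the two wingtips per frame.
#'
#' @param leftTip,rightTip numeric matrices (frames x 3).
#' @return numeric vector in the track's length units.
#' @export
wingspanSeries <- function(leftTip, rightTip) {
  sqrt(rowSums((leftTip - rightTip)^2))
}

#' Per-bout baseline subtraction
#'
#' For each stimulation bout, the baseline is the mean of the valid samples
#' in the `preWindowS` seconds before light onset; it is subtracted from the
#' trace over that bout's segment (from `preWindowS` before its onset up to
#' the same point relative to the next onset).
#'
#' @param series numeric vector (e.g. wingspan), `NA` where invalid.
#' @param frameRate Hz.
#' @param stimOnsetsS light-onset times in seconds, ascending.
#' @param preWindowS baseline window length in seconds (default 10).
#' @return baseline-subtracted copy of `series`.
#' @export
baselineSubtract <- function(series, frameRate, stimOnsetsS, preWindowS = 10) {
  stopifnot(length(stimOnsetsS) >= 1L, !is.unsorted(stimOnsetsS))
  n <- length(series)
  t <- (seq_len(n) - 1L) / frameRate
  out <- series
  seg_start <- stimOnsetsS - preWindowS
  seg_end <- c(seg_start[-1L], Inf)
  seg_start[1L] <- -Inf
  for (k in seq_along(stimOnsetsS)) {
    base_idx <- which(t >= stimOnsetsS[k] - preWindowS & t < stimOnsetsS[k] &
                        !is.na(series))
    if (length(base_idx) == 0L) stop("no baseline")
    base <- mean(series[base_idx])
    idx <- which(t >= seg_start[k] & t < seg_end[k])
    out[idx] <- series[idx] - base
  }
  out
}
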