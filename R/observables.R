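## Track-level processing: confidence gating, gap interpolation, and the
## assembly of per-frame observables with exact invalidity propagation.

#' Linearly interpolate short invalid gaps in a keypoint track
#'
#' Interior runs of invalid frames strictly shorter than `maxGapMs` are
#' filled by per-coordinate linear interpolation between the flanking valid
#' frames and marked valid. Longer runs and leading/trailing runs are left
#' untouched (no extrapolation).
#'
#' @param track a [Keypoint3DTrack-class].
#' @param maxGapMs gap-duration threshold in milliseconds (default 500).
#' @return a [Keypoint3DTrack-class] with gaps filled.
#' @export
interpolateGaps <- function(track, maxGapMs = 500) {
  coords <- track@coords
  valid <- track@valid
  max_frames <- maxGapMs / 1000 * track@frameRate  # run is filled iff len < this
  for (p in partNames(track)) {
    runs <- trueRuns(!valid[, p])
    if (nrow(runs) == 0L) next
    for (k in seq_len(nrow(runs))) {
      s <- runs$start[k]; e <- runs$end[k]
      len <- e - s + 1L
      if (s == 1L || e == nFrames(track)) next        # no extrapolation
      if (len >= max_frames) next                     # strictly < maxGapMs
      for (ax in 1:3) {
        coords[s:e, ax, p] <- seq(coords[s - 1L, ax, p], coords[e + 1L, ax, p],
                                  length.out = len + 2L)[2:(len + 1L)]
      }
      valid[s:e, p] <- TRUE
    }
  }
  methods::new("Keypoint3DTrack", frameRate = track@frameRate,
               coords = coords, valid = valid)
}

#' Compute kinematic observables from a keypoint track
#'
#' Derives speed, left/right wing pitch, wing offset angle, wingspan, and —
#' when the required parts/arena are available — body elevation and the
#' frontal/medial-plane wing elevation and azimuth angles. A signal is `NA`
#' at exactly the frames where any body part it depends on is invalid.
#'
#' Two body-axis conventions are supported: `"leastSquares"` (free-walking
#' rig: total-least-squares head/thorax/abdomen axis) and `"thoraxStripe1"`
#' (head-fixed rig: the thorax-to-first-abdominal-stripe vector plays the
#' role of the negative body vector for wing pitch).
#'
#' @param track a [Keypoint3DTrack-class] with parts named `head`, `thorax`,
#'   `abdomen_tip`, `left_wingtip`, `right_wingtip` (head-fixed tracks add
#'   `abdomen_stripe_1` ... `abdomen_stripe_4`).
#' @param arena optional [ArenaGeometry-class]; elevation is computed only
#'   when given.
#' @param bodyAxis `"leastSquares"` or `"thoraxStripe1"`.
#' @return an [ObservableSeries-class].
#' @export
computeObservables <- function(track, arena = NULL,
                               bodyAxis = c("leastSquares", "thoraxStripe1")) {
  bodyAxis <- match.arg(bodyAxis)
  parts <- partNames(track)
  n <- nFrames(track)
  get <- function(p) if (p %in% parts) partCoords(track, p) else NULL

  head <- get("head"); thorax <- get("thorax"); abdomen <- get("abdomen_tip")
  ltip <- get("left_wingtip"); rtip <- get("right_wingtip")
  stripe1 <- get("abdomen_stripe_1")

  sig <- list()
  if (!is.null(thorax)) sig$speed <- flySpeed(thorax, track@frameRate)

  axis_ok <- if (bodyAxis == "leastSquares")
    !is.null(head) && !is.null(thorax) && !is.null(abdomen)
  else !is.null(thorax) && !is.null(stripe1)
  body_ok <- !is.null(head) && !is.null(thorax) && !is.null(abdomen)
  do_pitch <- axis_ok && (!is.null(ltip) || !is.null(rtip))
  do_elev <- !is.null(arena) && body_ok
  do_planes <- body_ok && !is.null(ltip) && !is.null(rtip)
  planes <- if (do_elev) arenaPlanes(arena)

  if (do_pitch || do_elev || do_planes) {
    lp <- rp <- el <- rep(NA_real_, n)
    wa <- matrix(NA_real_, n, 4L,
                 dimnames = list(NULL, c("left_wing_elevation",
                                         "right_wing_elevation",
                                         "left_wing_azimuth",
                                         "right_wing_azimuth")))
    for (i in seq_len(n)) {
      bv_ls <- if (body_ok) bodyVector(head[i, ], thorax[i, ], abdomen[i, ])
      else rep(NA_real_, 3L)
      bv <- if (bodyAxis == "leastSquares") bv_ls else {
        d <- stripe1[i, ] - thorax[i, ]
        if (any(!is.finite(d)) || sqrt(sum(d^2)) < 1e-12) rep(NA_real_, 3L)
        else -unitize(d)  # stripe vector is abdomen-ward, i.e. -body vector
      }
      if (do_pitch && all(is.finite(bv))) {
        if (!is.null(ltip)) lp[i] <- wingPitch(bv, thorax[i, ], ltip[i, ])
        if (!is.null(rtip)) rp[i] <- wingPitch(bv, thorax[i, ], rtip[i, ])
      }
      if (do_elev && all(is.finite(bv_ls)))
        el[i] <- elevationAngleImpl(head[i, ], abdomen[i, ], bv_ls, planes,
                                    thorax = thorax[i, ])
      if (do_planes)
        wa[i, ] <- wingPlaneAngles(head[i, ], thorax[i, ], abdomen[i, ],
                                   ltip[i, ], rtip[i, ])
    }
    if (do_pitch && !is.null(ltip)) sig$left_pitch <- lp
    if (do_pitch && !is.null(rtip)) sig$right_pitch <- rp
    if (do_pitch && !is.null(ltip) && !is.null(rtip))
      sig$offset_angle <- wingOffsetAngle(lp, rp)
    if (do_elev) sig$elevation <- el
    if (do_planes) for (cn in colnames(wa)) sig[[cn]] <- wa[, cn]
  }

  if (!is.null(ltip) && !is.null(rtip))
    sig$wingspan <- wingspanSeries(ltip, rtip)

  observableSeries(do.call(cbind, sig), track@frameRate)
}

#' Read a pose-estimation CSV (DeepLabCut dialect)
#'
#' Parses the 3-row-header CSV layout (scorer / bodyparts / coords) with
#' `x`, `y`, `likelihood` columns per body part for one camera view.
#'
#' @param path CSV file path.
#' @return named list, one entry per body part, each a list with `xy`
#'   (n x 2 matrix) and `likelihood` (numeric n).
#' @export
readDlcCsv <- function(path) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3L,
                         colClasses = "character")
  dat <- utils::read.csv(path, header = FALSE, skip = 3L)
  parts <- as.character(unlist(hdr[2L, -1L]))
  coords <- as.character(unlist(hdr[3L, -1L]))
  out <- list()
  for (p in unique(parts)) {
    cols <- which(parts == p) + 1L
    names(cols) <- coords[parts == p]
    out[[p]] <- list(
      xy = cbind(dat[[cols[["x"]]]], dat[[cols[["y"]]]]),
      likelihood = dat[[cols[["likelihood"]]]])
  }
  out
}

#' Triangulate a multi-view pose-estimation session into a 3D track
#'
#' Gates each 2D detection at the confidence threshold (detections below it
#' are treated as unseen), then reconstructs each part per frame from the
#' >= 2 remaining views.
#'
#' @param models list of [CameraModel-class] objects.
#' @param views list (one per camera, same order) of [readDlcCsv()] outputs.
#' @param frameRate Hz.
#' @param confidenceMin detections with likelihood below this are dropped
#'   (default 0.7).
#' @return a [Keypoint3DTrack-class].
#' @export
triangulateSession <- function(models, views, frameRate, confidenceMin = 0.7) {
  parts <- names(views[[1L]])
  n <- nrow(views[[1L]][[1L]]$xy)
  coords <- array(NA_real_, c(n, 3L, length(parts)),
                  dimnames = list(NULL, c("x", "y", "z"), parts))
  valid <- matrix(FALSE, n, length(parts), dimnames = list(NULL, parts))
  for (p in parts) {
    obs <- lapply(views, function(v) {
      list(uv = v[[p]]$xy, visible = v[[p]]$likelihood >= confidenceMin)
    })
    tri <- triangulatePoints(models, obs)
    coords[, , p] <- tri$points
    valid[, p] <- tri$valid
  }
  keypointTrack(coords, valid, frameRate)
}

#' Write observables as tidy CSV
#'
#' Long layout: `frame, time_s, signal, value, valid`.
#'
#' @param obs an [ObservableSeries-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeObservablesCsv <- function(obs, path) {
  s <- obs@signals
  df <- data.frame(
    frame = rep(seq_len(nrow(s)), ncol(s)),
    time_s = rep((seq_len(nrow(s)) - 1L) / obs@frameRate, ncol(s)),
    signal = rep(colnames(s), each = nrow(s)),
    value = as.vector(s),
    valid = !is.na(as.vector(s)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read observables from tidy CSV
#'
#' @param path CSV written by [writeObservablesCsv()].
#' @param frameRate Hz.
#' @return an [ObservableSeries-class].
#' @export
readObservablesCsv <- function(path, frameRate) {
  df <- utils::read.csv(path)
  sigs <- unique(df$signal)
  n <- max(df$frame)
  m <- matrix(NA_real_, n, length(sigs), dimnames = list(NULL, sigs))
  for (s in sigs) {
    sub <- df[df$signal == s, ]
    m[sub$frame, s] <- sub$value
  }
  observableSeries(m, frameRate)
}
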