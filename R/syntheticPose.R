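## Synthetic pose sessions with scripted action bouts. The generator
## emulates the free-walking assay's structure (15 trials per fly, 30.5 s
## trials, light on from 0.5 to 15.5 s, 100 Hz) with minimal
## piecewise-smooth kinematic templates: enough to exercise the observable
## geometry and the threshold logic of the classifier, not a biomechanical
## simulation. Templates are built to respect the classifier's thresholds
## by construction, so the intended label is the ground truth away from
## bout-transition frames.

#' Script for a synthetic pose session
#'
#' @param nTrials trials per fly (default 15).
#' @param trialS trial length in seconds (default 30.5).
#' @param stimOnS,stimOffS light window in seconds (defaults 0.5 and 15.5).
#' @param frameRate Hz (default 100).
#' @param bouts data.frame with `trial`, `action` (one of `wing_threat`,
#'   `wing_extension`, `alert`, `thrust`), `start_s`, `duration_s`, `side`
#'   (`"left"`/`"right"`, used by wing extension). Bouts must lie within
#'   the trial; wing threat and wing extension may not overlap.
#' @param noiseSdDeg Gaussian angular noise added to wing pitch and body
#'   pitch, degrees (default 0).
#' @param dropoutRate per-frame probability that one randomly chosen body
#'   part fails tracking (default 0).
#' @param threatPitchRange,extensionPitchRange ranges the per-bout wing
#'   pitch plateau is drawn from, degrees (defaults 50-70 and 40-70).
#' @param alertElevationRange body-pitch plateau range of the alert stance,
#'   degrees (default 25-40).
#' @param baselinePitchDeg resting wing pitch (default 10).
#' @param walkSpeed baseline walking speed in mm/s (default 3).
#' @param alertSpeed speed during alert bouts in mm/s (default 0.2).
#' @param seed integer seed; all generation is deterministic under it.
#' @return a validated script (list, class `poseScript`).
#' @export
poseScript <- function(nTrials = 15, trialS = 30.5, stimOnS = 0.5,
                       stimOffS = 15.5, frameRate = 100,
                       bouts = data.frame(), noiseSdDeg = 0, dropoutRate = 0,
                       threatPitchRange = c(50, 70),
                       extensionPitchRange = c(40, 70),
                       alertElevationRange = c(25, 40),
                       baselinePitchDeg = 10, walkSpeed = 3, alertSpeed = 0.2,
                       seed = 1) {
  script <- list(nTrials = nTrials, trialS = trialS, stimOnS = stimOnS,
                 stimOffS = stimOffS, frameRate = frameRate, bouts = bouts,
                 noiseSdDeg = noiseSdDeg, dropoutRate = dropoutRate,
                 threatPitchRange = threatPitchRange,
                 extensionPitchRange = extensionPitchRange,
                 alertElevationRange = alertElevationRange,
                 baselinePitchDeg = baselinePitchDeg, walkSpeed = walkSpeed,
                 alertSpeed = alertSpeed, seed = seed)
  class(script) <- "poseScript"
  validatePoseScript(script)
  script
}

validatePoseScript <- function(script) {
  b <- script$bouts
  if (nrow(b) == 0L) return(invisible(TRUE))
  stopifnot(all(c("trial", "action", "start_s", "duration_s") %in% names(b)))
  ok_actions <- c("wing_threat", "wing_extension", "alert", "thrust")
  if (!all(b$action %in% ok_actions))
    stop("unknown scripted action: ", setdiff(b$action, ok_actions)[1])
  if (any(b$start_s < 0 | b$start_s + b$duration_s > script$trialS))
    stop("bout outside trial bounds")
  ## wing threat and wing extension are incompatible poses
  wing <- b[b$action %in% c("wing_threat", "wing_extension"), , drop = FALSE]
  for (tr in unique(wing$trial)) {
    w <- wing[wing$trial == tr, , drop = FALSE]
    if (nrow(w) < 2L) next
    o <- order(w$start_s)
    s <- w$start_s[o]; e <- s + w$duration_s[o]
    if (any(s[-1L] < e[-length(e)] - 1e-9))
      stop("overlapping incompatible bouts (wing threat/extension)")
  }
  invisible(TRUE)
}

#' Default bout schedule for a synthetic session
#'
#' One wing-threat, one wing-extension and one alert bout per trial at
#' fixed times inside the stimulus window.
#'
#' @param nTrials number of trials.
#' @return bout data.frame for [poseScript()].
#' @export
defaultBoutSchedule <- function(nTrials = 15) {
  do.call(rbind, lapply(seq_len(nTrials), function(tr) {
    data.frame(trial = tr,
               action = c("wing_threat", "wing_extension", "alert"),
               start_s = c(1.5, 6.0, 10.0),
               duration_s = c(2.0, 1.5, 3.0),
               side = c(NA, if (tr %% 2) "left" else "right", NA))
  }))
}

#' Generate a synthetic pose session with ground truth
#'
#' Realises each trial of the script: the fly walks a circular path on the
#' arena floor; scripted bouts override the wing pitches (threat: both
#' wings up; extension: one wing up), the body pitch (alert/thrust) and
#' the speed (alert slows the fly; thrust adds a speed transient with a
#' rise-then-drop body-pitch excursion). Gaussian angular noise and random
#' tracking dropouts are applied last. Deterministic under the script seed.
#'
#' @param script a [poseScript()].
#' @param arena the [ArenaGeometry-class] the session is staged in
#'   (default [arenaBox()], the 20 x 10 x 10 mm chamber).
#' @return list with `tracks` (per-trial [Keypoint3DTrack-class]),
#'   `truth` (per-trial ground-truth [Ethogram-class]), `script`, `arena`.
#' @export
generatePoseSession <- function(script, arena = arenaBox()) {
  validatePoseScript(script)
  set.seed(script$seed)
  tracks <- vector("list", script$nTrials)
  truth <- vector("list", script$nTrials)
  for (tr in seq_len(script$nTrials)) {
    g <- generatePoseTrial(script, tr)
    tracks[[tr]] <- g$track
    truth[[tr]] <- g$truth
  }
  list(tracks = tracks, truth = truth, script = script, arena = arena)
}

generatePoseTrial <- function(script, trial) {
  fps <- script$frameRate
  n <- round(script$trialS * fps)
  t <- (seq_len(n) - 1L) / fps
  b <- script$bouts
  b <- b[b$trial == trial, , drop = FALSE]

  frameWindow <- function(start_s, dur_s) {
    lo <- floor(start_s * fps + 1e-9) + 1L
    hi <- min(n, floor((start_s + dur_s) * fps - 1e-9) + 1L)
    if (hi < lo) integer(0) else lo:hi
  }

  ## per-frame kinematic programs
  speed <- rep(script$walkSpeed, n)
  lpitch <- rep(script$baselinePitchDeg, n)
  rpitch <- rep(script$baselinePitchDeg, n)
  bpitch <- rep(0, n)   # body pitch above the floor plane, degrees
  labels <- matrix(FALSE, n, 4L, dimnames = list(NULL, actionNames()))

  if (nrow(b)) for (k in seq_len(nrow(b))) {
    idx <- frameWindow(b$start_s[k], b$duration_s[k])
    if (length(idx) == 0L) next
    switch(b$action[k],
      wing_threat = {
        v <- stats::runif(1, script$threatPitchRange[1], script$threatPitchRange[2])
        lpitch[idx] <- v; rpitch[idx] <- v
        labels[idx, "wing_threat"] <- TRUE
      },
      wing_extension = {
        v <- stats::runif(1, script$extensionPitchRange[1],
                          script$extensionPitchRange[2])
        if (identical(b$side[k], "right")) rpitch[idx] <- v else lpitch[idx] <- v
        labels[idx, "wing_extension"] <- TRUE
      },
      alert = {
        v <- stats::runif(1, script$alertElevationRange[1],
                          script$alertElevationRange[2])
        bpitch[idx] <- v
        speed[idx] <- script$alertSpeed
        labels[idx, "alert"] <- TRUE
      },
      thrust = {
        ## rise-then-drop elevation excursion with a speed transient;
        ## stays below the alert elevation threshold
        m <- length(idx)
        env <- sin(pi * seq_len(m) / (m + 1L))
        bpitch[idx] <- pmax(bpitch[idx], 20 * env)
        speed[idx] <- script$walkSpeed + 12 * env
      })
  }

  if (script$noiseSdDeg > 0) {
    lpitch <- lpitch + stats::rnorm(n, 0, script$noiseSdDeg)
    rpitch <- rpitch + stats::rnorm(n, 0, script$noiseSdDeg)
    bpitch <- bpitch + stats::rnorm(n, 0, script$noiseSdDeg)
  }

  ## circular walking path of the abdomen base on the floor
  r <- 3; ctr <- c(10, 5)
  alpha <- cumsum(c(stats::runif(1, 0, 2 * pi), speed[-1L] / fps / r))
  abd <- cbind(ctr[1] + r * cos(alpha), ctr[2] + r * sin(alpha), 0.3)
  fwd <- cbind(-sin(alpha), cos(alpha), 0)
  left <- cbind(-cos(alpha), -sin(alpha), 0)
  up <- c(0, 0, 1)

  parts <- c("head", "thorax", "abdomen_tip", "left_wingtip", "right_wingtip")
  coords <- array(NA_real_, c(n, 3L, length(parts)),
                  dimnames = list(NULL, c("x", "y", "z"), parts))
  phi <- deg2rad(bpitch)
  bv <- fwd * cos(phi) + matrix(up, n, 3L, byrow = TRUE) * sin(phi)
  upb <- t(vapply(seq_len(n), function(i) vcross(bv[i, ], left[i, ]),
                  numeric(3L)))
  coords[, , "abdomen_tip"] <- abd
  coords[, , "thorax"] <- abd + 1.2 * bv + 0.15 * upb
  coords[, , "head"] <- abd + 2.0 * bv
  thetaL <- deg2rad(lpitch); thetaR <- deg2rad(rpitch)
  coords[, , "left_wingtip"] <- coords[, , "thorax"] +
    2.0 * (-cos(thetaL) * bv + sin(thetaL) * left)
  coords[, , "right_wingtip"] <- coords[, , "thorax"] +
    2.0 * (-cos(thetaR) * bv + sin(thetaR) * (-left))

  valid <- matrix(TRUE, n, length(parts), dimnames = list(NULL, parts))
  if (script$dropoutRate > 0) {
    drop_frame <- stats::runif(n) < script$dropoutRate
    drop_part <- sample.int(length(parts), n, replace = TRUE)
    for (i in which(drop_frame)) {
      valid[i, drop_part[i]] <- FALSE
      coords[i, , drop_part[i]] <- NA_real_
    }
    labels[drop_frame, ] <- NA
  }

  list(track = keypointTrack(coords, valid, fps),
       truth = ethogram(labels, fps))
}

#' Generate a scheduled two-component wing-pitch mixture series
#'
#' Samples each frame from a two-component Gaussian mixture whose means
#' and mixing proportion follow a piecewise-linear schedule; emulates the
#' declining high-pitch occupancy seen over a stimulus bout. `mixing` is
#' the proportion of the high-pitch component (`mean2`).
#'
#' @param schedule data.frame with `time_s`, `mean1`, `mean2`, `mixing`;
#'   values are interpolated linearly between rows.
#' @param sd common component standard deviation, degrees (default 3).
#' @param frameRate Hz (default 100).
#' @param durationS series length in seconds; defaults to the schedule end.
#' @param seed integer seed.
#' @return numeric vector of wing pitches (degrees).
#' @export
generateWingpitchMixture <- function(schedule, sd = 3, frameRate = 100,
                                     durationS = NULL, seed = 1) {
  stopifnot(all(c("time_s", "mean1", "mean2", "mixing") %in% names(schedule)))
  set.seed(seed)
  if (is.null(durationS)) durationS <- max(schedule$time_s)
  n <- round(durationS * frameRate)
  t <- (seq_len(n) - 1L) / frameRate
  interp <- function(col) stats::approx(schedule$time_s, schedule[[col]],
                                        xout = t, rule = 2)$y
  m1 <- interp("mean1"); m2 <- interp("mean2"); mix <- interp("mixing")
  comp2 <- stats::runif(n) < mix
  stats::rnorm(n, ifelse(comp2, m2, m1), sd)
}

#' Write / read a pose script as JSON
#'
#' @param script a [poseScript()].
#' @param path file path.
#' @return the path (writing) or a script (reading).
#' @export
writePoseScript <- function(script, path) {
  jsonlite::write_json(unclass(script), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname writePoseScript
#' @export
readPoseScript <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$bouts <- if (length(raw$bouts)) as.data.frame(raw$bouts) else data.frame()
  do.call(poseScript, raw)
}
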