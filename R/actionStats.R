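## Rule-based action classification and temporal statistics. All rules use
## strict inequalities exactly as specified; boundary frames are unlabeled.

#' Classification thresholds
#'
#' The default threshold set for [classifyFrames()] and downstream
#' statistics. Angles are in degrees, speeds in mm/s, durations in their
#' stated units.
#'
#' @param wingThreatPitch wing pitch above which a symmetric display is a
#'   wing threat (45).
#' @param wingExtensionPitch wing pitch above which an asymmetric display is
#'   a wing extension, and the lower pitch bound of low wing threat (35).
#' @param offsetMax wing offset angle below which wings count as symmetric
#'   (10); offsets above it mark wing extension.
#' @param alertSpeedMax speed below which the fly is stationary (1 mm/s).
#' @param alertElevationMin body elevation above which a stationary fly is
#'   in the alert stance (22.5).
#' @return named list of thresholds.
#' @export
aggressionThresholds <- function(wingThreatPitch = 45,
                                 wingExtensionPitch = 35,
                                 offsetMax = 10,
                                 alertSpeedMax = 1,
                                 alertElevationMin = 22.5) {
  list(wingThreatPitch = wingThreatPitch,
       wingExtensionPitch = wingExtensionPitch,
       offsetMax = offsetMax,
       alertSpeedMax = alertSpeedMax,
       alertElevationMin = alertElevationMin)
}

#' Classify frames into aggression-related actions
#'
#' Per-frame rules over the observables (all inequalities strict):
#' \itemize{
#'   \item wing threat: either wing pitch > 45 deg and wing offset < 10 deg;
#'   \item wing extension: either wing pitch > 35 deg and offset > 10 deg;
#'   \item low wing threat: either wing pitch in (35, 45) deg, offset
#'     < 10 deg, and not a wing threat;
#'   \item alert stance: speed < 1 mm/s and elevation > 22.5 deg.
#' }
#' The three wing labels are mutually exclusive; alert is scored
#' independently and may co-occur with them. A label is `NA` wherever an
#' observable it depends on is invalid.
#'
#' @param obs an [ObservableSeries-class] with `left_pitch`, `right_pitch`
#'   and `offset_angle` (and `speed`/`elevation` for the alert stance).
#' @param thresholds see [aggressionThresholds()].
#' @return an [Ethogram-class].
#' @export
classifyFrames <- function(obs, thresholds = aggressionThresholds()) {
  n <- nFrames(obs)
  sig <- function(s) if (s %in% colnames(obs@signals)) obs@signals[, s] else
    rep(NA_real_, n)
  L <- sig("left_pitch"); R <- sig("right_pitch"); off <- sig("offset_angle")
  sp <- sig("speed"); el <- sig("elevation")
  th <- thresholds

  hi <- pmax(L, R)  # NA if either missing? pmax propagates NA only if both NA
  hi[is.na(L) | is.na(R)] <- NA_real_

  wing_threat <- hi > th$wingThreatPitch & off < th$offsetMax
  wing_ext <- hi > th$wingExtensionPitch & off > th$offsetMax
  low_wt <- ((L > th$wingExtensionPitch & L < th$wingThreatPitch) |
               (R > th$wingExtensionPitch & R < th$wingThreatPitch)) &
    off < th$offsetMax & !wing_threat
  alert <- sp < th$alertSpeedMax & el > th$alertElevationMin

  labels <- cbind(wing_threat = wing_threat, wing_extension = wing_ext,
                  low_wing_threat = low_wt, alert = alert)
  colnames(labels) <- actionNames()
  ethogram(labels, frameRate(obs))
}

#' Extract action bouts from a per-frame flag series
#'
#' Bouts are maximal runs of `TRUE`; `NA` (unknown) frames terminate runs.
#' Runs shorter than `minDurationMs` are dropped. Bout times are half-open
#' intervals `[start_s, end_s)` on the frame grid (frame `i` spans
#' `[(i-1)/rate, i/rate)`).
#'
#' @param flags logical vector with `NA` for unknown frames, or an
#'   [Ethogram-class] together with `action`.
#' @param frameRate Hz (ignored when `flags` is an ethogram).
#' @param minDurationMs minimum bout duration in milliseconds (default 0).
#' @param action action name when `flags` is an [Ethogram-class].
#' @return data.frame with `start_s`, `end_s`, `duration_s`.
#' @export
extractBouts <- function(flags, frameRate = NULL, minDurationMs = 0,
                         action = NULL) {
  if (methods::is(flags, "Ethogram")) {
    stopifnot(!is.null(action))
    frameRate <- frameRate(flags)
    flags <- actionFlags(flags)[, action]
  }
  stopifnot(!is.null(frameRate))
  runs <- trueRuns(flags)
  start_s <- (runs$start - 1L) / frameRate
  end_s <- runs$end / frameRate
  out <- data.frame(start_s = start_s, end_s = end_s,
                    duration_s = end_s - start_s)
  out[out$duration_s * 1000 >= minDurationMs | minDurationMs <= 0, ,
      drop = FALSE]
}

#' Latency to the first action bout after stimulus onset
#'
#' Time from light onset to the start of the first bout of the action that
#' begins after the onset and lasts more than `minBoutMs`. Bouts that
#' straddle the onset (begin before it) are skipped.
#'
#' @param etho an [Ethogram-class].
#' @param action action name (see [actionNames()]).
#' @param stimulusOnsetS onset time in seconds.
#' @param minBoutMs minimum qualifying bout duration (default 30 ms,
#'   strictly exceeded).
#' @return latency in seconds, or `NA` if no qualifying bout exists.
#' @export
firstBoutLatency <- function(etho, action, stimulusOnsetS, minBoutMs = 30) {
  bouts <- extractBouts(etho, action = action)
  ok <- bouts$start_s > stimulusOnsetS & bouts$duration_s * 1000 > minBoutMs
  if (!any(ok)) return(NA_real_)
  min(bouts$start_s[ok]) - stimulusOnsetS
}

#' Per-fly proportion-of-trials time course
#'
#' For one fly, the fraction of trials in which the action is being
#' performed at each time point — trials whose label is unknown at that
#' time point are excluded from both numerator and denominator — smoothed
#' by a centred 250 ms moving mean (window shrinks at the edges).
#'
#' @param ethograms list of [Ethogram-class] objects (the fly's trials, on a
#'   common time base).
#' @param action action name.
#' @param smoothMs moving-mean width in milliseconds (default 250).
#' @return numeric vector of smoothed proportions per frame.
#' @export
proportionTimecourse <- function(ethograms, action, smoothMs = 250) {
  stopifnot(length(ethograms) >= 1L)
  fr <- frameRate(ethograms[[1L]])
  flags <- vapply(ethograms, function(e) actionFlags(e)[, action],
                  numeric(nFrames(ethograms[[1L]])) * NA)
  prop <- rowMeans(flags, na.rm = TRUE)
  prop[rowSums(!is.na(flags)) == 0L] <- NA_real_
  k <- max(1L, round(smoothMs / 1000 * fr))
  movingMeanCentered(prop, k)
}

#' Binned two-group rank-sum tests over time
#'
#' Splits the time axis into non-overlapping bins, averages each fly's
#' proportion over the bin, and compares the two groups per bin with a
#' two-sided Wilcoxon rank-sum test at the stated significance cutoff. For
#' small samples the exact permutation distribution of the midrank statistic
#' is enumerated (valid under ties); otherwise the tie-corrected normal
#' approximation is used. No multiplicity correction is applied across bins.
#'
#' @param groupA,groupB numeric matrices (flies x frames) of per-fly
#'   proportion time courses.
#' @param frameRate Hz.
#' @param binS bin width in seconds (default 0.5).
#' @param alpha significance cutoff (default 0.01).
#' @return data.frame with `bin_start_s`, `bin_end_s`, `statistic` (rank sum
#'   of group A), `p`, `significant`; `p` is `NA` for all-missing bins.
#' @export
binnedGroupTest <- function(groupA, groupB, frameRate, binS = 0.5,
                            alpha = 0.01) {
  stopifnot(nrow(groupA) >= 2L, nrow(groupB) >= 2L,
            ncol(groupA) == ncol(groupB))
  n <- ncol(groupA)
  bin_frames <- round(binS * frameRate)
  starts <- seq(1L, n, by = bin_frames)
  res <- lapply(starts, function(s) {
    idx <- s:min(n, s + bin_frames - 1L)
    a <- rowMeans(groupA[, idx, drop = FALSE], na.rm = TRUE)
    b <- rowMeans(groupB[, idx, drop = FALSE], na.rm = TRUE)
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) {
      return(c(stat = NA_real_, p = NA_real_))
    }
    c(stat = sum(rank(c(a, b))[seq_along(a)]), p = ranksumP(a, b))
  })
  res <- do.call(rbind, res)
  data.frame(bin_start_s = (starts - 1L) / frameRate,
             bin_end_s = pmin(starts - 1L + bin_frames, n) / frameRate,
             statistic = res[, "stat"], p = res[, "p"],
             significant = !is.na(res[, "p"]) & res[, "p"] < alpha)
}

## Two-sided rank-sum p. Exact permutation enumeration of the midrank sum
## when feasible (correct under ties); tie-corrected normal approximation
## otherwise.
ranksumP <- function(a, b, max_comb = 1e5) {
  na <- length(a); nb <- length(b)
  if (choose(na + nb, na) <= max_comb) {
    r <- rank(c(a, b))
    obs <- sum(r[seq_len(na)])
    cmb <- utils::combn(na + nb, na)
    sums <- colSums(matrix(r[cmb], nrow = na))
    mu <- mean(sums)
    mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
}

#' Wingspan response metrics of one stimulation bout
#'
#' On a baseline-subtracted wingspan trace: the first local maximum
#' exceeding the sex-specific threshold (0.22 mm for males, 0.25 mm for
#' females — male wings are shorter) and its latency from light onset;
#' the baseline shift, mean over 20-30 s after light offset minus mean over
#' the 10 s before onset; and the within-bout habituation, mean over the
#' first 2 s of the stimulus minus mean over its last 2 s. Traces are not
#' smoothed before peak detection; a local maximum is a sign change of the
#' first difference.
#'
#' @param trace baseline-subtracted wingspan (mm), `NA` where invalid.
#' @param frameRate Hz.
#' @param stimOnS,stimOffS light-on and light-off times in seconds.
#' @param sex `"male"` or `"female"`.
#' @param peakThresholds named thresholds in mm (default c(male = 0.22,
#'   female = 0.25)).
#' @return list with `first_peak_latency_s` (NA if no qualifying peak),
#'   `baseline_shift`, `habituation`; window means are `NA` when the record
#'   does not cover them.
#' @export
wingspanMetrics <- function(trace, frameRate, stimOnS, stimOffS,
                            sex = c("male", "female"),
                            peakThresholds = c(male = 0.22, female = 0.25)) {
  sex <- match.arg(sex)
  thr <- peakThresholds[[sex]]
  n <- length(trace)
  t <- (seq_len(n) - 1L) / frameRate

  winMean <- function(lo, hi) {
    idx <- which(t >= lo & t < hi)
    if (length(idx) == 0L || all(is.na(trace[idx]))) NA_real_
    else mean(trace[idx], na.rm = TRUE)
  }

  ## first local maximum above threshold at/after light onset
  lat <- NA_real_
  d <- diff(trace)
  peaks <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  peaks <- peaks[!is.na(trace[peaks]) & trace[peaks] > thr & t[peaks] >= stimOnS]
  if (length(peaks)) lat <- t[peaks[1L]] - stimOnS

  list(first_peak_latency_s = lat,
       baseline_shift = winMean(stimOffS + 20, stimOffS + 30) -
         winMean(stimOnS - 10, stimOnS),
       habituation = winMean(stimOnS, stimOnS + 2) -
         winMean(stimOffS - 2, stimOffS))
}

#' Write / read an ethogram as CSV
#'
#' Columns: `frame, time_s`, one logical column per action (empty where
#' indeterminate) and `unknown`.
#'
#' @param etho an [Ethogram-class].
#' @param path file path.
#' @param frameRate Hz (reading).
#' @return the path (writing) or an [Ethogram-class] (reading).
#' @export
writeEthogramCsv <- function(etho, path) {
  lab <- actionFlags(etho)
  df <- data.frame(frame = seq_len(nrow(lab)),
                   time_s = (seq_len(nrow(lab)) - 1L) / frameRate(etho))
  for (a in actionNames()) df[[a]] <- lab[, a]
  df$unknown <- unknownMask(etho)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEthogramCsv
#' @export
readEthogramCsv <- function(path, frameRate) {
  df <- utils::read.csv(path)
  lab <- as.matrix(sapply(actionNames(), function(a) as.logical(df[[a]])))
  colnames(lab) <- actionNames()
  ethogram(lab, frameRate)
}
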