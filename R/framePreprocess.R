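## Pixel-statistics foreground segmentation of behavioural video.
##
## Moving-fly pixels vary strongly relative to their brightness, so the
## log10 coefficient of variation (LCV) of each pixel across frames
## separates the animal from the static arena: foreground pixels satisfy
## LCV > 0.25 together with log10(sd) < 0.45. Contrast equalization and
## sharpening downstream of the mask are standard image ops and out of
## scope here; the contract of this module ends at the mask.

#' Per-pixel background image of a frame stack
#'
#' Background is the per-pixel mean over a strided subsample of frames.
#' A session-level background can be formed with [sessionBackground()] as
#' the mean of per-trial backgrounds, which guards against trials where the
#' fly never moves.
#'
#' @param frames numeric array (height x width x frames) of grayscale
#'   intensities, or a list of equally sized matrices.
#' @param subsampleStride keep every `subsampleStride`-th frame (>= 1).
#' @return numeric matrix (height x width).
#' @examples
#' fr <- array(rep(c(10, 30), each = 4), c(2, 2, 2))
#' computeBackground(fr)  # all 20
#' @export
computeBackground <- function(frames, subsampleStride = 1L) {
  frames <- as_frame_array(frames)
  stopifnot(subsampleStride >= 1)
  n <- dim(frames)[3]
  if (n < 1L) stop("no frames")
  idx <- seq(1L, n, by = as.integer(subsampleStride))
  sub <- frames[, , idx, drop = FALSE]
  apply(sub, c(1L, 2L), mean)
}

#' Session background from per-trial backgrounds
#'
#' @param backgrounds list of per-trial background matrices of equal size.
#' @return their per-pixel mean.
#' @export
sessionBackground <- function(backgrounds) {
  if (length(backgrounds) == 0L) stop("no frames")
  Reduce(`+`, backgrounds) / length(backgrounds)
}

#' Per-pixel temporal statistics
#'
#' Computes the per-pixel temporal mean, standard deviation and LCV
#' \eqn{\log_{10}(\sigma/\mu)} of a grayscale frame stack. Pixels with
#' \eqn{\mu \le 0} or \eqn{\sigma = 0} have an undefined LCV and are flagged;
#' they are classified background by [lcvForegroundMask()], never an error.
#'
#' @param frames numeric array (height x width x frames) or list of matrices;
#'   at least 2 frames.
#' @return a [PixelStatsImage-class].
#' @export
pixelStats <- function(frames) {
  frames <- as_frame_array(frames)
  n <- dim(frames)[3]
  if (n < 2L) stop("pixel statistics need at least 2 frames")
  mu <- apply(frames, c(1L, 2L), mean)
  ## population-style sd is irrelevant at video frame counts; sample sd used
  sdev <- apply(frames, c(1L, 2L), stats::sd)
  defined <- mu > 0 & sdev > 0
  lcv <- matrix(NA_real_, nrow(mu), ncol(mu))
  lcv[defined] <- log10(sdev[defined] / mu[defined])
  methods::new("PixelStatsImage", mean = mu, sd = sdev, lcv = lcv,
               defined = defined, nFrames = as.integer(n))
}

#' LCV foreground mask
#'
#' Applies the foreground rule: a pixel is foreground exactly when its LCV
#' exceeds `lcvMin` and its log10 standard deviation is below `logStdMax`.
#' Undefined-LCV pixels are background. The mask is monotone in `lcvMin`:
#' raising it never adds pixels.
#'
#' @param stats a [PixelStatsImage-class].
#' @param lcvMin LCV threshold (default 0.25).
#' @param logStdMax log10 standard deviation ceiling (default 0.45).
#' @return logical matrix, `TRUE` on foreground.
#' @export
lcvForegroundMask <- function(stats, lcvMin = 0.25, logStdMax = 0.45) {
  stopifnot(methods::is(stats, "PixelStatsImage"))
  mask <- stats@defined & !is.na(stats@lcv) &
    stats@lcv > lcvMin & log10(pmax(stats@sd, .Machine$double.xmin)) < logStdMax
  mask & stats@defined
}

as_frame_array <- function(frames) {
  if (is.list(frames)) {
    if (length(frames) == 0L) stop("no frames")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dim(frames[[1]]), length(frames)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) stop("frames must be height x width x frames")
  if (dim(frames)[3] < 1L) stop("no frames")
  frames
}
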