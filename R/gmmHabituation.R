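## Sliding-window Gaussian mixture analysis of wing pitch. During
## stimulation flies hold their wings slightly ajar even when not
## displaying, so the pitch distribution in a window is modelled as a
## two-component Gaussian mixture (display vs. non-display), with a
## fallback to a single Gaussian when the two-component fit is not
## supported (worse BIC) or the component means are closer than 5 degrees.

#' Sliding-window GMM habituation analysis of wing pitch
#'
#' Fits a single Gaussian to the pre-onset baseline window, then a
#' two-component Gaussian mixture (unequal variances, EM via \pkg{mclust})
#' to sliding windows over the stimulus period. A window falls back to one
#' component when the two-component BIC is worse than the single-Gaussian
#' BIC or the fitted means differ by less than `meanGapMinDeg`. BIC is the
#' standard \eqn{-2\log L + k \log n} with \eqn{k = 3G - 1} free parameters
#' (mean, sd and weight per component); lower is better.
#'
#' @param pitch wing pitch series in degrees, `NA` where invalid.
#' @param frameRate Hz.
#' @param onsetS stimulus onset time (s).
#' @param endS end of the analysed period (s); defaults to the series end.
#' @param baselineS pre-onset baseline window length (default 0.5 s).
#' @param windowS sliding window length (default 1.5 s).
#' @param overlapS overlap between consecutive windows (default 1 s, i.e.
#'   a 0.5 s step).
#' @param minSamples windows with fewer valid samples are skipped and
#'   flagged (default 10).
#' @param meanGapMinDeg minimum separation of the two component means
#'   (default 5 degrees).
#' @return list with `baseline` (list `mean`, `sd`, `n`) and `windows`, a
#'   data.frame with one row per window: `window_center_s`, `n_components`,
#'   `mean1`, `mean2`, `sd1`, `sd2`, `mixing1`, `mixing2`, `bic_1`, `bic_2`,
#'   `skipped`. Components are ordered by increasing mean; single-component
#'   rows leave the second component `NA`.
#' @export
gmmHabituation <- function(pitch, frameRate, onsetS, endS = NULL,
                           baselineS = 0.5, windowS = 1.5, overlapS = 1.0,
                           minSamples = 10, meanGapMinDeg = 5) {
  stopifnot(windowS > overlapS)
  n <- length(pitch)
  t <- (seq_len(n) - 1L) / frameRate
  if (is.null(endS)) endS <- n / frameRate

  base <- pitch[t >= onsetS - baselineS & t < onsetS & !is.na(pitch)]
  if (length(base) < 2L) stop("baseline window has fewer than 2 valid samples")
  baseline <- list(mean = mean(base), sd = stats::sd(base), n = length(base))

  step <- windowS - overlapS
  starts <- seq(onsetS, endS - windowS, by = step)
  rows <- lapply(starts, function(s) {
    x <- pitch[t >= s & t < s + windowS & !is.na(pitch)]
    row <- data.frame(window_center_s = s + windowS / 2, n_components = NA_integer_,
                      mean1 = NA_real_, mean2 = NA_real_, sd1 = NA_real_,
                      sd2 = NA_real_, mixing1 = NA_real_, mixing2 = NA_real_,
                      bic_1 = NA_real_, bic_2 = NA_real_, skipped = FALSE)
    if (length(x) < minSamples) { row$skipped <- TRUE; return(row) }
    f1 <- fitGauss1(x)
    f2 <- fitGauss2(x)
    row$bic_1 <- f1$bic
    use1 <- is.null(f2) || f2$bic > f1$bic ||
      abs(diff(f2$means)) < meanGapMinDeg
    if (!is.null(f2)) row$bic_2 <- f2$bic
    if (use1) {
      row$n_components <- 1L
      row$mean1 <- f1$mean; row$sd1 <- f1$sd; row$mixing1 <- 1
    } else {
      o <- order(f2$means)
      row$n_components <- 2L
      row$mean1 <- f2$means[o[1]]; row$mean2 <- f2$means[o[2]]
      row$sd1 <- f2$sds[o[1]]; row$sd2 <- f2$sds[o[2]]
      row$mixing1 <- f2$mixing[o[1]]; row$mixing2 <- f2$mixing[o[2]]
    }
    row
  })
  list(baseline = baseline, windows = do.call(rbind, rows))
}

fitGauss1 <- function(x) {
  n <- length(x)
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))  # ML variance
  ll <- sum(stats::dnorm(x, mu, max(sdev, 1e-12), log = TRUE))
  list(mean = mu, sd = sdev, bic = -2 * ll + 2 * log(n))
}

#' @importFrom mclust Mclust mclustBIC
fitGauss2 <- function(x) {
  n <- length(x)
  fit <- tryCatch(
    Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$parameters
  list(means = as.numeric(p$mean),
       sds = sqrt(as.numeric(p$variance$sigmasq)),
       mixing = as.numeric(p$pro),
       bic = -2 * fit$loglik + 5 * log(n))
}
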