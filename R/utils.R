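## Small numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Unsigned angle between two 3D vectors, degrees in [0, 180].
## atan2 of (|cross|, dot) is numerically stabler than acos of the dot.
angleBetweenDeg <- function(u, v) {
  cr <- vcross(u, v)
  rad2deg(atan2(sqrt(sum(cr^2)), sum(u * v)))
}

#' Centred moving mean with shrinking edge windows
#'
#' Averages each point over a centred window of `k` samples; near the series
#' edges the window shrinks to the available samples. `NA`s are dropped from
#' each window (all-`NA` windows give `NA`).
#'
#' @param x numeric vector.
#' @param k window width in samples (>= 1).
#' @return numeric vector of the same length.
#' @export
movingMeanCentered <- function(x, k) {
  stopifnot(k >= 1)
  n <- length(x)
  if (k == 1 || n == 0) return(x)
  half_lo <- floor((k - 1) / 2)
  half_hi <- k - 1 - half_lo
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half_lo):min(n, i + half_hi)]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

## Run-length segments of TRUE in a logical vector where NA breaks runs.
## Returns data.frame(start, end) in frame indices (inclusive).
trueRuns <- function(flag) {
  f <- !is.na(flag) & flag
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

## Adjusted Rand index between two labelings (standard contingency formula).
#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, used to score planted-
#' module recovery of the clustering stages. 1 means identical partitions
#' (up to label permutation), 0 is the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
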