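# Histogram thresholding used by the length filter (Otsu) and the
# fluorescence positivity gate (triangle). Both operate on explicit
# histograms so that integer-valued inputs give exactly reproducible cuts.

#' Otsu threshold on a numeric sample
#'
#' Bins the values into `nbins` equal-width bins over their range and returns
#' the bin-edge threshold maximizing the between-class variance. Used to
#' separate the bimodal cell-length histogram of rod-shaped vs dividing cells.
#'
#' @param x Numeric vector (e.g. cell lengths in pixels).
#' @param nbins Number of histogram bins (default 64).
#' @return The threshold value (a bin upper edge), or `NA` if `x` is constant.
#' @export
otsu_threshold <- function(x, nbins = 64) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) == 0) return(NA_real_)
  edges <- seq(min(x), max(x), length.out = nbins + 1)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), nbins), nbins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  k <- otsu_split(counts, mids)
  if (is.na(k)) return(NA_real_)
  edges[k + 1]
}

# Index k (classes = bins 1..k vs k+1..n) maximizing between-class variance.
otsu_split <- function(counts, mids) {
  n <- length(counts)
  w <- cumsum(counts)
  total <- w[n]
  if (total == 0) return(NA_integer_)
  s <- cumsum(counts * mids)
  mu_t <- s[n] / total
  k <- seq_len(n - 1)
  w0 <- w[k] / total
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n - 1)
  mu0 <- s[k] / w[k]
  mu1 <- (s[n] - s[k]) / (total - w[k])
  sigma_b[valid] <- (w0 * (1 - w0) * (mu0 - mu1)^2)[valid]
  if (all(!is.finite(sigma_b))) return(NA_integer_)
  # empty bins between two modes leave the criterion flat; take the middle
  # of the maximizing plateau so the cut sits centrally in the gap
  top <- which(sigma_b >= max(sigma_b) - 1e-12 * max(1, abs(max(sigma_b))))
  top[ceiling(length(top) / 2)]
}

#' Triangle threshold on a histogram
#'
#' Geometric threshold for skewed unimodal histograms: a line is drawn from
#' the histogram peak to the far end of the non-empty range and the threshold
#' is placed at the bin whose count lies furthest (perpendicular distance)
#' below that line. If the peak sits nearer the upper end, the histogram is
#' flipped first so the long tail is always to the right of the peak.
#'
#' @param counts Integer vector of histogram counts.
#' @param mids Optional numeric vector of bin centers; when supplied the
#'   threshold is returned on the value scale, otherwise as a bin index.
#' @return Threshold (bin index of the cut bin, or its bin-center value);
#'   `NA` if the histogram is degenerate (all mass in one bin or empty).
#' @export
triangle_threshold <- function(counts, mids = NULL) {
  n <- length(counts)
  nz <- which(counts > 0)
  if (!length(nz) || length(nz) == 1) return(if (is.null(mids)) NA_integer_ else NA_real_)
  peak <- which.max(counts)
  lo <- nz[1]; hi <- nz[length(nz)]
  flipped <- (peak - lo) > (hi - peak)  # tail on the left -> flip
  cts <- counts
  if (flipped) {
    cts <- rev(counts)
    peak <- n - peak + 1
    hi <- n - lo + 1
  }
  if (hi <= peak) return(if (is.null(mids)) NA_integer_ else NA_real_)
  i <- peak:hi
  # Perpendicular distance of (i, cts[i]) below the line through
  # (peak, cts[peak]) and (hi, cts[hi]); constant positive factors dropped
  # (zero at both endpoints, positive below the chord).
  dx <- hi - peak
  dy <- cts[peak] - cts[hi]
  d <- dx * (cts[peak] - cts[i]) - dy * (i - peak)
  k <- i[which.max(d)]
  if (flipped) k <- n - k + 1
  if (is.null(mids)) as.integer(k) else mids[k]
}

#' Triangle threshold of an image
#'
#' Convenience wrapper: histograms the image into `nbins` bins over its range
#' and returns the triangle threshold on the intensity scale.
#'
#' @param img Numeric matrix.
#' @param nbins Number of bins (default 256).
#' @return Threshold intensity, or `NA` for a flat image.
#' @export
triangle_threshold_image <- function(img, nbins = 256) {
  v <- as.vector(img)
  rg <- range(v)
  if (diff(rg) == 0) return(NA_real_)
  edges <- seq(rg[1], rg[2], length.out = nbins + 1)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins), nbins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  triangle_threshold(counts, mids)
}
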