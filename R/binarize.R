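#' Binarize a grayscale image
#'
#' Thresholds an image into a logical mask. `method = "fixed"` uses the
#' supplied threshold; `method = "otsu"` derives it from a 256-bin histogram by
#' maximizing between-class variance. The comparison is strict
#' (`intensity > threshold`), so a pixel exactly at the threshold is
#' background.
#'
#' @param image numeric matrix of intensities.
#' @param method `"fixed"` or `"otsu"`.
#' @param threshold intensity cutoff; required for `"fixed"`.
#' @return list with `mask` (logical matrix, 8-connectivity convention) and
#'   `threshold` (the value used).
#' @export
binarize <- function(image, method = c("fixed", "otsu"), threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  if (method == "fixed") {
    if (is.null(threshold)) stop("method = 'fixed' requires a threshold")
  } else {
    threshold <- otsu_threshold(image)
  }
  list(mask = image > threshold, threshold = threshold)
}

#' Otsu threshold from a 256-bin histogram
#'
#' @param image numeric matrix; must not be constant.
#' @return threshold on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image) {
  lo <- min(image); hi <- max(image)
  if (hi <= lo) stop("otsu threshold undefined: image is constant")
  nbins <- 256L
  # bin i covers [lo + (i-1)*w, lo + i*w); cut points are bin upper edges
  b <- pmin(nbins, floor((image - lo) / (hi - lo) * nbins) + 1L)
  h <- tabulate(b, nbins)
  p <- h / sum(h)
  centers <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  # between-class variance for threshold after bin k
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  lo + k * (hi - lo) / nbins  # upper edge of bin k
}
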