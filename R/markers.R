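#' Default marker correlation target
#'
#' A realistic weak-correlation structure for the four transporter markers,
#' built from reported average per-image correlation coefficients (all below
#' 0.5): GLAST-GLT1 0.23, GLAST-GAT3 0.46, GLAST-AQP4 0.27, GLT1-GAT3 0.46,
#' GLT1-AQP4 0.39; the unreported GAT3-AQP4 pair is set to 0.30.
#'
#' @return 4 x 4 symmetric correlation matrix.
#' @export
default_marker_corr <- function() {
  markers <- c("GLAST", "GLT1", "GAT3", "AQP4")
  m <- diag(4)
  dimnames(m) <- list(markers, markers)
  m["GLAST", "GLT1"] <- m["GLT1", "GLAST"] <- 0.23
  m["GLAST", "GAT3"] <- m["GAT3", "GLAST"] <- 0.46
  m["GLAST", "AQP4"] <- m["AQP4", "GLAST"] <- 0.27
  m["GLT1", "GAT3"] <- m["GAT3", "GLT1"] <- 0.46
  m["GLT1", "AQP4"] <- m["AQP4", "GLT1"] <- 0.39
  m["GAT3", "AQP4"] <- m["AQP4", "GAT3"] <- 0.30
  m
}

#' Generate correlated per-cell marker intensities
#'
#' Draws lognormal marker intensities through a Gaussian copula: multivariate
#' normal scores with the target correlation (via the symmetric matrix square
#' root) are transformed to lognormal marginals with the requested means and
#' coefficients of variation. For `n_cells >= 1000` the sample Pearson
#' correlation of the underlying Gaussian scores recovers the target to within
#' about +/- 0.05 entrywise.
#'
#' @param n_cells number of rows (cells).
#' @param target_corr symmetric positive semi-definite correlation matrix with
#'   unit diagonal; defaults to [default_marker_corr()].
#' @param means per-marker intensity means (recycled).
#' @param cvs per-marker coefficients of variation (recycled).
#' @param seed integer seed; the table is a pure function of the arguments.
#' @return data.frame of non-negative intensities, one row per cell, with the
#'   Gaussian scores in attribute `"scores"`.
#' @export
generate_marker_table <- function(n_cells, target_corr = default_marker_corr(),
                                  means = 100, cvs = 0.5, seed = 1) {
  stopifnot(n_cells >= 1)
  target_corr <- as.matrix(target_corr)
  p <- ncol(target_corr)
  if (!isTRUE(all.equal(target_corr, t(target_corr), tolerance = 1e-8)))
    stop("target_corr must be symmetric")
  if (any(abs(diag(target_corr) - 1) > 1e-8))
    stop("target_corr must have unit diagonal")
  ev <- eigen(target_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("target_corr is not positive semi-definite")
  markers <- colnames(target_corr)
  if (is.null(markers)) markers <- paste0("M", seq_len(p))
  means <- rep_len(means, p)
  cvs <- rep_len(cvs, p)

  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_cells * p), n_cells, p)
  rootm <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  scores <- z %*% rootm
  colnames(scores) <- markers
  sdlog <- sqrt(log(1 + cvs^2))
  meanlog <- log(means) - sdlog^2 / 2
  vals <- exp(sweep(sweep(scores, 2, sdlog, `*`), 2, meanlog, `+`))
  out <- as.data.frame(vals)
  names(out) <- markers
  attr(out, "scores") <- scores
  out
}
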