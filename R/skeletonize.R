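#' Skeletonize a binary mask
#'
#' Homotopic thinning to a one-pixel-wide, 8-connected skeleton. A foreground
#' pixel is deletable when it is 8-simple (Yokoi connectivity number equal to
#' 1) and has 2 to 6 foreground neighbours (so endpoints are preserved).
#' Deletions are applied in four sub-passes over the (row mod 2, col mod 2)
#' colour classes; pixels of one class are never in each other's
#' 8-neighbourhood, so each parallel sub-pass is equivalent to sequential
#' simple-point removal and the thinning is homotopic: the number of
#' 8-connected components is preserved and the skeleton is a subset of the
#' mask. Iteration stops at a fixed point, which makes the operation
#' idempotent.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape, the thinned skeleton.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with a background ring so neighbour shifts need no bounds checks
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mask

  rowpar <- matrix(seq_len(nr) %% 2L, nr, nc)
  colpar <- matrix(rep(seq_len(nc) %% 2L, each = nr), nr, nc)

  repeat {
    changed <- FALSE
    for (a in 0:1) for (b in 0:1) {
      del <- deletable_pixels(P, nr, nc) & rowpar == a & colpar == b
      if (any(del)) {
        changed <- TRUE
        P[2:(nr + 1L), 2:(nc + 1L)][del] <- FALSE
      }
    }
    if (!changed) break
  }
  P[2:(nr + 1L), 2:(nc + 1L)]
}

# Yokoi-simple, non-endpoint, non-interior pixels of the padded image
deletable_pixels <- function(P, nr, nc) {
  s <- function(dr, dc) P[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  fg <- s(0L, 0L)
  N <- s(-1L, 0L); NE <- s(-1L, 1L); E <- s(0L, 1L); SE <- s(1L, 1L)
  S <- s(1L, 0L);  SW <- s(1L, -1L); W <- s(0L, -1L); NW <- s(-1L, -1L)
  B <- N + NE + E + SE + S + SW + W + NW
  xN <- !N; xNE <- !NE; xE <- !E; xSE <- !SE
  xS <- !S; xSW <- !SW; xW <- !W; xNW <- !NW
  C8 <- (xN & !(xNE & xE)) + (xE & !(xSE & xS)) +
        (xS & !(xSW & xW)) + (xW & !(xNW & xN))
  fg & C8 == 1L & B >= 2L & B <= 7L
}

# 8-connected component count via union-find (shared test/oracle utility)
count_components8 <- function(mask) {
  px <- which(mask)
  n <- length(px)
  if (n == 0L) return(0L)
  nr <- nrow(mask)
  id <- integer(length(mask)); id[px] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  r <- (px - 1L) %% nr + 1L
  c <- (px - 1L) %/% nr + 1L
  for (off in list(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    q <- id[(c2[ok] - 1L) * nr + r2[ok]]
    p0 <- which(ok)[q > 0L]
    q <- q[q > 0L]
    for (k in seq_along(q)) {
      a <- find(id[px[p0[k]]]); b <- find(q[k])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}
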