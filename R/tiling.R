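#' Detect tiling violations between cells
#'
#' A branch of cell *i* violates the tiling when any of its rasterized
#' skeleton pixels lies within Chebyshev distance `epsilon` of a pixel
#' belonging to a different cell. With the default `epsilon = 1`, overlap or
#' 8-adjacency counts — the operational form of "touch or override". Detection
#' is symmetric: if a branch of A violates against B, at least one branch of B
#' is flagged against A. A branch is counted as violating once, regardless of
#' how many partner cells it touches. Self-overlaps (a cell coinciding with
#' itself away from a shared node) are tallied separately and excluded from
#' the tiling statistic, which is defined between astrocytes.
#'
#' @param cells list of `cell_skeleton` objects sharing one coordinate frame.
#' @param epsilon non-negative Chebyshev radius in pixels.
#' @return an object of class `violation_report`: `branches` (cell, branch,
#'   violating, partners), `per_cell` (cell, branch_count, violating_count,
#'   violation_percentage, has_violation, self_overlap_branches), `per_culture`
#'   (mean_violation_percentage, pct_cells_with_violation,
#'   mean_violating_count), and `epsilon`.
#' @export
detect_violations <- function(cells, epsilon = 1) {
  stopifnot(epsilon >= 0)
  ids <- vapply(cells, function(cs) as.integer(cs$cell_id), 1L)
  if (anyDuplicated(ids)) stop("duplicate cell ids")
  k <- length(cells)
  eps <- as.integer(floor(epsilon))  # pixels are integer, so Chebyshev <= eps
  if (k == 0L) {
    return(structure(list(
      branches = data.frame(cell = integer(0), branch = integer(0),
                            violating = logical(0), partners = character(0)),
      per_cell = data.frame(cell = integer(0), branch_count = integer(0),
                            violating_count = integer(0),
                            violation_percentage = numeric(0),
                            has_violation = logical(0),
                            self_overlap_branches = integer(0)),
      per_culture = list(mean_violation_percentage = NaN,
                         pct_cells_with_violation = NaN,
                         mean_violating_count = NaN),
      epsilon = epsilon), class = "violation_report"))
  }

  # rasterized pixels per branch, per cell
  pxl <- lapply(cells, function(cs)
    lapply(cs$polylines, rasterize_polyline))
  cellpx <- lapply(pxl, function(l)
    if (length(l)) do.call(rbind, l) else matrix(integer(0), 0, 2))
  nbr <- vapply(pxl, length, 1L)

  allpx <- do.call(rbind, cellpx)
  stride <- (if (nrow(allpx)) max(allpx[, 2]) else 0L) + 2L * eps + 3L
  shift <- eps + 1L
  enc <- function(px) (px[, 1] + shift) * stride + (px[, 2] + shift)
  offsets <- as.vector(outer(-eps:eps * stride, -eps:eps, "+"))

  enc_cell <- lapply(cellpx, function(px)
    if (nrow(px)) enc(px) else numeric(0))
  branch_of <- lapply(seq_len(k), function(i)
    rep(seq_len(nbr[i]), vapply(pxl[[i]], nrow, 1L)))
  enc_sorted <- lapply(enc_cell, sort)
  bbox <- lapply(cellpx, function(px)
    if (nrow(px)) c(range(px[, 1]), range(px[, 2])) else rep(NA_real_, 4))

  violating <- lapply(nbr, function(m) logical(m))
  partners <- lapply(nbr, function(m) vector("list", m))

  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    bi <- bbox[[i]]; bj <- bbox[[j]]
    if (anyNA(bi) || anyNA(bj)) next
    if (bi[1] > bj[2] + eps || bj[1] > bi[2] + eps ||
        bi[3] > bj[4] + eps || bj[3] > bi[4] + eps) next
    sj <- enc_sorted[[j]]
    si <- enc_sorted[[i]]
    hit_i <- rep(FALSE, length(enc_cell[[i]]))
    hit_j <- rep(FALSE, length(enc_cell[[j]]))
    for (off in offsets) {
      hit_i <- hit_i | enc_in(enc_cell[[i]] + off, sj)
      hit_j <- hit_j | enc_in(enc_cell[[j]] + off, si)
    }
    if (any(hit_i)) {
      vb <- unique(branch_of[[i]][hit_i])
      violating[[i]][vb] <- TRUE
      for (b in vb) partners[[i]][[b]] <- union(partners[[i]][[b]], ids[j])
    }
    if (any(hit_j)) {
      vb <- unique(branch_of[[j]][hit_j])
      violating[[j]][vb] <- TRUE
      for (b in vb) partners[[j]][[b]] <- union(partners[[j]][[b]], ids[i])
    }
  }

  self_overlap <- vapply(seq_len(k), function(i) {
    if (nbr[i] < 2L) return(0L)
    e <- enc_cell[[i]]
    dup <- duplicated(e) | duplicated(e, fromLast = TRUE)
    if (!any(dup)) return(0L)
    # shared node pixels between branches meeting at a node are expected;
    # count a branch when it coincides with a branch not sharing a node
    adj <- cells[[i]]$edges[, c("node_a", "node_b")]
    hits <- integer(0)
    de <- e[dup]; db <- branch_of[[i]][dup]
    for (v in unique(de)) {
      bs <- unique(db[de == v])
      if (length(bs) < 2L) next
      pairs <- utils::combn(bs, 2L)
      for (p in seq_len(ncol(pairs))) {
        b1 <- pairs[1, p]; b2 <- pairs[2, p]
        if (length(intersect(unlist(adj[b1, ]), unlist(adj[b2, ]))) == 0L)
          hits <- union(hits, c(b1, b2))
      }
    }
    length(hits)
  }, 1L)

  branches <- do.call(rbind, lapply(seq_len(k), function(i) {
    if (nbr[i] == 0L)
      return(data.frame(cell = integer(0), branch = integer(0),
                        violating = logical(0), partners = character(0)))
    data.frame(cell = ids[i], branch = seq_len(nbr[i]),
               violating = violating[[i]],
               partners = vapply(partners[[i]], function(p)
                 paste(sort(p), collapse = ";"), ""),
               stringsAsFactors = FALSE)
  }))
  per_cell <- data.frame(
    cell = ids,
    branch_count = nbr,
    violating_count = vapply(violating, sum, 1L),
    violation_percentage = ifelse(nbr > 0,
                                  100 * vapply(violating, sum, 1L) / nbr, 0),
    has_violation = vapply(violating, any, TRUE),
    self_overlap_branches = self_overlap)
  per_culture <- list(
    mean_violation_percentage = mean(per_cell$violation_percentage),
    pct_cells_with_violation = 100 * mean(per_cell$has_violation),
    mean_violating_count = mean(per_cell$violating_count))
  structure(list(branches = branches, per_cell = per_cell,
                 per_culture = per_culture, epsilon = epsilon),
            class = "violation_report")
}

# membership of values in a sorted table
enc_in <- function(x, sorted_table) {
  if (length(sorted_table) == 0L) return(rep(FALSE, length(x)))
  i <- findInterval(x, sorted_table)
  i > 0L & sorted_table[pmax(i, 1L)] == x
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf("Tiling violations (epsilon = %g): mean %.2f%% of branches per cell, %.0f%% of cells affected\n",
              x$epsilon, x$per_culture$mean_violation_percentage,
              x$per_culture$pct_cells_with_violation))
  invisible(x)
}

#' Brute-force violation detection (quadratic reference)
#'
#' All-pairs Chebyshev comparison between rasterized pixels of different
#' cells, used as the exact reference for [detect_violations()] on small
#' cultures.
#'
#' @param cells list of `cell_skeleton` objects.
#' @param epsilon Chebyshev radius, pixels.
#' @return logical list per cell of per-branch violation flags.
#' @export
detect_violations_bruteforce <- function(cells, epsilon = 1) {
  pxl <- lapply(cells, function(cs) lapply(cs$polylines, rasterize_polyline))
  k <- length(cells)
  out <- lapply(pxl, function(l) logical(length(l)))
  for (i in seq_len(k)) {
    other <- do.call(rbind, unlist(pxl[-i], recursive = FALSE))
    if (is.null(other) || nrow(other) == 0L) next
    for (b in seq_along(pxl[[i]])) {
      P <- pxl[[i]][[b]]
      if (nrow(P) == 0L) next
      hit <- FALSE
      for (q in seq_len(nrow(P))) {
        cheb <- pmax(abs(other[, 1] - P[q, 1]), abs(other[, 2] - P[q, 2]))
        if (any(cheb <= epsilon)) { hit <- TRUE; break }
      }
      out[[i]][b] <- hit
    }
  }
  out
}

#' Time-course summary of violation reports
#'
#' @param reports named list of `violation_report` objects, one per timepoint.
#' @return data.frame with one row per timepoint: `timepoint`, `n_cells`,
#'   `mean_violation_percentage`, `sem_violation_percentage`,
#'   `mean_violating_count`, `sem_violating_count`.
#' @export
violation_timecourse <- function(reports) {
  stopifnot(length(reports) >= 1)
  labs <- names(reports)
  if (is.null(labs)) labs <- as.character(seq_along(reports))
  rows <- lapply(seq_along(reports), function(t) {
    pc <- reports[[t]]$per_cell
    ms_p <- mean_sem(pc$violation_percentage)
    ms_c <- mean_sem(pc$violating_count)
    data.frame(timepoint = labs[t], n_cells = nrow(pc),
               mean_violation_percentage = ms_p$mean,
               sem_violation_percentage = ms_p$sem,
               mean_violating_count = ms_c$mean,
               sem_violating_count = ms_c$sem,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
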