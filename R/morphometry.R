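#' Topological branch orders
#'
#' Assigns each branch its topological order by traversal from the soma:
#' branches incident to the soma are order 1, and the order increases by 1
#' every time a junction node (degree 3 or more within the cell) is crossed,
#' i.e. the order of a branch is one plus the number of branching events
#' between the cell body and that branch. Along every soma-to-tip path the
#' orders therefore read 1, 2, ..., k with no gaps. If the cell subgraph
#' contains a cycle (a rare skeletonization artifact), the edge reachable from
#' two directions receives the minimum order over its two approach paths and
#' is flagged.
#'
#' @param cell a `cell_skeleton` (connected, with one soma).
#' @return integer vector of per-edge orders (parallel to `cell$edges`), with
#'   attribute `cycle` flagging edges on cycles.
#' @export
branch_orders <- function(cell) {
  stopifnot(inherits(cell, "cell_skeleton"))
  ne <- nrow(cell$edges)
  if (ne == 0L)
    return(structure(integer(0), cycle = logical(0)))

  nn <- nrow(cell$nodes)
  degree <- tabulate(c(cell$edges$node_a, cell$edges$node_b), nbins = nn)
  # incidence lists
  inc <- vector("list", nn)
  for (e in seq_len(ne)) {
    a <- cell$edges$node_a[e]; b <- cell$edges$node_b[e]
    inc[[a]] <- c(inc[[a]], e)
    if (b != a) inc[[b]] <- c(inc[[b]], e)
  }

  order_of <- rep(NA_integer_, ne)
  cycle <- logical(ne)
  node_in <- rep(NA_integer_, nn)   # order of the edge we arrived on
  soma <- cell$soma

  # bucket queue over incoming order so cycle edges get the minimum order
  maxo <- ne + 1L
  buckets <- vector("list", maxo + 1L)
  buckets[[1L]] <- soma
  node_in[soma] <- 0L
  for (o in 0:maxo) {
    nodes_here <- buckets[[o + 1L]]
    while (length(nodes_here)) {
      v <- nodes_here[[1L]]
      nodes_here <- nodes_here[-1L]
      for (e in inc[[v]]) {
        eo <- if (v == soma) 1L
              else if (degree[v] >= 3L) node_in[v] + 1L
              else node_in[v]
        if (!is.na(order_of[e])) {
          # reached again from the other side: keep the minimum order
          if (eo < order_of[e]) order_of[e] <- eo
          next
        }
        order_of[e] <- eo
        w <- if (cell$edges$node_a[e] == v) cell$edges$node_b[e]
             else cell$edges$node_a[e]
        if (is.na(node_in[w])) {
          node_in[w] <- eo
          if (eo >= o) {
            if (eo == o) nodes_here <- c(nodes_here, w)
            else buckets[[eo + 1L]] <- c(buckets[[eo + 1L]], w)
          }
        } else {
          cycle[e] <- TRUE  # second arrival at w closes a cycle
        }
      }
    }
  }
  if (anyNA(order_of))
    stop("cell subgraph is disconnected: some branches are unreachable ",
         "from the soma")
  structure(order_of, cycle = cycle)
}

#' Per-cell morphometrics
#'
#' Branch count (number of skeleton edges), total branch length (sum of edge
#' lengths in the orthogonal-1/diagonal-sqrt(2) step convention), axis-aligned
#' bounding-rectangle coverage area computed over the cell's rasterized
#' skeleton pixels as `(max_row - min_row + 1) * (max_col - min_col + 1)`,
#' maximum topological branch order, and the order histogram.
#'
#' @param cell a `cell_skeleton`.
#' @return an object of class `cell_metrics`: list with `cell_id`,
#'   `branch_count`, `total_length`, `bounding_rect_area`, `max_order`,
#'   `order_histogram` (counts for orders 1..max), `n_cycle_edges`.
#' @export
cell_metrics <- function(cell) {
  stopifnot(inherits(cell, "cell_skeleton"))
  orders <- branch_orders(cell)
  ne <- nrow(cell$edges)
  if (ne == 0L) {
    px <- rasterize_polyline(as.matrix(cell$nodes[cell$soma, c("row", "col")]))
  } else {
    px <- do.call(rbind, lapply(cell$polylines, rasterize_polyline))
  }
  area <- if (nrow(px) == 0L) 0 else
    (max(px[, 1]) - min(px[, 1]) + 1) * (max(px[, 2]) - min(px[, 2]) + 1)
  structure(list(cell_id = cell$cell_id,
                 branch_count = ne,
                 total_length = sum(cell$edges$length),
                 bounding_rect_area = area,
                 max_order = if (ne) max(orders) else 0L,
                 order_histogram = if (ne) tabulate(orders, nbins = max(orders))
                                   else integer(0),
                 n_cycle_edges = sum(attr(orders, "cycle"))),
            class = "cell_metrics")
}

#' @export
print.cell_metrics <- function(x, ...) {
  cat(sprintf("Cell %s: %d branches, total length %.1f px, rect area %g px^2, max order %d\n",
              as.character(x$cell_id), x$branch_count, x$total_length,
              x$bounding_rect_area, x$max_order))
  invisible(x)
}

#' Tidy metrics table for a set of cells
#'
#' @param cells list of `cell_skeleton` objects.
#' @return data.frame with one row per cell: `cell_id`, `branch_count`,
#'   `total_length`, `bounding_rect_area`, `max_order`.
#' @export
culture_metrics <- function(cells) {
  rows <- lapply(cells, function(cs) {
    m <- cell_metrics(cs)
    data.frame(cell_id = m$cell_id, branch_count = m$branch_count,
               total_length = m$total_length,
               bounding_rect_area = m$bounding_rect_area,
               max_order = m$max_order)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), branch_count = integer(0),
                      total_length = numeric(0),
                      bounding_rect_area = numeric(0), max_order = integer(0))
  out
}

#' Long-format order histogram for a set of cells
#'
#' @param cells list of `cell_skeleton` objects.
#' @return data.frame `cell_id`, `order`, `count`.
#' @export
order_histogram <- function(cells) {
  rows <- lapply(cells, function(cs) {
    m <- cell_metrics(cs)
    if (m$max_order == 0L) return(NULL)
    data.frame(cell_id = m$cell_id, order = seq_len(m$max_order),
               count = m$order_histogram)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), order = integer(0),
                      count = integer(0))
  out
}

#' Thresholded marker area and mean intensity
#'
#' Counts the pixels whose intensity strictly exceeds the threshold and
#' averages the intensity over those pixels, the per-image quantities used for
#' marker-positive-area time courses.
#'
#' @param image numeric matrix of intensities.
#' @param threshold intensity cutoff (strict).
#' @return list with `positive_area` (pixel count), `mean_intensity` (`NaN`
#'   with `defined = FALSE` when no pixel passes), `defined`.
#' @export
marker_area_intensity <- function(image, threshold) {
  stopifnot(is.matrix(image), is.numeric(image))
  pos <- image > threshold
  n <- sum(pos)
  list(positive_area = n,
       mean_intensity = if (n > 0) mean(image[pos]) else NaN,
       defined = n > 0)
}
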