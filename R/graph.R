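#' Extract a skeleton graph from a thinned mask
#'
#' Re-implementation of an AnalyzeSkeleton-style branch decomposition. Pixels
#' of a one-pixel-wide, 8-connected skeleton are classified by their number of
#' skeleton neighbours: 1 = endpoint, 2 = path, 3 or more = junction; isolated
#' pixels become zero-length single-node components. 8-adjacent junction
#' pixels are fused into a single junction node (avoiding spurious
#' micro-branches at crossings), and the pixel chains between nodes are traced
#' into edges carrying their polyline and a length equal to the step sum
#' (1 per orthogonal step, sqrt(2) per diagonal step — the ImageJ convention).
#' A connected component consisting only of path pixels (a pure cycle) gets an
#' artificial anchor node of kind `"loop"` and a single self-loop edge.
#'
#' All coordinates in the result are 0-based `(row, col)`.
#'
#' @param skeleton logical matrix, output of [skeletonize_mask()].
#' @return an object of class `skeleton_graph`: `nodes` (id, row, col, kind),
#'   `edges` (edge, node_a, node_b, length), `polylines` (list of integer
#'   matrices), `node_pixels` (list), `pixels` (per-pixel bookkeeping), `dim`.
#' @export
extract_graph <- function(skeleton) {
  stopifnot(is.matrix(skeleton), is.logical(skeleton))
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  # Non-thin input check. A fully-filled 2x3 or 3x2 block can never occur in
  # a thinned skeleton and raises an error. An isolated 2x2 plateau can: it is
  # the irreducible homotopic skeleton of an even-width X crossing (deleting
  # any of its four pixels would disconnect one arm), and its pixels all
  # classify as junction pixels, so it is fused into a single junction node
  # exactly like ImageJ's AnalyzeSkeleton treats it.
  if (nr > 2 && nc > 1) {
    blk3 <- skeleton[1:(nr - 2), , drop = FALSE] &
            skeleton[2:(nr - 1), , drop = FALSE] & skeleton[3:nr, , drop = FALSE]
    if (any(blk3[, -ncol(blk3), drop = FALSE] & blk3[, -1, drop = FALSE]))
      stop("input is not one pixel wide: fully-filled 3x2 block present; ",
           "run skeletonize_mask() first")
  }
  if (nc > 2 && nr > 1) {
    blk3 <- skeleton[, 1:(nc - 2), drop = FALSE] &
            skeleton[, 2:(nc - 1), drop = FALSE] & skeleton[, 3:nc, drop = FALSE]
    if (any(blk3[-nrow(blk3), , drop = FALSE] & blk3[-1, , drop = FALSE]))
      stop("input is not one pixel wide: fully-filled 2x3 block present; ",
           "run skeletonize_mask() first")
  }
  px <- which(skeleton)
  n <- length(px)
  empty <- function() {
    structure(list(nodes = data.frame(id = integer(0), row = numeric(0),
                                      col = numeric(0),
                                      kind = character(0)),
                   edges = data.frame(edge = integer(0), node_a = integer(0),
                                      node_b = integer(0), length = numeric(0)),
                   polylines = list(), node_pixels = list(),
                   pixels = data.frame(row = integer(0), col = integer(0),
                                       node = integer(0), edge = integer(0)),
                   dim = c(nr, nc)),
              class = "skeleton_graph")
  }
  if (n == 0L) return(empty())

  pid <- integer(nr * nc)
  pid[px] <- seq_len(n)
  pr <- (px - 1L) %% nr + 1L
  pc <- (px - 1L) %/% nr + 1L

  # 8-neighbour pids, 0 where absent
  offs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  nb <- matrix(0L, n, 8L)
  for (k in 1:8) {
    r2 <- pr + offs[k, 1]; c2 <- pc + offs[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb[ok, k] <- pid[(c2[ok] - 1L) * nr + r2[ok]]
  }
  deg <- rowSums(nb > 0L)

  is_junction <- deg >= 3L
  is_node_px <- deg != 2L

  # fuse 8-adjacent junction pixels (union-find)
  parent <- seq_len(n)
  uf_find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  jpx <- which(is_junction)
  for (i in jpx) {
    for (j in nb[i, ]) {
      if (j > 0L && is_junction[j]) {
        a <- uf_find(i); b <- uf_find(j)
        if (a != b) parent[a] <- b
      }
    }
  }

  node_of <- integer(n)
  nodes_row <- nodes_col <- numeric(0)
  nodes_kind <- character(0)
  node_pixels <- list()
  nnode <- 0L
  add_node <- function(pids, kind) {
    nnode <<- nnode + 1L
    node_of[pids] <<- nnode
    nodes_row[nnode] <<- mean(pr[pids]) - 1
    nodes_col[nnode] <<- mean(pc[pids]) - 1
    nodes_kind[nnode] <<- kind
    node_pixels[[nnode]] <<- cbind(row = pr[pids] - 1L, col = pc[pids] - 1L)
    nnode
  }
  for (i in which(deg == 0L)) add_node(i, "endpoint")
  for (i in which(deg == 1L)) add_node(i, "endpoint")
  if (length(jpx)) {
    roots <- vapply(jpx, uf_find, 1L)
    for (cl in split(jpx, roots)) add_node(cl, "junction")
  }

  # trace edges
  visited <- logical(n)        # for path pixels
  edges_a <- edges_b <- integer(0)
  polylines <- list()
  nedge <- 0L
  edge_of <- integer(n)        # interior path pixel -> edge
  buf <- integer(n + 2L)

  add_edge <- function(a, b, chain) {
    nedge <<- nedge + 1L
    edges_a[nedge] <<- a
    edges_b[nedge] <<- b
    polylines[[nedge]] <<- cbind(row = pr[chain] - 1L, col = pc[chain] - 1L)
    if (length(chain) > 2L)
      edge_of[chain[2:(length(chain) - 1L)]] <<- nedge
    nedge
  }

  trace_from <- function(start, first) {
    buf[1L] <- start; buf[2L] <- first
    visited[first] <<- TRUE
    len <- 2L
    prev <- start; cur <- first
    repeat {
      two <- nb[cur, ]
      two <- two[two > 0L]
      nxt <- two[two != prev]
      if (length(nxt) == 0L) nxt <- prev  # 2-cycle degenerate guard
      nxt <- nxt[1L]
      len <- len + 1L
      buf[len] <- nxt
      if (is_node_px[nxt]) break
      if (visited[nxt]) break  # closes a pure cycle back onto its anchor
      visited[nxt] <<- TRUE
      prev <- cur; cur <- nxt
    }
    buf[seq_len(len)]
  }

  direct_keys <- character(0)
  node_px_order <- which(is_node_px)
  for (i in node_px_order) {
    for (j in nb[i, ]) {
      if (j == 0L) next
      if (!is_node_px[j]) {
        if (!visited[j]) {
          chain <- trace_from(i, j)
          add_edge(node_of[i], node_of[chain[length(chain)]], chain)
        }
      } else {
        a <- node_of[i]; b <- node_of[j]
        if (a != b) {
          key <- paste0(min(a, b), "_", max(a, b))
          if (!(key %in% direct_keys)) {
            direct_keys <- c(direct_keys, key)
            add_edge(a, b, c(i, j))
          }
        }
      }
    }
  }

  # pure cycles: remaining untraced path pixels
  repeat {
    left <- which(!visited & deg == 2L & node_of == 0L)
    if (length(left) == 0L) break
    anchorpx <- left[1L]
    a <- add_node(anchorpx, "loop")
    visited[anchorpx] <- TRUE  # so the cycle trace terminates here
    first <- nb[anchorpx, ][nb[anchorpx, ] > 0L][1L]
    chain <- trace_from(anchorpx, first)
    add_edge(a, node_of[chain[length(chain)]], chain)
  }

  lens <- vapply(polylines, polyline_length, 0)
  structure(list(nodes = data.frame(id = seq_len(nnode), row = nodes_row,
                                    col = nodes_col, kind = nodes_kind,
                                    stringsAsFactors = FALSE),
                 edges = data.frame(edge = seq_len(nedge),
                                    node_a = edges_a, node_b = edges_b,
                                    length = if (nedge) lens else numeric(0)),
                 polylines = polylines, node_pixels = node_pixels,
                 pixels = data.frame(row = pr - 1L, col = pc - 1L,
                                     node = node_of, edge = edge_of),
                 dim = c(nr, nc)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("Skeleton graph: %d nodes (%d endpoints, %d junctions), %d edges, total length %.1f px\n",
              nrow(x$nodes), sum(x$nodes$kind == "endpoint"),
              sum(x$nodes$kind == "junction"), nrow(x$edges),
              sum(x$edges$length)))
  invisible(x)
}

#' Partition a skeleton graph among cells by soma seeds
#'
#' Each soma coordinate is snapped to the nearest skeleton pixel (which must
#' lie within `max_snap` pixels); if that pixel falls mid-edge the edge is
#' split and a new node inserted. Every edge is then assigned to the cell
#' whose soma is geodesically nearest along the graph (distance from the soma
#' to the nearer endpoint of the edge, weighted by branch length) — not by
#' Euclidean proximity, so a branch threading between somata stays with its
#' own tree. Geodesic ties are broken toward the lower cell id and flagged
#' ambiguous; edges unreachable from every soma, or disconnected from their
#' assigned soma within the cell subgraph, are reported unassigned.
#'
#' @param graph a `skeleton_graph`.
#' @param somata matrix or data.frame of 0-based soma coordinates; columns
#'   `row`, `col` (and optionally `cell_id`; default ids are 1..k).
#' @param max_snap maximum snap distance in pixels.
#' @return an object of class `cell_assignment`: `cells` (list of
#'   `cell_skeleton`), `assignment` (per-edge cell, ambiguous flag),
#'   `unassigned` (edge ids and reason), and the (possibly split) `graph`.
#' @export
assign_cells <- function(graph, somata, max_snap = 5) {
  stopifnot(inherits(graph, "skeleton_graph"))
  somata <- as.data.frame(somata)
  if (!all(c("row", "col") %in% names(somata)))
    stop("somata must have 'row' and 'col' columns")
  if (is.null(somata$cell_id)) somata$cell_id <- seq_len(nrow(somata))
  k <- nrow(somata)
  if (anyDuplicated(somata$cell_id)) stop("duplicate cell ids in somata")

  soma_node <- integer(k)
  for (s in seq_len(k)) {
    d2 <- (graph$pixels$row - somata$row[s])^2 +
          (graph$pixels$col - somata$col[s])^2
    # pixels orphaned by terminal pruning are neither node nor edge members
    d2[graph$pixels$node == 0L & graph$pixels$edge == 0L] <- Inf
    i <- which.min(d2)
    if (length(i) == 0L || d2[i] > max_snap^2)
      stop(sprintf("soma %s is farther than %g px from any skeleton pixel",
                   as.character(somata$cell_id[s]), max_snap))
    if (graph$pixels$node[i] > 0L) {
      soma_node[s] <- graph$pixels$node[i]
    } else {
      res <- split_edge_at_pixel(graph, i)
      graph <- res$graph
      soma_node[s] <- res$node
    }
    graph$nodes$kind[soma_node[s]] <- "soma"
  }
  if (anyDuplicated(soma_node))
    stop("two somata snap to the same skeleton node; ",
         "check the soma seed coordinates")

  ne <- nrow(graph$edges)
  if (ne == 0L) {
    return(structure(list(cells = list(), assignment = NULL,
                          unassigned = data.frame(edge = integer(0),
                                                  reason = character(0)),
                          graph = graph, somata = somata),
                     class = "cell_assignment"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$node_a, to = graph$edges$node_b,
               weight = graph$edges$length),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$id))
  d <- igraph::distances(g, v = as.character(soma_node),
                         weights = igraph::E(g)$weight)
  d <- d[, as.character(graph$nodes$id), drop = FALSE]
  edist <- pmin(d[, graph$edges$node_a, drop = FALSE],
                d[, graph$edges$node_b, drop = FALSE])  # k x ne

  assigned <- integer(ne)
  ambiguous <- logical(ne)
  for (e in seq_len(ne)) {
    de <- edist[, e]
    if (all(is.infinite(de))) { assigned[e] <- 0L; next }
    m <- min(de)
    winners <- which(de <= m + 1e-9)
    assigned[e] <- winners[1L]
    ambiguous[e] <- length(winners) > 1L
  }
  unassigned <- data.frame(edge = which(assigned == 0L),
                           reason = rep("unreachable", sum(assigned == 0L)),
                           stringsAsFactors = FALSE)

  cells <- vector("list", k)
  for (s in seq_len(k)) {
    eids <- which(assigned == s)
    # keep only the component of the cell subgraph containing the soma
    if (length(eids)) {
      sg <- igraph::graph_from_data_frame(
        data.frame(from = graph$edges$node_a[eids],
                   to = graph$edges$node_b[eids]),
        directed = FALSE)
      comp <- igraph::components(sg)
      sn <- as.character(soma_node[s])
      if (sn %in% igraph::V(sg)$name) {
        soma_comp <- comp$membership[sn]
        keep <- comp$membership[as.character(graph$edges$node_a[eids])] ==
                soma_comp
      } else {
        keep <- rep(FALSE, length(eids))
      }
      if (any(!keep)) {
        unassigned <- rbind(unassigned,
                            data.frame(edge = eids[!keep],
                                       reason = "orphaned",
                                       stringsAsFactors = FALSE))
        eids <- eids[keep]
      }
    }
    cells[[s]] <- subgraph_to_cell(graph, eids, soma_node[s],
                                   somata$cell_id[s])
  }
  structure(list(cells = cells,
                 assignment = data.frame(edge = seq_len(ne), cell = assigned,
                                         ambiguous = ambiguous),
                 unassigned = unassigned, graph = graph, somata = somata),
            class = "cell_assignment")
}

split_edge_at_pixel <- function(graph, pix_i) {
  e <- graph$pixels$edge[pix_i]
  stopifnot(e > 0L)
  poly <- graph$polylines[[e]]
  pos <- which(poly[, 1] == graph$pixels$row[pix_i] &
               poly[, 2] == graph$pixels$col[pix_i])[1L]
  nnode <- nrow(graph$nodes) + 1L
  graph$nodes <- rbind(graph$nodes,
                       data.frame(id = nnode, row = poly[pos, 1],
                                  col = poly[pos, 2], kind = "soma",
                                  stringsAsFactors = FALSE))
  graph$node_pixels[[nnode]] <- poly[pos, , drop = FALSE]

  p1 <- poly[1:pos, , drop = FALSE]
  p2 <- poly[pos:nrow(poly), , drop = FALSE]
  old_b <- graph$edges$node_b[e]
  graph$edges$node_b[e] <- nnode
  graph$edges$length[e] <- polyline_length(p1)
  graph$polylines[[e]] <- p1
  ne <- nrow(graph$edges) + 1L
  graph$edges <- rbind(graph$edges,
                       data.frame(edge = ne, node_a = nnode, node_b = old_b,
                                  length = polyline_length(p2)))
  graph$polylines[[ne]] <- p2

  # refresh per-pixel bookkeeping for the split polylines
  upd <- function(eid, poly) {
    if (nrow(poly) > 2L) {
      interior <- poly[2:(nrow(poly) - 1L), , drop = FALSE]
      m <- match(interior[, 1] * 2147483 + interior[, 2],
                 graph$pixels$row * 2147483 + graph$pixels$col)
      graph$pixels$edge[m] <<- eid
    }
  }
  upd(e, p1); upd(ne, p2)
  graph$pixels$node[pix_i] <- nnode
  graph$pixels$edge[pix_i] <- 0L
  list(graph = graph, node = nnode)
}

subgraph_to_cell <- function(graph, eids, soma_node, cell_id) {
  nids <- sort(unique(c(soma_node,
                        graph$edges$node_a[eids], graph$edges$node_b[eids])))
  nodes <- graph$nodes[match(nids, graph$nodes$id), , drop = FALSE]
  nodes$id <- seq_along(nids)
  rownames(nodes) <- NULL
  remap <- function(v) match(v, nids)
  edges <- data.frame(edge = seq_along(eids),
                      node_a = remap(graph$edges$node_a[eids]),
                      node_b = remap(graph$edges$node_b[eids]),
                      length = graph$edges$length[eids])
  new_cell_skeleton(cell_id, nodes, soma = remap(soma_node), edges = edges,
                    polylines = graph$polylines[eids])
}

#' @export
print.cell_assignment <- function(x, ...) {
  cat(sprintf("Cell assignment: %d cells, %d edges unassigned, %d ambiguous\n",
              length(x$cells), nrow(x$unassigned),
              if (is.null(x$assignment)) 0L else sum(x$assignment$ambiguous)))
  invisible(x)
}
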