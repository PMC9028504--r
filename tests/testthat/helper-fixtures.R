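# Shared fixtures and independent oracles.

# small, fast growth configurations
tiny_params <- function(...) {
  growth_params(n_cells = 1, field_size = c(120, 120), soma_min_spacing = 10,
                primaries_per_cell = 3, step_length = 2, angle_noise_sd = 0,
                branch_prob = 0, divergence_angle = 1.2, avoid_radius = 2,
                n_candidate_dirs = 4, n_steps = 10, ...)
}

small_tiled_params <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 4, field_size = c(400, 400), soma_min_spacing = 120,
         n_steps = 60),
    list(...))
  do.call(growth_params, args)
}

# hand-built node tree: soma at origin, one stem of `stem` nodes, then two
# arms of `arm` nodes each (a Y)
y_tree <- function(stem = 2, arm = 2, step = 2) {
  x <- 0; y <- 0; parent <- 0L
  for (i in seq_len(stem)) { x <- c(x, 0); y <- c(y, i * step); parent <- c(parent, i) }
  base <- stem + 1L
  cur <- base
  for (i in seq_len(arm)) {
    x <- c(x, -i * step); y <- c(y, stem * step + i * step)
    parent <- c(parent, cur); cur <- length(x)
  }
  cur <- base
  for (i in seq_len(arm)) {
    x <- c(x, i * step); y <- c(y, stem * step + i * step)
    parent <- c(parent, cur); cur <- length(x)
  }
  data.frame(x = x, y = y, parent = parent, born = seq_along(x) - 1L)
}

tree_culture <- function(trees, field = c(200, 200)) {
  somata <- do.call(rbind, lapply(trees, function(nd) c(x = nd$x[1], y = nd$y[1])))
  structure(list(cells = trees, somata = somata,
                 params = growth_params(n_cells = length(trees),
                                        field_size = field,
                                        soma_min_spacing = 1),
                 seed = 0L),
            class = "astro_culture")
}

# shift a node tree in space
shift_tree <- function(nd, dx, dy) { nd$x <- nd$x + dx; nd$y <- nd$y + dy; nd }

# --- independent oracle: neighbor-count classification of a thin skeleton ---
# endpoint pixels: <= 1 skeleton neighbor; junction clusters: connected
# components (8-conn) of pixels with >= 3 neighbors; edges: components of
# degree-2 pixels (each chain or pure cycle is one edge) plus deduplicated
# direct adjacencies between distinct nodes. Built on igraph, independently
# of extract_graph's union-find/trace implementation.
oracle_graph_counts <- function(skel) {
  px <- which(skel)
  n <- length(px)
  if (n == 0L) return(list(endpoints = 0L, junctions = 0L, edges = 0L))
  nr <- nrow(skel); nc <- ncol(skel)
  r <- (px - 1L) %% nr + 1L
  c <- (px - 1L) %/% nr + 1L
  id <- integer(nr * nc); id[px] <- seq_len(n)
  pairs <- NULL
  for (off in list(c(-1L,-1L), c(0L,-1L), c(1L,-1L), c(-1L,0L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    q <- integer(n); q[ok] <- id[(c2[ok] - 1L) * nr + r2[ok]]
    w <- which(q > 0L)
    if (length(w)) pairs <- rbind(pairs, cbind(w, q[w]))
  }
  if (is.null(pairs))  # only isolated pixels
    return(list(endpoints = n, junctions = 0L, edges = 0L))
  deg <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
  endpoints <- sum(deg <= 1L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  jpx <- which(deg >= 3L)
  junctions <- if (length(jpx))
    igraph::components(igraph::induced_subgraph(g, as.character(jpx)))$no
  else 0L
  # node id per pixel: endpoints own id, junction pixels -> cluster id
  node_of <- integer(n)
  node_of[deg <= 1L] <- seq_len(endpoints)
  if (length(jpx)) {
    memb <- igraph::components(igraph::induced_subgraph(g, as.character(jpx)))$membership
    node_of[as.integer(names(memb))] <- endpoints + memb
  }
  ppx <- which(deg == 2L)
  chains <- if (length(ppx))
    igraph::components(igraph::induced_subgraph(g, as.character(ppx)))$no
  else 0L
  # direct adjacencies between pixels of two distinct nodes
  direct <- 0L
  if (!is.null(pairs)) {
    a <- node_of[pairs[, 1]]; b <- node_of[pairs[, 2]]
    both <- a > 0L & b > 0L & a != b
    if (any(both))
      direct <- length(unique(paste(pmin(a[both], b[both]),
                                    pmax(a[both], b[both]))))
  }
  list(endpoints = endpoints, junctions = junctions, edges = chains + direct)
}

# --- independent oracle: per-branch order by path enumeration on a tree ---
oracle_orders <- function(cs) {
  ne <- nrow(cs$edges)
  if (ne == 0L) return(integer(0))
  deg <- tabulate(c(cs$edges$node_a, cs$edges$node_b), nbins = nrow(cs$nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = cs$edges$node_a, to = cs$edges$node_b),
    directed = FALSE, vertices = data.frame(name = cs$nodes$id))
  vapply(seq_len(ne), function(e) {
    ends <- c(cs$edges$node_a[e], cs$edges$node_b[e])
    dists <- igraph::distances(g, v = as.character(cs$soma),
                               to = as.character(ends))
    prox <- ends[which.min(dists)]
    path <- igraph::shortest_paths(g, from = as.character(cs$soma),
                                   to = as.character(prox))$vpath[[1]]
    onpath <- as.integer(igraph::V(g)$name[as.integer(path)])
    onpath <- setdiff(onpath, cs$soma)
    1L + sum(deg[onpath] >= 3L)
  }, 1L)
}

# --- independent oracle: studentized range CDF by numerical integration ---
ptukey_numeric <- function(q, k, df) {
  inner <- function(x)
    k * vapply(x, function(z)
      stats::integrate(function(u)
        stats::dnorm(u) * (stats::pnorm(u) - stats::pnorm(u - z))^(k - 1),
        -Inf, Inf, rel.tol = 1e-10)$value, 0)
  if (is.infinite(df)) return(inner(q))
  fs <- function(s) 2 * (df / 2)^(df / 2) / gamma(df / 2) *
    s^(df - 1) * exp(-df * s^2 / 2)
  stats::integrate(function(s) fs(s) * inner(q * s), 0, Inf,
                   rel.tol = 1e-9, subdivisions = 400L)$value
}

# random small masks for property tests
random_mask <- function(nr, nc, p = 0.45) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
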