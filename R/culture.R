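#' Generate a synthetic astrocyte culture
#'
#' Grows `params$n_cells` branch trees on a 2-D field under the agent-based
#' tip-extension model described in [growth_params()]. Somata are placed by
#' rejection sampling at pairwise distance of at least `soma_min_spacing`.
#' The result is ground truth: every cell is a tree of (x, y) nodes with known
#' ownership, from which rasters, SWC files and morphometric tables can be
#' derived.
#'
#' Growth is incremental and nodes are only ever appended, so a run with fewer
#' steps is an exact prefix of a longer run with the same `(params, seed)`;
#' use [snapshot_culture()] to recover earlier developmental time points from
#' one simulation.
#'
#' @param params a [growth_params()] object.
#' @param seed integer random seed; the culture is a pure function of
#'   `(params, seed)`.
#' @return an object of class `astro_culture`: list with `cells` (each a
#'   data.frame of nodes `x`, `y`, `parent` (0 = soma), `born`), `somata`
#'   (n x 2 matrix), `params`, `seed`.
#' @export
generate_culture <- function(params, seed) {
  stopifnot(inherits(params, "growth_params"))
  validate_growth_params(params)
  seed <- as.integer(seed)
  set.seed(seed)

  somata <- place_somata(params)

  res <- .grow_culture_cpp(somata,
                           params$primaries_per_cell, params$step_length,
                           params$angle_noise_sd, params$branch_prob,
                           params$divergence_angle, params$avoid_radius,
                           params$n_candidate_dirs, params$n_steps,
                           params$repulsion, params$self_avoidance,
                           params$field_size[1], params$field_size[2],
                           2.0)

  cells <- vector("list", params$n_cells)
  for (c in seq_len(params$n_cells)) {
    idx <- which(res$cell == c)
    par_local <- match(res$parent[idx], idx)
    par_local[is.na(par_local)] <- 0L
    cells[[c]] <- data.frame(x = res$x[idx], y = res$y[idx],
                             parent = par_local, born = res$born[idx])
  }

  structure(list(cells = cells, somata = somata, params = params,
                 seed = seed),
            class = "astro_culture")
}

# Somata on a jittered grid (confluent-culture layout); the jitter is bounded
# so the pairwise spacing constraint holds by construction. Falls back to
# rejection sampling when the grid pitch cannot accommodate the spacing.
place_somata <- function(params) {
  w <- params$field_size[1]
  h <- params$field_size[2]
  s <- params$soma_min_spacing
  n <- params$n_cells
  margin <- min(s / 2, min(w, h) / 4)
  if (w - 2 * margin <= 0 || h - 2 * margin <= 0)
    stop("field too small for the requested soma_min_spacing")

  gx <- ceiling(sqrt(n))
  gy <- ceiling(n / gx)
  pitch_x <- (w - 2 * margin) / gx
  pitch_y <- (h - 2 * margin) / gy
  if (min(pitch_x, pitch_y) >= s) {
    jit <- (min(pitch_x, pitch_y) - s) / 2
    jit <- min(jit, 0.25 * min(pitch_x, pitch_y))
    cx <- margin + (rep(seq_len(gx), gy)[seq_len(n)] - 0.5) * pitch_x
    cy <- margin + (rep(seq_len(gy), each = gx)[seq_len(n)] - 0.5) * pitch_y
    pts <- cbind(x = cx + stats::runif(n, -jit, jit),
                 y = cy + stats::runif(n, -jit, jit))
    return(pts)
  }

  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("could not place %d somata at soma_min_spacing = %g",
                          " in a %g x %g field after %d attempts"),
                   n, s, w, h, max_attempts))
    cand <- c(stats::runif(1, margin, w - margin),
              stats::runif(1, margin, h - margin))
    if (placed == 0L ||
        min(sqrt((pts[seq_len(placed), 1] - cand[1])^2 +
                 (pts[seq_len(placed), 2] - cand[2])^2)) >= s) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Earlier developmental snapshot of a culture
#'
#' Because growth only appends nodes, the culture at step `step` is the subset
#' of nodes created up to that step, with identical topology and coordinates.
#'
#' @param culture an `astro_culture`.
#' @param step integer growth step (0 = somata only).
#' @return an `astro_culture` restricted to nodes born at or before `step`.
#' @export
snapshot_culture <- function(culture, step) {
  stopifnot(inherits(culture, "astro_culture"))
  out <- culture
  out$cells <- lapply(culture$cells, function(nd) {
    keep <- nd$born <= step
    # children are always born after parents, so keep is prefix-closed
    nd[keep, , drop = FALSE]
  })
  out$snapshot_step <- as.integer(step)
  out
}

#' Apply excitotoxic terminal-branch retraction
#'
#' Emulates the glutamate-excitotoxicity phenotype: over `rp$n_rounds` rounds
#' each terminal branch (the chain of nodes from a tip back to, but excluding,
#' the nearest branch point or the soma) is deleted independently with
#' probability `rp$terminal_prune_prob`. A branch point left with a single
#' child simply becomes a pass-through chain node, so adjacent branches fuse
#' in any subsequent branch decomposition. If `rp$exploration` is on,
#' each surviving tip then extends `rp$exploration_steps` short segments with
#' no avoidance test (neutral, territory-ignoring regrowth).
#'
#' With exploration off, total branch length, branch count and maximum branch
#' order are non-increasing for every cell.
#'
#' @param culture an `astro_culture`.
#' @param rp a [retraction_params()] object.
#' @param seed integer seed; deterministic given `(culture, rp, seed)`.
#' @return the perturbed `astro_culture`.
#' @export
apply_retraction <- function(culture, rp, seed) {
  stopifnot(inherits(culture, "astro_culture"),
            inherits(rp, "retraction_params"))
  if (length(culture$cells) == 0) stop("empty culture")
  set.seed(as.integer(seed))
  p <- culture$params

  out <- culture
  out$cells <- lapply(culture$cells, function(nd) {
    for (round in seq_len(rp$n_rounds)) {
      n <- nrow(nd)
      if (n <= 1L) break
      nchild <- tabulate(nd$parent[nd$parent > 0L], nbins = n)
      anchor <- nchild >= 2L
      anchor[1L] <- TRUE  # soma
      leaves <- which(nchild == 0L & seq_len(n) != 1L)
      if (length(leaves) == 0L) break
      drop <- rep(FALSE, n)
      for (lf in leaves) {
        prune <- stats::runif(1) < rp$terminal_prune_prob
        node <- lf
        while (!anchor[node]) {
          if (prune) drop[node] <- TRUE
          node <- nd$parent[node]
        }
      }
      if (any(drop)) {
        keep <- which(!drop)
        remap <- match(seq_len(n), keep)
        nd <- nd[keep, , drop = FALSE]
        pa <- nd$parent
        pa[pa > 0L] <- remap[pa[pa > 0L]]  # 0 (soma) stays 0
        nd$parent <- pa
        rownames(nd) <- NULL
      }
    }
    if (rp$exploration && rp$exploration_steps > 0L) {
      nd <- explore_tips(nd, p, rp$exploration_steps)
    }
    nd
  })
  out$retraction <- rp
  out
}

# neutral (non-avoiding) extension of every tip; stays inside the field
explore_tips <- function(nd, p, n_steps) {
  n <- nrow(nd)
  nchild <- tabulate(nd$parent[nd$parent > 0L], nbins = n)
  tips <- which(nchild == 0L & seq_len(n) != 1L)
  w <- p$field_size[1]; h <- p$field_size[2]; m <- 2
  maxborn <- if (n > 0) max(nd$born) else 0L
  for (t in tips) {
    heading <- if (nd$parent[t] > 0L) {
      atan2(nd$y[t] - nd$y[nd$parent[t]], nd$x[t] - nd$x[nd$parent[t]])
    } else stats::runif(1, 0, 2 * pi)
    cur <- t
    for (s in seq_len(n_steps)) {
      heading <- heading + stats::rnorm(1, 0, p$angle_noise_sd)
      nx <- nd$x[cur] + p$step_length * cos(heading)
      ny <- nd$y[cur] + p$step_length * sin(heading)
      if (nx < m || nx > w - m || ny < m || ny > h - m) break
      nd <- rbind(nd, data.frame(x = nx, y = ny, parent = cur,
                                 born = maxborn + s))
      cur <- nrow(nd)
    }
  }
  rownames(nd) <- NULL
  nd
}

#' @export
print.astro_culture <- function(x, ...) {
  nseg <- sum(vapply(x$cells, function(nd) max(nrow(nd) - 1L, 0L), 1L))
  cat(sprintf("Synthetic astrocyte culture: %d cells, %d segments, %g x %g field\n",
              length(x$cells), nseg, x$params$field_size[1],
              x$params$field_size[2]))
  cat(sprintf("  regime: %s, seed %d%s%s\n",
              if (x$params$repulsion) "repulsive (tiled)" else "neutral",
              x$seed,
              if (!is.null(x$snapshot_step))
                sprintf(", snapshot at step %d", x$snapshot_step) else "",
              if (!is.null(x$retraction)) ", retraction applied" else ""))
  invisible(x)
}

#' @export
summary.astro_culture <- function(object, ...) {
  sk <- culture_to_skeletons(object)
  m <- culture_metrics(sk)
  cat(sprintf("Culture of %d cells\n", length(object$cells)))
  print(m)
  invisible(m)
}

#' @export
plot.astro_culture <- function(x, col = NULL, asp = 1, ...) {
  if (is.null(col))
    col <- grDevices::hcl.colors(max(length(x$cells), 3), "Dark 3")
  plot(NA, xlim = c(0, x$params$field_size[1]),
       ylim = c(0, x$params$field_size[2]), asp = asp,
       xlab = "x (px)", ylab = "y (px)", ...)
  for (c in seq_along(x$cells)) {
    nd <- x$cells[[c]]
    has_par <- nd$parent > 0L
    segments(nd$x[nd$parent[has_par]], nd$y[nd$parent[has_par]],
             nd$x[has_par], nd$y[has_par], col = col[c])
  }
  points(x$somata, pch = 16, col = col[seq_along(x$cells)])
  invisible(x)
}

#' Convert ground-truth trees to skeleton form
#'
#' Decomposes every cell's node tree into branches (maximal chains between the
#' soma, branch points with two or more children, and tips) and packages them
#' as [cell_skeleton] objects in the shared (row, col) coordinate convention
#' (row = y, col = x), so the same morphometry and tiling code runs on ground
#' truth and on image-derived skeletons alike.
#'
#' @param culture an `astro_culture`.
#' @return a list of `cell_skeleton` objects.
#' @export
culture_to_skeletons <- function(culture) {
  stopifnot(inherits(culture, "astro_culture"))
  lapply(seq_along(culture$cells), function(c)
    tree_to_skeleton(culture$cells[[c]], cell_id = c))
}

# node tree (x, y, parent) -> cell_skeleton (branch graph)
tree_to_skeleton <- function(nd, cell_id) {
  n <- nrow(nd)
  row <- nd$y
  col <- nd$x
  if (n == 1L) {
    nodes <- data.frame(id = 1L, row = row, col = col, kind = "soma",
                        stringsAsFactors = FALSE)
    return(new_cell_skeleton(cell_id, nodes, soma = 1L,
                             edges = data.frame(edge = integer(0),
                                                node_a = integer(0),
                                                node_b = integer(0),
                                                length = numeric(0)),
                             polylines = list()))
  }
  nchild <- tabulate(nd$parent[nd$parent > 0L], nbins = n)
  is_gnode <- nchild >= 2L | nchild == 0L
  is_gnode[1L] <- TRUE
  anchor <- nchild >= 2L
  anchor[1L] <- TRUE

  # branch membership: a node opens a new branch when its parent is an anchor
  branch_id <- integer(n)
  nb <- 0L
  for (i in 2:n) {
    pa <- nd$parent[i]
    if (anchor[pa]) {
      nb <- nb + 1L
      branch_id[i] <- nb
    } else {
      branch_id[i] <- branch_id[pa]
    }
  }

  gid <- cumsum(is_gnode)            # tree node -> skeleton node id
  kinds <- ifelse(seq_len(n) == 1L, "soma",
                  ifelse(nchild >= 2L, "junction", "endpoint"))
  gnodes <- which(is_gnode)
  nodes <- data.frame(id = seq_along(gnodes), row = row[gnodes],
                      col = col[gnodes], kind = kinds[gnodes],
                      stringsAsFactors = FALSE)

  members <- split(seq_len(n)[branch_id > 0L], branch_id[branch_id > 0L])
  polylines <- vector("list", length(members))
  node_a <- node_b <- integer(length(members))
  len <- numeric(length(members))
  for (b in seq_along(members)) {
    mem <- members[[b]]
    a <- nd$parent[mem[1L]]
    chain <- c(a, mem)
    poly <- cbind(row = row[chain], col = col[chain])
    polylines[[b]] <- poly
    node_a[b] <- gid[a]
    node_b[b] <- gid[mem[length(mem)]]
    len[b] <- polyline_length(poly)
  }
  edges <- data.frame(edge = seq_along(members), node_a = node_a,
                      node_b = node_b, length = len)
  new_cell_skeleton(cell_id, nodes, soma = 1L, edges = edges,
                    polylines = polylines)
}

polyline_length <- function(poly) {
  if (nrow(poly) < 2L) return(0)
  sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))
}

new_cell_skeleton <- function(cell_id, nodes, soma, edges, polylines) {
  structure(list(cell_id = cell_id, nodes = nodes, soma = soma,
                 edges = edges, polylines = polylines),
            class = "cell_skeleton")
}

#' @export
print.cell_skeleton <- function(x, ...) {
  cat(sprintf("Cell skeleton %s: %d nodes, %d branches, total length %.1f px\n",
              as.character(x$cell_id), nrow(x$nodes), nrow(x$edges),
              sum(x$edges$length)))
  invisible(x)
}

#' Rasterize a polyline to pixel coordinates
#'
#' Samples each segment densely, rounds to the 0-based pixel grid and removes
#' duplicates. Used to put continuous ground-truth branches and image-derived
#' pixel branches on the same footing.
#'
#' @param poly numeric matrix with columns (row, col).
#' @return integer matrix of unique pixels, columns (row, col).
#' @keywords internal
rasterize_polyline <- function(poly) {
  if (nrow(poly) == 0L) return(matrix(integer(0), 0, 2))
  if (nrow(poly) == 1L)
    return(matrix(as.integer(round(poly)), 1, 2,
                  dimnames = list(NULL, c("row", "col"))))
  r <- poly[, 1]; c <- poly[, 2]
  steps <- sqrt(diff(r)^2 + diff(c)^2)
  rs <- cs <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    k <- max(2L, ceiling(steps[i] / 0.4) + 1L)
    t <- seq(0, 1, length.out = k)
    rs[[i]] <- r[i] + t * (r[i + 1] - r[i])
    cs[[i]] <- c[i] + t * (c[i + 1] - c[i])
  }
  pr <- as.integer(round(unlist(rs)))
  pc <- as.integer(round(unlist(cs)))
  keep <- !duplicated(pr * 2147483L + pc)
  cbind(row = pr[keep], col = pc[keep])
}
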