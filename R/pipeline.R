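#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by
#' [simulate_experiment()] and [analyze_experiment()]. Unknown keys are
#' rejected by name, so typos fail before any stage runs. All randomness
#' flows from the single root `seed`, split per stage by
#' [derive_seed()] (documented multiplicative scheme), so a configuration is
#' fully reproducible.
#'
#' @param seed root integer seed.
#' @param out_dir output directory.
#' @param preset growth preset name passed to [growth_preset()].
#' @param growth named list of [growth_params()] overrides.
#' @param conditions named list of condition blocks; each may contain a
#'   `retraction` list of [retraction_params()] arguments (or be an empty
#'   list for an unperturbed condition).
#' @param timepoints named vector of growth steps at which snapshots are
#'   taken; defaults to the full run labelled `"final"`.
#' @param render list of [render_image()] arguments (`line_width`,
#'   `noise_sd`, `background`, `foreground`) or `NULL` to skip rasters.
#' @param epsilon Chebyshev radius for [detect_violations()].
#' @param threshold binarization threshold; `NULL` selects Otsu.
#' @param alpha significance level for post-hoc comparisons.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir = NULL, preset = "tiled-DIV15",
                            growth = list(), conditions = list(control = list()),
                            timepoints = NULL, render = NULL, epsilon = 1,
                            threshold = NULL, alpha = 0.05) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, preset = preset,
              growth = growth, conditions = conditions,
              timepoints = timepoints, render = render, epsilon = epsilon,
              threshold = threshold, alpha = alpha)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  known <- c("seed", "out_dir", "preset", "growth", "conditions",
             "timepoints", "render", "epsilon", "threshold", "alpha")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  gknown <- names(formals(growth_params))
  gex <- setdiff(names(cfg$growth), gknown)
  if (length(gex))
    stop(sprintf("unknown growth key(s): %s", paste(gex, collapse = ", ")))
  rknown <- names(formals(retraction_params))
  for (cn in names(cfg$conditions)) {
    cond <- cfg$conditions[[cn]]
    cex <- setdiff(names(cond), "retraction")
    if (length(cex))
      stop(sprintf("unknown condition key(s) in '%s': %s", cn,
                   paste(cex, collapse = ", ")))
    rex <- setdiff(names(cond$retraction), rknown)
    if (length(rex))
      stop(sprintf("unknown retraction key(s) in '%s': %s", cn,
                   paste(rex, collapse = ", ")))
  }
  if (!is.null(cfg$render)) {
    rex <- setdiff(names(cfg$render),
                   c("line_width", "noise_sd", "background", "foreground"))
    if (length(rex))
      stop(sprintf("unknown render key(s): %s", paste(rex, collapse = ", ")))
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("config needs a seed")
  stopifnot(cfg$epsilon >= 0, cfg$alpha > 0, cfg$alpha < 1)
  invisible(cfg)
}

#' Derive a stage seed from the root seed
#'
#' Multiplicative congruential split: `(seed * 48271 + stage) mod (2^31 - 1)`,
#' mapped away from 0. Keeps every stage seed a valid 32-bit integer.
#'
#' @param seed root seed.
#' @param stage small non-negative integer identifying the stage.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + stage
  as.integer(s %% m) + 1L
}

#' Run the synthetic-experiment stage
#'
#' Generates the base culture from the configured preset, takes the configured
#' snapshots, applies per-condition retraction, and writes SWC trees (one file
#' per cell), soma seed CSVs, optional TIFF renders, a ground-truth metrics
#' CSV and a manifest JSON recording the seed and full parameter set.
#'
#' @param config a [pipeline_config()].
#' @param force overwrite a non-empty output directory.
#' @return invisibly, a list of per-(condition, timepoint) output directories.
#' @export
simulate_experiment <- function(config, force = FALSE) {
  validate_config(config)
  out <- config$out_dir
  if (is.null(out)) stop("config$out_dir is required to simulate")
  if (dir.exists(out) && length(list.files(out)) > 0 && !force)
    stop(sprintf("output dir '%s' exists and is not empty (use force = TRUE)",
                 out))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  params <- do.call(growth_preset, c(list(name = config$preset), config$growth))
  culture <- generate_culture(params, derive_seed(config$seed, 1L))
  tps <- config$timepoints
  if (is.null(tps)) tps <- stats::setNames(params$n_steps, "final")

  made <- list()
  for (cn in names(config$conditions)) {
    cond <- config$conditions[[cn]]
    for (tn in names(tps)) {
      cult <- snapshot_culture(culture, tps[[tn]])
      if (!is.null(cond$retraction)) {
        rp <- do.call(retraction_params, cond$retraction)
        cult <- apply_retraction(cult, rp,
                                 derive_seed(config$seed, 100L + match(cn, names(config$conditions))))
      }
      d <- file.path(out, cn, tn)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      lw <- if (is.null(config$render$line_width)) 3 else config$render$line_width
      write_swc(cult, d, line_width = lw)
      write_soma_csv(cult, file.path(d, "somata.csv"))
      gt <- culture_metrics(culture_to_skeletons(cult))
      utils::write.csv(gt, file.path(d, "ground_truth_metrics.csv"),
                       row.names = FALSE)
      if (!is.null(config$render)) {
        rr <- do.call(render_image,
                      c(list(culture = cult,
                             seed = derive_seed(config$seed, 200L)),
                        config$render))
        write_image_tiff(rr$image, file.path(d, "image.tif"))
        write_image_tiff(rr$labels, file.path(d, "labels.tif"))
      }
      made[[paste(cn, tn, sep = "/")]] <- d
    }
  }
  manifest <- list(seed = config$seed, preset = config$preset,
                   params = unclass(params),
                   param_hash = fnv1a(deparse(unclass(params))),
                   conditions = config$conditions,
                   timepoints = as.list(tps))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(made)
}

# polynomial string hash (parameter fingerprinting for the manifest)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Analyze one experiment directory
#'
#' Consumes either the SWC trees written by [simulate_experiment()] (the
#' image stages are skipped and ground-truth geometry is used directly) or a
#' rendered TIFF plus soma seed CSV, in which case the full image pipeline
#' runs: binarize, skeletonize, extract the skeleton graph, assign cells by
#' geodesic soma distance. Either way it computes per-cell morphometrics,
#' order histograms and the tiling-violation report, and writes them as CSV
#' (plus a JSON violation summary) when `out_dir` is given.
#'
#' @param dir directory containing `cell_*.swc`, or `image.tif` +
#'   `somata.csv`.
#' @param epsilon Chebyshev radius for [detect_violations()].
#' @param threshold binarization threshold; `NULL` uses Otsu.
#' @param out_dir optional output directory for the CSV tables.
#' @param prefer `"swc"` or `"image"` when a directory offers both.
#' @return list with `metrics`, `orders`, `violations` (a
#'   `violation_report`), `cells`.
#' @export
analyze_experiment <- function(dir, epsilon = 1, threshold = NULL,
                               out_dir = NULL, prefer = c("swc", "image")) {
  prefer <- match.arg(prefer)
  swcs <- list.files(dir, pattern = "^cell_.*\\.swc$", full.names = TRUE)
  has_img <- file.exists(file.path(dir, "image.tif")) &&
             file.exists(file.path(dir, "somata.csv"))
  use_swc <- length(swcs) > 0 && (prefer == "swc" || !has_img)
  if (use_swc) {
    culture <- read_swc(sort(swcs))
    cells <- culture_to_skeletons(culture)
  } else {
    if (!has_img) stop(sprintf("'%s' has neither SWC files nor image.tif + somata.csv", dir))
    img <- read_image_tiff(file.path(dir, "image.tif"))
    somata <- read_soma_csv(file.path(dir, "somata.csv"))
    cells <- cells_from_image(img, somata, threshold = threshold)
  }
  res <- analyze_skeletons(cells, epsilon = epsilon)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$orders, file.path(out_dir, "order_histogram.csv"),
                     row.names = FALSE)
    utils::write.csv(res$edges, file.path(out_dir, "edges.csv"),
                     row.names = FALSE)
    utils::write.csv(res$violations$branches,
                     file.path(out_dir, "violations_branch.csv"),
                     row.names = FALSE)
    utils::write.csv(res$violations$per_cell,
                     file.path(out_dir, "violations_cell.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$violations$per_culture,
                         file.path(out_dir, "violation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Image to cells: the full image-analysis chain
#'
#' @param img numeric intensity matrix.
#' @param somata soma seed data.frame (`cell_id`, `row`, `col`).
#' @param threshold fixed binarization threshold, or `NULL` for Otsu.
#' @param prune_terminal drop terminal edges shorter than this many pixels
#'   (deterministic stand-in for manual skeleton cleanup); 0 disables.
#' @return list of `cell_skeleton` objects.
#' @export
cells_from_image <- function(img, somata, threshold = NULL,
                             prune_terminal = 3) {
  bin <- if (is.null(threshold)) binarize(img, "otsu")
         else binarize(img, "fixed", threshold)
  if (!any(bin$mask)) {
    warning("empty image: no foreground pixels above the threshold")
    return(list())
  }
  skel <- skeletonize_mask(bin$mask)
  skel <- prune_spurs(skel, min_len = prune_terminal)
  graph <- extract_graph(skel)
  assign_cells(graph, somata)$cells
}

#' Remove short terminal spurs from a skeleton, at the pixel level
#'
#' Thinning a wide line produces short side spurs whose junction pixels
#' swallow centerline length. This removes the pixels of terminal edges
#' shorter than `min_len` (keeping junction-cluster pixels), re-thins, and
#' repeats until stable — the deterministic stand-in for manual skeleton
#' cleanup.
#'
#' @param skel logical skeleton matrix.
#' @param min_len minimum terminal edge length in pixels; 0 disables.
#' @param max_iter safety bound on despurring passes.
#' @return the cleaned logical skeleton matrix.
#' @export
prune_spurs <- function(skel, min_len = 3, max_iter = 5) {
  if (min_len <= 0) return(skel)
  nr <- nrow(skel)
  for (it in seq_len(max_iter)) {
    g <- extract_graph(skel)
    if (nrow(g$edges) == 0L) return(skel)
    deg <- tabulate(c(g$edges$node_a, g$edges$node_b), nbins = nrow(g$nodes))
    is_end <- g$nodes$kind == "endpoint"
    short <- which(g$edges$length < min_len &
                   ((is_end[g$edges$node_a] & deg[g$edges$node_a] == 1L) |
                    (is_end[g$edges$node_b] & deg[g$edges$node_b] == 1L)))
    if (length(short) == 0L) return(skel)
    junction_px <- do.call(rbind, g$node_pixels[g$nodes$kind == "junction"])
    jset <- if (is.null(junction_px)) numeric(0) else
      junction_px[, 2] * nr + junction_px[, 1]
    for (e in short) {
      poly <- g$polylines[[e]]
      # drop the spur's pixels except junction-cluster pixels, which carry
      # the surviving branches
      key <- poly[, 2] * nr + poly[, 1]
      drop <- !(key %in% jset)
      skel[poly[drop, 1] + 1L + poly[drop, 2] * nr] <- FALSE
    }
    skel <- skeletonize_mask(skel)
  }
  skel
}

#' Drop short terminal edges from a skeleton graph
#'
#' Removes edges shorter than `min_len` whose far end is an endpoint node — a
#' deterministic replacement for manual skeleton editing. Nodes left without
#' edges are kept (they become zero-length components).
#'
#' @param graph a `skeleton_graph`.
#' @param min_len minimum terminal edge length in pixels; 0 disables.
#' @return the pruned `skeleton_graph`.
#' @export
prune_short_terminals <- function(graph, min_len = 3) {
  if (min_len <= 0 || nrow(graph$edges) == 0L) return(graph)
  deg <- tabulate(c(graph$edges$node_a, graph$edges$node_b),
                  nbins = nrow(graph$nodes))
  is_end <- graph$nodes$kind == "endpoint"
  drop <- graph$edges$length < min_len &
          ((is_end[graph$edges$node_a] & deg[graph$edges$node_a] == 1L) |
           (is_end[graph$edges$node_b] & deg[graph$edges$node_b] == 1L))
  if (!any(drop)) return(graph)
  keep <- which(!drop)
  graph$edges <- graph$edges[keep, , drop = FALSE]
  graph$polylines <- graph$polylines[keep]
  graph$edges$edge <- seq_len(nrow(graph$edges))
  rownames(graph$edges) <- NULL
  graph$pixels$edge <- 0L
  for (e in seq_along(graph$polylines)) {
    poly <- graph$polylines[[e]]
    if (nrow(poly) > 2L) {
      interior <- poly[2:(nrow(poly) - 1L), , drop = FALSE]
      m <- match(interior[, 1] * 2147483 + interior[, 2],
                 graph$pixels$row * 2147483 + graph$pixels$col)
      graph$pixels$edge[m] <- e
    }
  }
  graph
}

#' Core per-directory analysis on assembled cells
#'
#' @param cells list of `cell_skeleton` objects.
#' @param epsilon Chebyshev radius for [detect_violations()].
#' @return list with `metrics` (per-cell data.frame), `orders` (long
#'   histogram), `violations` (a `violation_report`), `cells`.
#' @export
analyze_skeletons <- function(cells, epsilon = 1) {
  list(metrics = culture_metrics(cells),
       orders = order_histogram(cells),
       edges = edge_table(cells),
       violations = detect_violations(cells, epsilon = epsilon),
       cells = cells)
}

# per-branch edge list across cells: cell_id, branch, node_a, node_b, length,
# order (the CSV graph dump)
edge_table <- function(cells) {
  rows <- lapply(cells, function(cs) {
    if (nrow(cs$edges) == 0L)
      return(NULL)
    o <- branch_orders(cs)
    data.frame(cell_id = cs$cell_id, branch = cs$edges$edge,
               node_a = cs$edges$node_a, node_b = cs$edges$node_b,
               length = cs$edges$length, order = as.integer(o))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), branch = integer(0),
                      node_a = integer(0), node_b = integer(0),
                      length = numeric(0), order = integer(0))
  out
}
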