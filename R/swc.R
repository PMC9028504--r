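#' Write a culture as SWC files, one per cell
#'
#' SWC is the standard interchange format for tree morphologies: one node per
#' line with `id type x y z radius parent`. The soma node carries type code 1,
#' branch nodes type 0 (undefined); z is 0 for these planar cultures and the
#' radius column is fixed at `line_width / 2`. Coordinates are written as
#' `x = col`, `y = row` with full `%.17g` precision, so a write/read round
#' trip reproduces every node coordinate and the tree topology exactly.
#'
#' @param culture an `astro_culture`.
#' @param dir output directory (created if needed).
#' @param line_width brush width used for the radius column.
#' @return invisibly, the vector of file paths (`cell_001.swc`, ...).
#' @export
write_swc <- function(culture, dir, line_width = 3) {
  stopifnot(inherits(culture, "astro_culture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(culture$cells))
  for (c in seq_along(culture$cells)) {
    nd <- culture$cells[[c]]
    paths[c] <- file.path(dir, sprintf("cell_%03d.swc", c))
    lines <- sprintf("%d %d %s %s 0 %s %d",
                     seq_len(nrow(nd)),
                     ifelse(nd$parent == 0L, 1L, 0L),
                     sprintf("%.17g", nd$x), sprintf("%.17g", nd$y),
                     sprintf("%.17g", line_width / 2),
                     ifelse(nd$parent == 0L, -1L, nd$parent))
    writeLines(c("# SWC export: id type x y z radius parent", lines),
               paths[c])
  }
  invisible(paths)
}

#' Read SWC files back into a culture
#'
#' Inverse of [write_swc()]. Each file becomes one cell; the type-1 node is
#' the soma and must be the tree root.
#'
#' @param paths character vector of SWC files (or a directory containing
#'   `*.swc`).
#' @param params optional [growth_params()] to attach as provenance (field
#'   size defaults to the bounding box plus a margin when absent).
#' @return an `astro_culture`.
#' @export
read_swc <- function(paths, params = NULL) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.swc$", full.names = TRUE))
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) stop("no SWC files found")
  cells <- lapply(paths, function(p) {
    tab <- utils::read.table(p, comment.char = "#",
                             col.names = c("id", "type", "x", "y", "z",
                                           "radius", "parent"))
    tab <- tab[order(tab$id), , drop = FALSE]
    if (any(tab$id != seq_len(nrow(tab))))
      stop(sprintf("%s: SWC node ids must be 1..n", p))
    root <- which(tab$parent == -1L)
    if (length(root) != 1L || root != 1L || tab$type[1L] != 1L)
      stop(sprintf("%s: expected a single type-1 root as first node", p))
    if (any(tab$parent[-1L] >= tab$id[-1L]))
      stop(sprintf("%s: parents must precede children", p))
    data.frame(x = tab$x, y = tab$y,
               parent = ifelse(tab$parent == -1L, 0L, tab$parent),
               born = c(0L, seq_len(nrow(tab) - 1L)))
  })
  somata <- do.call(rbind, lapply(cells, function(nd) c(nd$x[1], nd$y[1])))
  colnames(somata) <- c("x", "y")
  if (is.null(params)) {
    allx <- unlist(lapply(cells, `[[`, "x"))
    ally <- unlist(lapply(cells, `[[`, "y"))
    params <- growth_params(n_cells = length(cells),
                            field_size = c(ceiling(max(allx)) + 3,
                                           ceiling(max(ally)) + 3),
                            soma_min_spacing = 1)
  }
  structure(list(cells = cells, somata = somata, params = params,
                 seed = NA_integer_),
            class = "astro_culture")
}

#' Soma seed CSV helpers
#'
#' Writes and reads the `cell_id,row,col` seed files consumed by the image
#' analysis pipeline (0-based pixel coordinates).
#'
#' @param culture an `astro_culture`.
#' @param path CSV path.
#' @return `write_soma_csv`: the path, invisibly. `read_soma_csv`: a
#'   data.frame with `cell_id`, `row`, `col`.
#' @export
write_soma_csv <- function(culture, path) {
  df <- data.frame(cell_id = seq_along(culture$cells),
                   row = culture$somata[, "y"], col = culture$somata[, "x"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_soma_csv
#' @export
read_soma_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "row", "col") %in% names(df)))
  df
}
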