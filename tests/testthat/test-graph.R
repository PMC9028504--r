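path_mask <- function(pixels, nr = 16, nc = 16) {
  m <- matrix(FALSE, nr, nc)
  m[pixels] <- TRUE
  m
}

test_that("a straight 10-pixel path gives 2 endpoints, 1 edge, length 9", {
  m <- matrix(FALSE, 5, 14)
  m[3, 3:12] <- TRUE
  g <- extract_graph(m)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length, 9)
})

test_that("a 10-pixel diagonal uses the sqrt(2) step convention", {
  m <- matrix(FALSE, 14, 14)
  for (i in 1:10) m[i + 2, i + 2] <- TRUE
  g <- extract_graph(m)
  expect_equal(g$edges$length, 9 * sqrt(2))
})

test_that("a hand-drawn Y decomposes into the enumerated branches", {
  # stem: 5 orthogonal steps; arms: 4 diagonal steps each
  m <- matrix(FALSE, 20, 20)
  m[10, 3:8] <- TRUE                       # stem, 6 px
  for (i in 1:4) m[10 - i, 8 + i] <- TRUE  # arm up
  for (i in 1:4) m[10 + i, 8 + i] <- TRUE  # arm down
  g <- extract_graph(m)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(sort(g$edges$length), sort(c(5, 4 * sqrt(2), 4 * sqrt(2))))
  expect_equal(sum(g$edges$length), 5 + 8 * sqrt(2))
})

test_that("isolated pixels become zero-length single-node components", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[5, 5] <- TRUE
  g <- extract_graph(m)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 0L)
})

test_that("pixel conservation: every pixel is in exactly one node or edge interior", {
  set.seed(11)
  for (rep in 1:40) {
    s <- skeletonize_mask(random_mask(10, 10, 0.5))
    g <- extract_graph(s)
    node_px <- sum(vapply(g$node_pixels, nrow, 1L))
    interior_px <- sum(vapply(g$polylines, function(p) max(nrow(p) - 2L, 0L), 1L))
    expect_equal(node_px + interior_px, sum(s))
  }
})

test_that("non-thin input is rejected", {
  m <- matrix(TRUE, 3, 5)
  expect_error(extract_graph(m), "not one pixel wide")
  m2 <- matrix(FALSE, 6, 6)
  m2[2:4, 2:4] <- TRUE  # filled 3x3 blob
  expect_error(extract_graph(m2), "not one pixel wide")
  m3 <- matrix(FALSE, 6, 8)
  m3[3:4, 2:6] <- TRUE  # 2-px-wide bar
  expect_error(extract_graph(m3), "not one pixel wide")
})

test_that("an even-width X crossing resolves to a fused junction cluster", {
  m <- matrix(FALSE, 12, 12)
  for (i in 1:4) {
    m[6 - i, 6 - i] <- TRUE; m[6 - i, 7 + i] <- TRUE
    m[7 + i, 6 - i] <- TRUE; m[7 + i, 7 + i] <- TRUE
  }
  m[6:7, 6:7] <- TRUE  # irreducible 2x2 plateau, all junction pixels
  g <- extract_graph(m)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4L)
  expect_equal(nrow(g$edges), 4L)
})

test_that("extract_graph matches neighbour-count classification on random masks", {
  set.seed(2024)
  for (rep in 1:400) {
    s <- skeletonize_mask(random_mask(7, 7, runif(1, 0.25, 0.75)))
    g <- extract_graph(s)
    o <- oracle_graph_counts(s)
    expect_equal(sum(g$nodes$kind == "endpoint"), o$endpoints)
    expect_equal(sum(g$nodes$kind == "junction"), o$junctions)
    expect_equal(nrow(g$edges), o$edges)
  }
})

test_that("pure cycles become a single self-loop edge", {
  # diamond ring of 8 pixels, every pixel with exactly two diagonal neighbours
  m <- matrix(FALSE, 10, 10)
  ring <- rbind(c(3, 5), c(4, 6), c(5, 7), c(6, 6),
                c(7, 5), c(6, 4), c(5, 3), c(4, 4))
  m[ring] <- TRUE
  g <- extract_graph(m)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$node_a, g$edges$node_b)
  expect_equal(sum(g$nodes$kind == "loop"), 1L)
  expect_equal(g$edges$length, 8 * sqrt(2))
})
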