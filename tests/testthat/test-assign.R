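test_that("one soma claims a fully connected skeleton", {
  m <- matrix(FALSE, 20, 20)
  m[10, 3:17] <- TRUE
  for (i in 1:5) m[10 - i, 10 + i] <- TRUE
  g <- extract_graph(m)
  asg <- assign_cells(g, data.frame(cell_id = 1, row = 9, col = 2))
  expect_equal(length(asg$cells), 1L)
  expect_equal(nrow(asg$unassigned), 0L)
  expect_equal(nrow(asg$cells[[1]]$edges), nrow(asg$graph$edges))
})

test_that("two disjoint components split by component membership", {
  m <- matrix(FALSE, 20, 30)
  m[5, 3:12] <- TRUE
  m[15, 18:27] <- TRUE
  g <- extract_graph(m)
  asg <- assign_cells(g, data.frame(cell_id = c(1, 2), row = c(4, 14),
                                    col = c(4, 20)))
  expect_equal(sum(asg$cells[[1]]$edges$length), 9)
  expect_equal(sum(asg$cells[[2]]$edges$length), 9)
  expect_equal(nrow(asg$unassigned), 0L)
})

test_that("soma falling mid-edge splits the edge and becomes a node", {
  m <- matrix(FALSE, 10, 22)
  m[5, 2:20] <- TRUE
  g <- extract_graph(m)
  asg <- assign_cells(g, data.frame(cell_id = 1, row = 4, col = 10))
  cs <- asg$cells[[1]]
  expect_equal(nrow(cs$edges), 2L)
  expect_equal(cs$nodes$kind[cs$soma], "soma")
  expect_equal(sum(cs$edges$length), 18)
})

test_that("soma seed constraints are enforced", {
  m <- matrix(FALSE, 20, 20)
  m[10, 3:17] <- TRUE
  g <- extract_graph(m)
  expect_error(assign_cells(g, data.frame(cell_id = 1, row = 2, col = 2)),
               "farther than")
  expect_error(
    assign_cells(g, data.frame(cell_id = c(1, 2), row = c(9, 8),
                               col = c(2, 2))),
    "same skeleton node")
  expect_error(
    assign_cells(g, data.frame(cell_id = c(1, 1), row = c(9, 9),
                               col = c(2, 16))),
    "duplicate cell ids")
})

test_that("assignment follows geodesic, not Euclidean, distance", {
  # a long branch of cell 1 threads close to soma 2 but stays connected to 1
  m <- matrix(FALSE, 30, 40)
  m[10, 3:35] <- TRUE            # cell 1: long horizontal branch
  m[12:25, 4] <- TRUE            # cell 1's soma arm (soma at bottom)
  m[11, 4] <- TRUE
  m[12:25, 34] <- TRUE           # cell 2's component near the branch tip
  m[11, 34] <- TRUE
  g <- extract_graph(m)
  # break the skeleton so cell 2 is its own component
  m2 <- m; m2[11, 34] <- FALSE
  g2 <- extract_graph(m2)
  asg <- assign_cells(g2, data.frame(cell_id = c(1, 2), row = c(20, 20),
                                     col = c(3, 33)))
  # the horizontal branch is Euclid-close to soma 2 but geodesically cell 1's
  horiz <- which(vapply(seq_len(nrow(asg$graph$edges)), function(e)
    any(asg$graph$polylines[[e]][, 1] == 9), TRUE))
  expect_true(all(asg$assignment$cell[horiz] == 1L))
})

test_that("ground-truth ownership is recovered on a rendered culture", {
  p <- growth_preset("tiled-DIV15", n_cells = 4, field_size = c(420, 420),
                     soma_min_spacing = 130, n_steps = 50, avoid_radius = 8,
                     step_length = 6, branch_prob = 0.35, angle_noise_sd = 0.3)
  cu <- generate_culture(p, 5)
  rr <- render_image(cu, line_width = 1, noise_sd = 0)
  somata <- data.frame(cell_id = seq_along(cu$cells),
                       row = cu$somata[, "y"], col = cu$somata[, "x"])
  g <- extract_graph(skeletonize_mask(rr$labels != 0L))
  asg <- assign_cells(g, somata)
  nrl <- nrow(rr$labels)
  agree <- total <- 0
  for (i in seq_along(asg$cells)) {
    cs <- asg$cells[[i]]
    for (b in seq_along(cs$polylines)) {
      px <- cs$polylines[[b]]
      owners <- rr$labels[px[, 2] * nrl + px[, 1] + 1L]
      len <- cs$edges$length[b]
      total <- total + len
      if (mean(owners == i | owners == 65535L) > 0.5) agree <- agree + len
    }
  }
  expect_gt(agree / total, 0.95)
})
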