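test_that("a single unbranched edge has order 1", {
  cu <- tree_culture(list(data.frame(x = c(5, 7, 9), y = 5,
                                     parent = c(0L, 1L, 2L), born = 0:2)))
  cs <- culture_to_skeletons(cu)[[1]]
  o <- branch_orders(cs)
  expect_equal(as.integer(o), 1L)
  expect_equal(cell_metrics(cs)$max_order, 1L)
})

test_that("Y-tree orders match the path-enumeration oracle", {
  cs <- culture_to_skeletons(tree_culture(list(y_tree(3, 3))))[[1]]
  o <- branch_orders(cs)
  expect_equal(sort(as.integer(o)), c(1L, 2L, 2L))
  expect_equal(as.integer(o), oracle_orders(cs))
})

test_that("orders agree with the oracle on random grown cultures", {
  for (s in 1:4) {
    cu <- generate_culture(small_tiled_params(n_steps = 35), s)
    for (cs in culture_to_skeletons(cu)) {
      o <- branch_orders(cs)
      expect_equal(as.integer(o), oracle_orders(cs))
      # conservation: per-order counts sum to the edge count
      m <- cell_metrics(cs)
      expect_equal(sum(m$order_histogram), m$branch_count)
      # monotonicity: orders along every soma-to-tip geodesic are 1..k
      expect_true(all(sort(unique(o)) == seq_len(max(o))))
    }
  }
})

test_that("order increments only at junctions along each root-to-tip path", {
  # chain -> junction -> two arms, one arm has a further junction
  nd <- y_tree(stem = 4, arm = 3)
  extra <- data.frame(x = c(-3.5, -4.5), y = c(15, 16),
                      parent = c(7L, 11L), born = 0L)
  nd2 <- rbind(nd, extra)
  cs <- culture_to_skeletons(tree_culture(list(nd2), field = c(300, 300)))[[1]]
  o <- branch_orders(cs)
  expect_equal(as.integer(o), oracle_orders(cs))
  expect_equal(max(o), 3L)
})

test_that("cell metrics match the worked single-branch example", {
  nd <- data.frame(x = seq(2, 11), y = 5, parent = c(0L, 1:9), born = 0:9)
  cs <- culture_to_skeletons(tree_culture(list(nd), field = c(40, 20)))[[1]]
  m <- cell_metrics(cs)
  expect_equal(m$branch_count, 1L)
  expect_equal(m$total_length, 9)
  expect_equal(m$bounding_rect_area, 1 * 10)
})

test_that("Y-tree metrics sum the oracle edge lengths", {
  cs <- culture_to_skeletons(tree_culture(list(y_tree(3, 3))))[[1]]
  m <- cell_metrics(cs)
  expect_equal(m$branch_count, 3L)
  expect_equal(m$total_length, 6 + 12 * sqrt(2), tolerance = 1e-9)
})

test_that("bounding rectangle area is invariant under 90-degree rotation", {
  cu <- generate_culture(small_tiled_params(n_steps = 30), 12)
  rot <- cu
  w <- cu$params$field_size[1]
  rot$cells <- lapply(cu$cells, function(nd) {
    data.frame(x = nd$y, y = w - nd$x, parent = nd$parent, born = nd$born)
  })
  rot$somata <- cbind(x = cu$somata[, "y"], y = w - cu$somata[, "x"])
  a0 <- culture_metrics(culture_to_skeletons(cu))$bounding_rect_area
  a1 <- culture_metrics(culture_to_skeletons(rot))$bounding_rect_area
  expect_equal(sort(a0), sort(a1))
})

test_that("thresholded marker area and intensity follow the strict rule", {
  expect_equal(marker_area_intensity(matrix(7, 4, 4), 7)$positive_area, 0)
  expect_false(marker_area_intensity(matrix(7, 4, 4), 7)$defined)

  img <- matrix(0, 10, 10)
  img[cbind(rep(1:5, 8), rep(1:8, each = 5))] <- 100  # 40 bright pixels
  r <- marker_area_intensity(img, 50)
  expect_equal(r$positive_area, 40)
  expect_equal(r$mean_intensity, 100)

  cu <- generate_culture(small_tiled_params(n_steps = 25), 3)
  rr <- render_image(cu, line_width = 3, noise_sd = 0)
  r2 <- marker_area_intensity(rr$image, 0)
  expect_equal(r2$positive_area, sum(rr$labels != 0L))
})
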