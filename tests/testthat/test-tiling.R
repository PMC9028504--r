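two_bar_culture <- function(gap) {
  # two horizontal single-branch cells separated vertically by `gap` rows
  a <- data.frame(x = c(5, 25), y = 10, parent = c(0L, 1L), born = 0:1)
  b <- data.frame(x = c(5, 25), y = 10 + gap, parent = c(0L, 1L), born = 0:1)
  tree_culture(list(a, b), field = c(60, 60))
}

test_that("cells separated by more than epsilon report no violations", {
  v <- detect_violations(culture_to_skeletons(two_bar_culture(5)), epsilon = 1)
  expect_true(all(!v$branches$violating))
  expect_equal(v$per_cell$violation_percentage, c(0, 0))
  expect_equal(v$per_culture$mean_violation_percentage, 0)
})

test_that("touching and crossing branches are flagged symmetrically", {
  # cell A: one horizontal branch; cell B: 10 branches, one crossing A
  a <- data.frame(x = c(5, 45), y = 20, parent = c(0L, 1L), born = 0:1)
  bx <- c(25, rep(NA, 10)); by <- c(40, rep(NA, 10)); bp <- c(0L, rep(NA, 10))
  b <- data.frame(x = 25, y = 40, parent = 0L, born = 0L)
  for (i in 1:9)  # fan of short branches staying clear of A
    b <- rbind(b, data.frame(x = 25 + 6 * cos(pi * i / 10),
                             y = 40 + 6 * sin(pi * i / 10),
                             parent = 1L, born = i))
  b <- rbind(b, data.frame(x = 25, y = 15, parent = 1L, born = 10L))  # crosses A
  cu <- tree_culture(list(a, b), field = c(60, 60))
  v <- detect_violations(culture_to_skeletons(cu), epsilon = 1)
  pc <- v$per_cell
  expect_gte(pc$violating_count[pc$cell == 2], 1L)
  expect_gte(pc$violation_percentage[pc$cell == 2], 10)
  expect_gte(pc$violating_count[pc$cell == 1], 1L)  # symmetry
  # brute-force agreement
  bf <- detect_violations_bruteforce(culture_to_skeletons(cu), 1)
  sk <- culture_to_skeletons(cu)
  v_flags <- split(v$branches$violating, v$branches$cell)
  expect_equal(unname(v_flags[["1"]]), bf[[1]])
  expect_equal(unname(v_flags[["2"]]), bf[[2]])
})

test_that("violation counts are non-decreasing in epsilon", {
  cu <- generate_culture(growth_params(n_cells = 4, field_size = c(300, 300),
                                       soma_min_spacing = 90, n_steps = 35,
                                       repulsion = FALSE), 5)
  sk <- culture_to_skeletons(cu)
  counts <- vapply(0:3, function(e)
    sum(detect_violations(sk, e)$per_cell$violating_count), 1)
  expect_true(all(diff(counts) >= 0))
})

test_that("spatial-index detection equals brute force on small cultures", {
  for (s in 1:6) {
    cu <- generate_culture(growth_params(n_cells = 3, field_size = c(200, 200),
                                         soma_min_spacing = 60, n_steps = 20,
                                         repulsion = FALSE), s)
    sk <- culture_to_skeletons(cu)
    npx <- sum(vapply(sk, function(cs)
      sum(vapply(cs$polylines, nrow, 1L)), 1L))
    expect_lt(npx, 2000)  # brute-force regime
    v <- detect_violations(sk, 1)
    bf <- detect_violations_bruteforce(sk, 1)
    flags <- split(v$branches$violating, v$branches$cell)
    for (i in seq_along(sk))
      expect_equal(unname(flags[[as.character(i)]]), bf[[i]])
  }
})

test_that("duplicate cell ids are rejected", {
  sk <- culture_to_skeletons(two_bar_culture(5))
  sk[[2]]$cell_id <- sk[[1]]$cell_id
  expect_error(detect_violations(sk, 1), "duplicate")
})

test_that("timecourse summary matches hand-computed mean and sem", {
  v0 <- detect_violations(culture_to_skeletons(two_bar_culture(5)), 1)
  tc <- violation_timecourse(list(t1 = v0))
  expect_equal(tc$mean_violation_percentage, 0)
  expect_equal(tc$sem_violation_percentage, 0)

  v1 <- detect_violations(culture_to_skeletons(two_bar_culture(1)), 1)
  tc2 <- violation_timecourse(list(a = v0, b = v1))
  expect_equal(tc2$timepoint, c("a", "b"))
  # both cells fully violating at gap 1: per-cell percentages c(100, 100)
  expect_equal(tc2$mean_violation_percentage[2], 100)
  expect_equal(tc2$sem_violation_percentage[2], 0)
  # hand-computed two-value case
  x <- c(100, 0)
  expect_equal(violation_timecourse(list(v = list(per_cell = data.frame(
    violation_percentage = x, violating_count = c(1, 0)))))$sem_violation_percentage,
    sd(x) / sqrt(2))
})

test_that("violations stay flat over development while territories expand", {
  p <- small_tiled_params(n_steps = 60)
  cu <- generate_culture(p, 21)
  lens <- c(20, 40, 60)
  reports <- lapply(lens, function(s)
    detect_violations(culture_to_skeletons(snapshot_culture(cu, s)), 1))
  names(reports) <- paste0("t", lens)
  tc <- violation_timecourse(reports)
  expect_true(all(tc$mean_violation_percentage < 5))
  tot <- vapply(lens, function(s)
    sum(culture_metrics(culture_to_skeletons(snapshot_culture(cu, s)))$total_length), 0)
  expect_true(all(diff(tot) > 0))
})
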