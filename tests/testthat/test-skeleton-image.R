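# binarization and thinning

test_that("binarization is strict and Otsu separates a bimodal image", {
  z <- matrix(0, 5, 5)
  expect_false(any(binarize(z, "fixed", threshold = 0)$mask))

  img <- matrix(10, 10, 10)
  img[3:7, 3:7] <- 200
  b <- binarize(img, "otsu")
  expect_identical(b$mask, img == 200)

  expect_error(binarize(matrix(7, 4, 4), "otsu"), "constant")
  expect_error(binarize(img, "fixed"), "threshold")
})

test_that("Otsu matches an exhaustive between-class-variance search", {
  set.seed(31)
  for (rep in 1:20) {
    img <- matrix(c(rnorm(150, 40, 12), rnorm(150, 160, 20)), 20, 15)
    thr <- otsu_threshold(img)
    # brute force on the same 256-bin histogram: maximize w0*w1*(mu0-mu1)^2
    lo <- min(img); hi <- max(img)
    b <- pmin(256, floor((img - lo) / (hi - lo) * 256) + 1)
    h <- tabulate(b, 256)
    centers <- lo + (1:256 - 0.5) * (hi - lo) / 256
    bcv <- vapply(1:255, function(k) {
      w0 <- sum(h[1:k]); w1 <- sum(h) - w0
      if (w0 == 0 || w1 == 0) return(-Inf)
      mu0 <- sum(h[1:k] * centers[1:k]) / w0
      mu1 <- sum(h[(k + 1):256] * centers[(k + 1):256]) / w1
      w0 * w1 * (mu0 - mu1)^2
    }, 0)
    expect_equal(thr, lo + which.max(bcv) * (hi - lo) / 256)
  }
})

test_that("binarizing a clean render recovers the rasterized foreground", {
  cu <- generate_culture(small_tiled_params(n_steps = 25), 8)
  rr <- render_image(cu, line_width = 1, noise_sd = 0)
  b <- binarize(rr$image, "otsu")
  expect_identical(b$mask, rr$labels != 0L)
})

test_that("a wide bar thins to a single 8-connected path", {
  m <- matrix(FALSE, 9, 36)
  m[4:6, 3:32] <- TRUE
  s <- skeletonize_mask(m)
  expect_equal(count_components8(s), 1L)
  expect_true(all(s[m == FALSE] == FALSE))     # skeleton subset of mask
  g <- extract_graph(s)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2L)
  expect_equal(nrow(g$edges), 1L)
})

test_that("empty masks stay empty and thinning is idempotent", {
  m <- matrix(FALSE, 6, 6)
  expect_identical(skeletonize_mask(m), m)
  set.seed(17)
  for (rep in 1:60) {
    m <- random_mask(9, 9, p = runif(1, 0.2, 0.8))
    s1 <- skeletonize_mask(m)
    expect_identical(skeletonize_mask(s1), s1)
    expect_true(all(!s1[!m]))
    expect_equal(count_components8(s1), count_components8(m))
  }
})

test_that("a plus-sign mask thins to one junction and four endpoints", {
  m <- matrix(FALSE, 31, 31)
  m[15:17, 4:28] <- TRUE
  m[4:28, 15:17] <- TRUE
  # raw thinning leaves sub-3-px end spurs; the standard despurring pass is
  # part of the image pipeline
  s <- prune_spurs(skeletonize_mask(m), 3)
  g <- extract_graph(s)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4L)
  expect_equal(nrow(g$edges), 4L)
})
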