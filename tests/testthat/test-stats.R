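test_that("mean_sem matches hand calculations and translation invariance", {
  expect_equal(mean_sem(c(5, 5, 5)), list(mean = 5, sem = 0, n = 3L,
                                          single = FALSE))
  ms <- mean_sem(c(1, 2, 3, 4))
  expect_equal(ms$mean, 2.5)
  expect_equal(ms$sem, 1.2909944 / 2, tolerance = 1e-6)  # sd 1.2910 / sqrt(4)
  shifted <- mean_sem(c(1, 2, 3, 4) + 17)
  expect_equal(shifted$mean, 19.5)
  expect_equal(shifted$sem, ms$sem)
  expect_error(mean_sem(numeric(0)), "empty")
  expect_true(mean_sem(3)$single)
})

test_that("normalization to a reference behaves like a ratio", {
  s <- c(DIV5 = 2, DIV9 = 6)
  expect_equal(normalize_to_reference(s, "DIV5"), c(DIV5 = 1, DIV9 = 3))
  expect_equal(unname(normalize_to_reference(s, "DIV9")["DIV9"]), 1)
  # inverse consistency
  s2 <- c(DIV5 = 2, DIV9 = 6, DIV15 = 9)
  via9 <- normalize_to_reference(s2, "DIV9") * (s2[["DIV9"]] / s2[["DIV5"]])
  expect_equal(via9, normalize_to_reference(s2, "DIV5"))
  expect_error(normalize_to_reference(s, "DIV3"), "absent")
  expect_error(normalize_to_reference(c(DIV5 = 0, DIV9 = 2), "DIV5"), "zero")
})

test_that("correlation matrix handles self, anti and grouped cases", {
  x <- c(1, 2, 3); y <- c(3, 2, 1)
  m <- correlation_matrix(data.frame(a = x, b = x, c = y))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
  expect_error(correlation_matrix(data.frame(a = x, b = c(2, 2, 2))), "b")
  # per-image averaging: mean of within-group correlations
  df <- data.frame(a = c(1, 2, 3, 1, 2, 3), b = c(1, 2, 3, 3, 2, 1))
  grouped <- correlation_matrix(df, image = rep(1:2, each = 3))
  expect_equal(grouped["a", "b"], 0)  # (+1 + -1) / 2
})

test_that("identical groups give q near 0 and p near 1", {
  g <- rep(list(c(4, 5, 6, 5)), 3)
  names(g) <- c("a", "b", "c")
  tk <- anova_tukey(g)
  expect_true(all(tk$pairs$q < 1e-10))
  expect_true(all(tk$pairs$p_adj > 0.999))
})

test_that("balanced textbook example matches the brute-force q formula", {
  g <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 8, 7),
            c = c(13, 9, 11, 8, 7, 12))
  tk <- anova_tukey(g)
  n <- 6
  msw <- mean(vapply(g, var, 0))
  m <- vapply(g, mean, 0)
  q_expected <- c(abs(m[2] - m[1]), abs(m[3] - m[1]), abs(m[3] - m[2])) /
    sqrt(msw / n)
  expect_equal(tk$pairs$q, unname(q_expected), tolerance = 1e-12)
  expect_true(tk$balanced)
  # p from the studentized range distribution
  expect_equal(tk$pairs$p_adj,
               ptukey(tk$pairs$q, 3, 15, lower.tail = FALSE))
  # agreement with stats::TukeyHSD as an independent reference
  df <- data.frame(v = unlist(g), g = rep(names(g), each = n))
  th <- TukeyHSD(aov(v ~ g, data = df))$g
  expect_equal(sort(tk$pairs$p_adj), sort(unname(th[, "p adj"])),
               tolerance = 1e-9)
})

test_that("Tukey-Kramer with unequal n agrees with TukeyHSD", {
  set.seed(8)
  g <- list(a = rnorm(5, 0), b = rnorm(9, 1), c = rnorm(7, 0.5))
  tk <- anova_tukey(g)
  expect_false(tk$balanced)
  df <- data.frame(v = unlist(g), g = rep(names(g), times = lengths(g)))
  th <- TukeyHSD(aov(v ~ g, data = df))$g
  expect_equal(sort(tk$pairs$p_adj), sort(unname(th[, "p adj"])),
               tolerance = 1e-9)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("with two groups Tukey reduces to the pooled t test (q = t sqrt 2)", {
  set.seed(4)
  a <- rnorm(8); b <- rnorm(11, 0.8)
  tk <- anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(tk$pairs$q, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-10)
  expect_equal(tk$pairs$p_adj, tt$p.value, tolerance = 1e-9)
})

test_that("studentized range CDF matches numerical integration and q tables", {
  # published 5% critical points of the studentized range distribution
  tab <- data.frame(k = c(3, 4, 5, 3, 4, 5, 3, 4, 5),
                    df = c(10, 10, 10, 20, 20, 20, Inf, Inf, Inf),
                    q95 = c(3.877, 4.327, 4.654, 3.578, 3.958, 4.232,
                            3.314, 3.633, 3.858))
  for (i in seq_len(nrow(tab))) {
    k <- tab$k[i]; df <- tab$df[i]
    # quantile agreement at the table's printed precision
    expect_equal(qtukey(0.95, k, df), tab$q95[i], tolerance = 5e-4)
    # CDF agreement with an independent numerical integration
    for (q in c(2.5, tab$q95[i], 5.5))
      expect_lt(abs(ptukey(q, k, df) - ptukey_numeric(q, k, df)), 1e-6)
  }
})

test_that("null p-values are approximately uniform (permutation check)", {
  set.seed(99)
  n_reps <- 500
  pv <- replicate(n_reps, {
    g <- split(rnorm(15), rep(1:3, each = 5))
    min(anova_tukey(g)$pairs$p_adj)
  })
  # minimum adjusted p is stochastically >= uniform on the null; the ANOVA F
  # p-value itself should be uniform
  pf <- replicate(n_reps, {
    g <- split(rnorm(15), rep(1:3, each = 5))
    anova_tukey(g)$anova$p
  })
  ks <- ks.test(pf, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pv > 0.05), 0.9)  # familywise error near nominal
})

test_that("normality report never gates and covers degenerate groups", {
  set.seed(2)
  rep <- normality_report(list(a = rnorm(20), b = rep(1, 5), c = rnorm(3)))
  expect_equal(nrow(rep), 3)
  expect_true(is.na(rep$W[rep$group == "b"]))
  expect_true(all(rep$p[!is.na(rep$p)] > 0))
})
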