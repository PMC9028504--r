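#' Mean and standard error of the mean
#'
#' @param values numeric vector, length >= 1.
#' @return list with `mean`, `sem` (sample sd / sqrt(n); 0 with
#'   `single = TRUE` when n = 1), `n`, `single`.
#' @export
mean_sem <- function(values) {
  if (length(values) == 0L) stop("mean_sem: empty input")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else 0,
       n = n, single = n == 1L)
}

#' Normalize a labelled series to a reference entry
#'
#' Divides every value by the reference value, as in time courses expressed
#' relative to the first day in vitro; the reference maps to exactly 1.
#'
#' @param series named numeric vector.
#' @param reference_label name of the reference entry; must exist and be
#'   nonzero.
#' @return named numeric vector of ratios.
#' @export
normalize_to_reference <- function(series, reference_label) {
  if (!(reference_label %in% names(series)))
    stop(sprintf("reference '%s' absent from series", reference_label))
  ref <- series[[reference_label]]
  if (!is.finite(ref) || ref == 0)
    stop(sprintf("reference '%s' is zero or non-finite", reference_label))
  series / ref
}

#' Pearson correlation matrix of marker intensities
#'
#' Computes the pairwise Pearson correlation of the numeric marker columns.
#' When `image` is supplied, correlations are computed within each image and
#' then averaged unweighted across images — matching the convention of
#' reporting average per-image correlation coefficients across independently
#' prepared samples.
#'
#' @param table data.frame of per-cell marker intensities (numeric columns).
#' @param image optional grouping vector (one entry per row).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, image = NULL) {
  num <- vapply(table, is.numeric, TRUE)
  x <- as.matrix(table[, num, drop = FALSE])
  if (nrow(x) < 3L) stop("need at least 3 rows")
  groups <- if (is.null(image)) rep(1L, nrow(x)) else image
  mats <- lapply(split(seq_len(nrow(x)), groups), function(idx) {
    xi <- x[idx, , drop = FALSE]
    sds <- apply(xi, 2, stats::sd)
    if (any(sds == 0))
      stop(sprintf("constant column: %s",
                   paste(colnames(xi)[sds == 0], collapse = ", ")))
    stats::cor(xi)
  })
  out <- Reduce(`+`, mats) / length(mats)
  diag(out) <- 1
  out
}

#' One-way ANOVA with Tukey / Tukey--Kramer post-hoc comparisons
#'
#' Fits a one-way ANOVA and compares every pair of groups with the studentized
#' range statistic `q = |m_i - m_j| / SE`, where
#' `SE = sqrt(MSW/2 * (1/n_i + 1/n_j))` (the Tukey--Kramer form, which reduces
#' to Tukey's HSD `sqrt(MSW/n)` for equal group sizes). Adjusted p-values come
#' from the studentized range distribution (`ptukey`, evaluated by R's
#' Copenhaver--Holland numerical routine).
#'
#' @param groups named list of numeric vectors, or a data.frame with columns
#'   `value` and `group`. At least 2 groups, each with n >= 2.
#' @param alpha familywise significance level for the `significant` flag.
#' @return an object of class `tukey_result`: `anova` (F statistic, df, p),
#'   `pairs` (group pair, mean difference, se, q, adjusted p, significant),
#'   `alpha`, `balanced`.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  kk <- length(groups)
  if (kk < 2L) stop("need at least 2 groups")
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("every group needs n >= 2")
  m <- vapply(groups, mean, 1)
  v <- vapply(groups, stats::var, 1)
  N <- sum(n)
  df_w <- N - kk
  df_b <- kk - 1L
  msw <- sum((n - 1L) * v) / df_w
  grand <- sum(n * m) / N
  msb <- sum(n * (m - grand)^2) / df_b
  f <- msb / msw
  p_f <- stats::pf(f, df_b, df_w, lower.tail = FALSE)

  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_len(kk))
  pr <- utils::combn(kk, 2L)
  diff <- m[pr[2, ]] - m[pr[1, ]]
  se <- sqrt(msw / 2 * (1 / n[pr[1, ]] + 1 / n[pr[2, ]]))
  q <- abs(diff) / se
  p_adj <- stats::ptukey(q, nmeans = kk, df = df_w, lower.tail = FALSE)
  pairs <- data.frame(group_a = labs[pr[1, ]], group_b = labs[pr[2, ]],
                      diff = unname(diff), se = unname(se), q = unname(q),
                      p_adj = unname(p_adj),
                      significant = unname(p_adj < alpha),
                      stringsAsFactors = FALSE)
  structure(list(anova = list(F = f, df = c(df_b, df_w), p = p_f, msw = msw),
                 pairs = pairs, alpha = alpha,
                 balanced = length(unique(n)) == 1L),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  cat(sprintf("%s post-hoc comparisons (alpha = %g):\n",
              if (x$balanced) "Tukey HSD" else "Tukey-Kramer", x$alpha))
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Shapiro--Wilk normality report
#'
#' Optional pre-analysis report; never gates any downstream computation.
#'
#' @param groups named list of numeric vectors or a `value`/`group`
#'   data.frame.
#' @return data.frame with `group`, `n`, `W`, `p`.
#' @export
normality_report <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_along(groups))
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (length(g) >= 3L && stats::sd(g) > 0) {
      sw <- stats::shapiro.test(g)
      data.frame(group = labs[i], n = length(g), W = unname(sw$statistic),
                 p = sw$p.value, stringsAsFactors = FALSE)
    } else {
      data.frame(group = labs[i], n = length(g), W = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
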