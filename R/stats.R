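#' Pearson correlation with two-sided test
#'
#' Product-moment correlation with the usual t-transform p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), both with positive
#'   variance.
#' @return A list with `r`, `p` (two-sided) and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (var(x) == 0 || var(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition across k independent groups.
#'
#' @param groups A list of numeric samples (>= 2 groups, each n >= 2).
#' @return A list with `F`, `p`, `df_between`, `df_within`, plus the group
#'   `means` and `n`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  n_i <- vapply(groups, length, 1L)
  if (any(n_i < 2L)) stop("degenerate group: every group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n_i))
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value,
       df_between = unname(ow$parameter[1L]),
       df_within = unname(ow$parameter[2L]),
       means = vapply(groups, mean, 1), n = n_i)
}

#' Post hoc test for linear trend across ordered groups
#'
#' The linear-contrast construction over ordered group means: contrast
#' coefficients are the centred (equally spaced) scores, the contrast sum of
#' squares is tested against the within-group mean square on (1, N - k)
#' degrees of freedom, and the slope is the least-squares slope of the group
#' means on the scores (per unit epoch). Following the convention of the
#' common post-test-for-trend implementations, `R2` is the share of the
#' between-group sum of squares explained by the linear contrast (not of the
#' total SS) — 1 when the means are exactly collinear with the scores, and 0
#' by convention when the means do not vary at all.
#'
#' @param groups A list of numeric samples in epoch order (>= 3 groups).
#' @param scores Numeric scores, one per group (default `1, 2, ..., k`).
#' @return An object of class `trend_result`: `slope`, `R2`, `p`, `F`,
#'   `df` (length 2), `group_means`.
#' @export
linear_trend <- function(groups, scores = seq_along(groups)) {
  if (!is.list(groups) || length(groups) < 3L) stop("need >= 3 ordered groups")
  if (length(scores) != length(groups)) stop("one score per group")
  n_i <- vapply(groups, length, 1L)
  if (any(n_i < 2L)) stop("degenerate group: every group needs n >= 2")
  k <- length(groups)
  N <- sum(n_i)
  means <- vapply(groups, mean, 1)
  cc <- scores - mean(scores)
  L <- sum(cc * means)
  ss_contrast <- L^2 / sum(cc^2 / n_i)
  ss_within <- sum(vapply(groups, function(gv) sum((gv - mean(gv))^2), 1))
  ms_within <- ss_within / (N - k)
  grand <- sum(n_i * means) / N
  ss_between <- sum(n_i * (means - grand)^2)
  Fv <- if (ms_within > 0) ss_contrast / ms_within else Inf
  p <- pf(Fv, 1, N - k, lower.tail = FALSE)
  structure(list(
    slope = L / sum(cc^2),
    R2 = if (ss_between > 0) ss_contrast / ss_between else 0,
    p = p, F = Fv, df = c(1L, N - k), group_means = means),
    class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> slope = %.4g, R2 = %.3f, F(%d,%d) = %.3g, p = %.4g\n",
              x$slope, x$R2, x$df[1L], x$df[2L], x$F, x$p))
  invisible(x)
}
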