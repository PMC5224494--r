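#' Two-sided Wilcoxon-Mann-Whitney test
#'
#' Exact null distribution when the combined sample size is at most
#' \code{exact_max} (default 25) and there are no ties; otherwise the normal
#' approximation with continuity and tie correction. Degenerate all-tied
#' input yields p = 1 with a warning.
#'
#' @param a,b Nonempty numeric vectors.
#' @param exact_max Combined-n switchover for the exact null.
#' @return List with \code{U} (Mann-Whitney statistic for sample \code{a})
#'   and \code{p_two_sided}.
#' @export
wilcoxon_mw <- function(a, b, exact_max = 25L) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  if (length(unique(c(a, b))) == 1L) {
    warning("all observations tied; p = 1")
    return(list(U = length(a) * length(b) / 2, p_two_sided = 1))
  }
  exact <- (length(a) + length(b)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p_two_sided = min(1, wt$p.value))
}

#' Pearson correlation with two-sided t-based p-value
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Spearman rank correlation with two-sided p-value
#' @inheritParams pearson_cor
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way analysis of variance with an explicit sum-of-squares partition
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each nonempty).
#' @return An \code{anova_partition}: \code{ss_between}, \code{ss_within},
#'   \code{ss_total}, degrees of freedom, \code{F}, \code{p}.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  grand <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(lengths(groups) * (means - grand)^2)
  ss_within <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  df_b <- length(groups) - 1L
  df_w <- length(x) - length(groups)
  msb <- ss_between / df_b
  msw <- ss_within / df_w
  F <- if (msw > 0) msb / msw else Inf
  structure(list(labels = names(groups),
                 ss_between = ss_between, ss_within = ss_within,
                 ss_total = sum((x - grand)^2),
                 df_between = df_b, df_within = df_w,
                 F = F, p = stats::pf(F, df_b, df_w, lower.tail = FALSE)),
            class = "anova_partition")
}
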