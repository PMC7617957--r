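# Group statistics used throughout the figure-legend comparisons, plus
# summary helpers. Two-group mode "auto" applies a Shapiro-Wilk normality
# gate and falls back on the rank test, mirroring standard practice of
# choosing parametric or non-parametric tests by a normality check.

#' One-sample t test with summary
#'
#' Two-sided one-sample t test against a null value (used, e.g., for
#' selectivity indices and bias indices against 0.5).
#'
#' @param values numeric, n >= 2.
#' @param null_value the null mean.
#' @return list: `statistic`, `p`, `n`, `mean`, `sem`.
#' @export
one_sample_test <- function(values, null_value) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("zero variance: t statistic undefined", call. = FALSE)
  tt <- stats::t.test(values, mu = null_value)
  list(statistic = unname(tt$statistic), p = tt$p.value, n = n,
       mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

#' Two-group comparison (Welch t or Mann-Whitney)
#'
#' `mode = "auto"` uses Welch's t test when both groups pass a Shapiro-Wilk
#' normality check at alpha = 0.05, otherwise the Mann-Whitney U test with
#' tie correction. All tests two-sided.
#'
#' @param a,b numeric groups, each n >= 2.
#' @param mode "auto", "t", or "mann_whitney".
#' @return list: `statistic`, `p`, `method`.
#' @export
two_group_test <- function(a, b, mode = c("auto", "t", "mann_whitney")) {
  mode <- match.arg(mode)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (mode == "auto") {
    normal <- function(x) length(unique(x)) > 2 &&
      stats::shapiro.test(x)$p.value >= 0.05
    mode <- if (normal(a) && normal(b)) "t" else "mann_whitney"
  }
  if (mode == "t") {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(tt$statistic), p = tt$p.value, method = "welch_t")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = "mann_whitney")
  }
}

#' Paired t test
#'
#' @param pre,post equal-length numeric vectors, n >= 2.
#' @return list: `statistic`, `p`, `n`, `mean_diff`.
#' @export
paired_test <- function(pre, post) {
  if (length(pre) != length(post)) stop("length mismatch", call. = FALSE)
  if (length(pre) < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0)
    stop("zero variance of differences: t statistic undefined", call. = FALSE)
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value, n = length(pre),
       mean_diff = mean(d))
}

#' Kruskal-Wallis test with Dunn's pairwise post hoc comparisons
#'
#' Kruskal-Wallis with tie correction, followed by Dunn's z tests on mean
#' ranks for every pair, Bonferroni-adjusted over the tested pairs.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 2).
#' @return list: `H`, `p_global`, `pairwise` (data.frame: `group1`, `group2`,
#'   `z`, `p_unadj`, `p_adj`).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 3) stop("need >= 3 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(names(groups), 2)
  pw <- apply(combs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
               (1 / nn[pr[1]] + 1 / nn[pr[2]]))
    z <- (rbar[pr[1]] - rbar[pr[2]]) / se
    unname(c(z, 2 * stats::pnorm(-abs(z))))
  })
  m <- ncol(combs)
  pairwise <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                         z = pw[1, ], p_unadj = pw[2, ],
                         p_adj = pmin(1, pw[2, ] * m),
                         stringsAsFactors = FALSE)
  list(H = unname(kw$statistic), p_global = kw$p.value, pairwise = pairwise)
}

#' Group summary: mean, SEM, and IQR
#'
#' IQR quantiles use linear interpolation (R type 7), the convention
#' documented in every report this package writes.
#'
#' @param values numeric vector.
#' @return list: `n`, `mean`, `sem`, `median`, `q25`, `q75`, `iqr`.
#' @export
group_summary <- function(values) {
  values <- values[is.finite(values)]
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(n = length(values), mean = mean(values),
       sem = stats::sd(values) / sqrt(length(values)),
       median = stats::median(values), q25 = q[1], q75 = q[2],
       iqr = q[2] - q[1])
}
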