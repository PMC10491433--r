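#' Summary statistics of one group of values
#'
#' Order statistics use linear-interpolation (type-7) quantiles.
#'
#' @param values numeric vector (finite, n >= 1).
#' @param name group label.
#' @return list of class `group_summary`: `name`, `n`, `median`, `q1`, `q3`,
#'   `mean`, `sd`, `max`.
#' @export
summarize_group <- function(values, name = "group") {
  values <- values[is.finite(values)]
  rc_assert(length(values) >= 1, "no finite values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(name = name, n = length(values), median = q[2],
                 q1 = q[1], q3 = q[3], mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 max = max(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n=%d median=%.4g [Q1=%.4g, Q3=%.4g] mean=%.4g sd=%.4g max=%.4g\n",
              x$name, x$n, x$median, x$q1, x$q3, x$mean, x$sd, x$max))
  invisible(x)
}

#' Nonparametric two-group comparison
#'
#' Two-sided Wilcoxon rank-sum test for unpaired samples, Wilcoxon
#' signed-rank test for paired samples; Cohen's d from the pooled SD
#' (unpaired) or the SD of differences (paired).
#'
#' @param a,b numeric vectors.
#' @param paired paired comparison?
#' @return list of class `comparison_result`: `test`, `statistic`, `p_value`,
#'   `cohens_d`, `n_a`, `n_b`, `low_n` (flagged below 5 per group).
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  if (paired) rc_assert(length(a) == length(b),
                        "paired comparison requires equal lengths")
  low_n <- min(length(a), length(b)) < 5
  if (low_n) warning("fewer than 5 values per group: low-power comparison")
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            alternative = "two.sided",
                                            exact = FALSE))
  d <- if (paired) {
    dd <- a - b
    if (stats::sd(dd) > 0) mean(dd) / stats::sd(dd) else 0
  } else {
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    if (sp > 0) (mean(a) - mean(b)) / sp else 0
  }
  structure(list(test = if (paired) "signed_rank" else "rank_sum",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 cohens_d = d, n_a = length(a), n_b = length(b), low_n = low_n),
            class = "comparison_result")
}

#' Pearson correlation, optionally on log-transformed values
#'
#' For the log variant, pairs with a non-positive member are dropped and
#' counted.
#'
#' @param x,y numeric vectors of equal length.
#' @param log_transform natural-log transform both variables first?
#' @return list of class `comparison_result`: `test = "pearson"`, `statistic`
#'   (r), `p_value`, `n`, `n_dropped`.
#' @export
correlate <- function(x, y, log_transform = FALSE) {
  rc_assert(length(x) == length(y), "x and y must have equal length")
  n_dropped <- 0L
  if (log_transform) {
    ok <- x > 0 & y > 0
    n_dropped <- sum(!ok)
    x <- log(x[ok]); y <- log(y[ok])
  }
  rc_assert(length(x) >= 3, "need at least 3 (usable) pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(structure(list(test = "pearson", statistic = NA_real_,
                          p_value = NA_real_, n = length(x),
                          n_dropped = n_dropped),
                     class = "comparison_result"))
  }
  ct <- stats::cor.test(x, y)
  structure(list(test = "pearson", statistic = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x), n_dropped = n_dropped),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g p=%.3g%s\n", x$test, x$statistic, x$p_value,
              if (!is.null(x$cohens_d)) sprintf(" d=%.3g", x$cohens_d) else ""))
  invisible(x)
}
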