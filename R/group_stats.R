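# Group statistics for per-cell descriptor tables: percent change versus a
# control, one-way ANOVA, Dunn's rank-based multiple comparisons, Pearson
# correlation and boxplot summaries with outlier flagging.

#' Percent change of a group mean versus a control mean
#'
#' @param group_mean,control_mean group and control means (`control_mean != 0`).
#' @param direction `"reduction"` gives `(ctrl - group) / ctrl * 100`,
#'   `"increase"` gives `(group - ctrl) / ctrl * 100`, matching how
#'   descriptor shifts are conventionally reported against the control.
#' @return Percent change (can be negative when the direction is reversed).
#' @export
percent_change <- function(group_mean, control_mean,
                           direction = c("reduction", "increase")) {
  direction <- match.arg(direction)
  if (control_mean == 0) stop("percent_change: zero control mean")
  if (direction == "reduction") (control_mean - group_mean) / control_mean * 100
  else (group_mean - control_mean) / control_mean * 100
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA via the between/within
#' sum-of-squares decomposition.
#'
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of the same length, >= 2 levels with
#'   >= 2 observations each.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  n <- tapply(values, groups, length)
  if (nlevels(groups) < 2 || any(is.na(n)) || any(n < 2))
    stop("one_way_anova: need >= 2 groups with >= 2 observations each")
  m <- tapply(values, groups, mean)
  gm <- mean(values)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((values - m[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  if (ssw == 0 && ssb == 0) return(list(F = 0, p = 1, df_between = df1, df_within = df2))
  if (ssw == 0) stop("one_way_anova: zero within-group variance in every group")
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

#' Dunn's rank-based multiple comparison test
#'
#' All observations are ranked jointly (mid-ranks for ties); for each pair of
#' groups the z statistic is the mean-rank difference over its tie-corrected
#' standard error
#' `sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t)` over tie groups. Raw two-sided normal p values are
#' adjusted by the stated method (default Bonferroni, capped at 1).
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of the same length; every group must
#'   be nonempty.
#' @param adjustment `"bonferroni"` (default) or `"holm"`.
#' @return Object of class `comparison_result`: list with `pairs` (data frame
#'   `group1, group2, z, p, p_adj, stars`), `omnibus` (the one-way ANOVA
#'   `F` and `p`), and `n` (per-group sizes).
#' @export
dunn_test <- function(values, groups, adjustment = c("bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  n <- tapply(values, groups, length)
  if (any(is.na(n)) || any(n == 0)) stop("dunn_test: empty group")
  N <- length(values)
  r <- rank(values)                        # mid-ranks for ties
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  T <- sum(ties^3 - ties)
  lev <- levels(groups)
  pairs <- t(utils::combn(seq_along(lev), 2))
  z <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    se2 <- (N * (N + 1) / 12 - T / (12 * (N - 1))) * (1 / n[i] + 1 / n[j])
    z[k] <- if (se2 > 0) (rbar[i] - rbar[j]) / sqrt(se2) else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- stats::p.adjust(p, method = adjustment)
  omni <- tryCatch(one_way_anova(values, groups),
                   error = function(e) list(F = NA_real_, p = NA_real_))
  structure(list(
    pairs = data.frame(group1 = lev[pairs[, 1]], group2 = lev[pairs[, 2]],
                       z = z, p = p, p_adj = p_adj,
                       stars = significance_stars(p_adj)),
    omnibus = list(F = omni$F, p = omni$p),
    n = as.vector(n)
  ), class = "comparison_result")
}

#' Pearson correlation with a two-sided t-based p value
#'
#' @param x,y numeric vectors (`n >= 3`, nonzero variance in both).
#' @return List with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("pearson_correlation: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Boxplot summary with explicit outliers
#'
#' Quartiles use linear interpolation (the type-7 quantile convention);
#' whiskers reach the most extreme observations within 1.5 x IQR of the
#' quartiles and everything beyond is listed as an outlier.
#'
#' @param values numeric vector (`n >= 1`).
#' @return List with `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) < 1) stop("boxplot_summary: empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = sort(values[!inside]), n = length(values))
}

#' Significance stars
#'
#' Annotation thresholds as used in the figure legends this reporting layer
#' mirrors: `*` p < 0.05, `**` p < 0.01, `***` p < 0.005, `****` p < 0.0001.
#'
#' @param p numeric vector of p values.
#' @return Character vector of star annotations (`"ns"` when not significant).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 0.0001) "****"
    else if (pi < 0.005) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Compare descriptor values across groups against a control
#'
#' Convenience wrapper for long-format descriptor tables: computes per-group
#' means, percent changes versus the control group, the omnibus one-way
#' ANOVA, Dunn's post-hoc pairs and per-group boxplot summaries.
#'
#' @param data data frame with at least the value and group columns.
#' @param value,group column names (strings).
#' @param control name of the control level (for percent changes); `NULL`
#'   skips percent changes.
#' @param direction passed to [percent_change()].
#' @param adjustment passed to [dunn_test()].
#' @return List with `group_means`, `percent_change`, `anova`, `dunn`,
#'   `boxplots`.
#' @export
compare_groups <- function(data, value, group, control = NULL,
                           direction = "reduction",
                           adjustment = "bonferroni") {
  v <- data[[value]]; g <- factor(data[[group]])
  keep <- is.finite(v)
  v <- v[keep]; g <- droplevels(g[keep])
  means <- tapply(v, g, mean)
  pc <- NULL
  if (!is.null(control)) {
    if (!control %in% levels(g)) stop("compare_groups: control level not found")
    pc <- vapply(setdiff(levels(g), control), function(lv)
      percent_change(means[[lv]], means[[control]], direction), 0.0)
  }
  list(group_means = means,
       percent_change = pc,
       anova = one_way_anova(v, g),
       dunn = dunn_test(v, g, adjustment = adjustment),
       boxplots = lapply(split(v, g), boxplot_summary))
}
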