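# Single-parameter analyses: Pearson correlation of G with one descriptor at
# a time, per-level and binned mean summaries, and two-group comparisons.

#' Correlate G with a single descriptor
#'
#' Pearson correlation with a two-tailed p-value from the exact t transform
#' on `n - 2` degrees of freedom, plus the ordinary least-squares line of
#' best fit. The x-intercept (abscissa where the fitted line crosses
#' `y = 0`) is reported: for sulfation it diagnoses whether unsulfated GAGs
#' have any effect, for the charge analysis whether the carboxylate charge
#' contributes.
#'
#' @param entries An entry data frame.
#' @param x Descriptor column name (numeric).
#' @param y Response column name, default `"G"`.
#' @param subset Optional logical vector or expression-like logical index
#'   restricting the entries (e.g. a single protein or GAG).
#' @return An object of class `gag_correlation`: `r`, `p`, `n`, `slope`,
#'   `intercept`, `x_intercept`, `se_slope`.
#' @export
correlate <- function(entries, x, y = "G", subset = NULL) {
  if (!x %in% names(entries)) stop("no such column: ", x)
  if (!y %in% names(entries)) stop("no such column: ", y)
  e <- if (is.null(subset)) entries else entries[subset, , drop = FALSE]
  xv <- as.numeric(e[[x]]); yv <- as.numeric(e[[y]])
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) stop("insufficient data: need at least 3 paired observations")
  if (stats::sd(xv) == 0) stop("insufficient data: x is constant")
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(yv ~ xv)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  structure(list(
    r = unname(ct$estimate), p = ct$p.value, n = n,
    slope = slope, intercept = intercept,
    se_slope = suppressWarnings(summary(fit))$coefficients[2L, 2L],
    x_intercept = if (slope != 0) -intercept / slope else NA_real_,
    x = x, y = y), class = "gag_correlation")
}

#' @export
print.gag_correlation <- function(x, ...) {
  cat(sprintf("Pearson correlation %s ~ %s: r = %.3f, p = %.3g (n = %d)\n",
              x$y, x$x, x$r, x$p, x$n))
  cat(sprintf("  best fit: slope = %.4g (se %.3g), intercept = %.4g, x-intercept = %.4g\n",
              x$slope, x$se_slope, x$intercept, x$x_intercept))
  invisible(x)
}

#' Mean G per level of a descriptor
#'
#' One summary (mean, SD, n) per distinct value of `x`, plus the correlation
#' of the level means with the level values — the averaging analysis used to
#' pool entries sharing the same sulfation or charge state.
#'
#' @param entries An entry data frame.
#' @param x Descriptor column name taking at least 3 distinct values.
#' @return A list with `groups` (data frame `level`, `mean_G`, `sd_G`, `n`)
#'   and `correlation` (a [correlate()] result over the level means).
#' @export
mean_G_by_level <- function(entries, x) {
  if (!x %in% names(entries)) stop("no such column: ", x)
  e <- entries[!is.na(entries[[x]]) & !is.na(entries$G), , drop = FALSE]
  lev <- sort(unique(e[[x]]))
  if (length(lev) < 3L)
    stop("insufficient data: need at least 3 distinct levels")
  groups <- data.frame(
    level = lev,
    mean_G = vapply(lev, function(l) mean(e$G[e[[x]] == l]), numeric(1)),
    sd_G = vapply(lev, function(l) {
      g <- e$G[e[[x]] == l]
      if (length(g) >= 2L) stats::sd(g) else NA_real_
    }, numeric(1)),
    n = vapply(lev, function(l) sum(e[[x]] == l), integer(1)))
  corr <- correlate(data.frame(level = groups$level, G = groups$mean_G),
                    x = "level")
  list(groups = groups, correlation = corr)
}

#' Mean G per bin of a continuous descriptor
#'
#' Bins the descriptor (by default at its quartiles), summarises G per
#' non-empty bin, and correlates the bin means with the bin centers — the
#' range-averaging analysis used for solute molarity and the protein:GAG
#' molar ratio.
#'
#' @param entries An entry data frame.
#' @param x Continuous descriptor column name.
#' @param breaks Optional numeric bin edges covering the observed range;
#'   default: quartile-based edges of the observed values.
#' @return A list with `groups` (`center`, `lower`, `upper`, `mean_G`,
#'   `sd_G`, `n`), `breaks`, and `correlation` over the bin centers (requires
#'   at least 3 non-empty bins).
#' @export
mean_G_by_bin <- function(entries, x, breaks = NULL) {
  if (!x %in% names(entries)) stop("no such column: ", x)
  e <- entries[!is.na(entries[[x]]) & !is.na(entries$G), , drop = FALSE]
  if (!nrow(e)) stop("insufficient data: no paired observations")
  xv <- as.numeric(e[[x]])
  if (is.null(breaks))
    breaks <- unique(stats::quantile(xv, probs = seq(0, 1, 0.25), names = FALSE))
  if (length(breaks) < 2L) stop("insufficient data: degenerate bin edges")
  if (min(xv) < min(breaks) || max(xv) > max(breaks))
    stop("bin edges must cover the observed range")
  idx <- findInterval(xv, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  bins <- sort(unique(idx))
  groups <- data.frame(
    lower = breaks[bins], upper = breaks[bins + 1L],
    center = (breaks[bins] + breaks[bins + 1L]) / 2,
    mean_G = vapply(bins, function(b) mean(e$G[idx == b]), numeric(1)),
    sd_G = vapply(bins, function(b) {
      g <- e$G[idx == b]
      if (length(g) >= 2L) stats::sd(g) else NA_real_
    }, numeric(1)),
    n = vapply(bins, function(b) sum(idx == b), integer(1)))
  corr <- if (nrow(groups) >= 3L)
    correlate(data.frame(center = groups$center, G = groups$mean_G),
              x = "center")
  else stop("insufficient data: fewer than 3 non-empty bins")
  list(groups = groups, breaks = breaks, correlation = corr)
}

#' Compare mean G between two descriptor levels
#'
#' Welch's unequal-variance two-sided t-test between entries at two levels of
#' a grouping descriptor, optionally restricted to entries matching fixed
#' covariate values (e.g. iduronic versus glucuronic GAGs among those with 2
#' sulfates per disaccharide unit). With fewer than 2 entries in either
#' group only the summaries are returned (`p = NA`).
#'
#' @param entries An entry data frame.
#' @param group_var Grouping column name.
#' @param level_a,level_b The two levels to compare.
#' @param match Optional named list of covariate values to hold fixed.
#' @return A list with `groups` (per-level mean/sd/n), `p`, `t`, `df`.
#' @export
compare_two_groups <- function(entries, group_var, level_a, level_b,
                               match = NULL) {
  if (!group_var %in% names(entries)) stop("no such column: ", group_var)
  e <- entries
  if (!is.null(match))
    for (v in names(match)) e <- e[!is.na(e[[v]]) & e[[v]] == match[[v]], ,
                                   drop = FALSE]
  ga <- e$G[!is.na(e$G) & e[[group_var]] == level_a]
  gb <- e$G[!is.na(e$G) & e[[group_var]] == level_b]
  if (!length(ga) || !length(gb))
    stop("empty group: both levels must be observed")
  groups <- data.frame(
    level = c(as.character(level_a), as.character(level_b)),
    mean_G = c(mean(ga), mean(gb)),
    sd_G = c(if (length(ga) >= 2L) stats::sd(ga) else NA_real_,
             if (length(gb) >= 2L) stats::sd(gb) else NA_real_),
    n = c(length(ga), length(gb)))
  if (length(ga) < 2L || length(gb) < 2L)
    return(list(groups = groups, p = NA_real_, t = NA_real_, df = NA_real_))
  tt <- stats::t.test(ga, gb, var.equal = FALSE, alternative = "two.sided")
  list(groups = groups, p = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter))
}
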