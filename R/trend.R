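#' Pearson trend correlation of an SLR time course
#'
#' The trend statistic of the study: the sample Pearson correlation R
#' between a probe's Signal Log Ratios (including the baseline's anchored 0)
#' and the timepoint coordinates (days after maturation, or hours of OGD
#' exposure). R is invariant to affine transformation of the times.
#'
#' @param series numeric SLR values, including the baseline 0.
#' @param times numeric coordinates, strictly increasing, same length as
#'   `series` (>= 3 points for a defined trend with a baseline anchor).
#' @param condition optional label carried through to the result.
#' @return list of class `trend_result` with `r` (NA when the series has
#'   zero variance — explicitly undefined, never coerced to 0), `n` and
#'   `condition`.
#' @export
pearson_trend <- function(series, times, condition = NA_character_) {
  if (length(series) != length(times))
    stop("'series' and 'times' must have equal length")
  if (length(series) < 3L) stop("need >= 3 timepoints")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  r <- if (stats::sd(series) == 0) NA_real_ else
    stats::cor(times, series, method = "pearson")
  structure(list(r = r, n = length(series), condition = condition),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> R = %s (n = %d%s)\n",
              if (is.na(x$r)) "undefined" else formatC(x$r, digits = 3, format = "f"),
              x$n,
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

#' Significance grade for a p-value
#'
#' Maps a p-value to the study's two-level star convention: the strict
#' symbol (`**` or `##`) below the stricter alpha (default 0.05), the loose
#' symbol (`*` or `#`) between the two alphas (default \[0.05, 0.10)), and
#' the empty string otherwise.
#'
#' @param p numeric p-value(s).
#' @param alphas `c(loose, strict)`, strictly decreasing.
#' @param symbols `c(loose, strict)` symbols, e.g. `c("*", "**")` or
#'   `c("#", "##")`.
#' @return character vector of grades.
#' @export
grade_significance <- function(p, alphas = c(0.10, 0.05),
                               symbols = c("*", "**")) {
  ifelse(p < alphas[2L], symbols[2L],
         ifelse(p < alphas[1L], symbols[1L], ""))
}

#' One-sample t-test against the baseline level
#'
#' Tests whether post-baseline SLR observations deviate from `mu` (0 for
#' SLR data, since the baseline is the reference). By convention the test
#' is one-tailed in the direction of the observed mean deviation with
#' df = n - 1 (n = 2 observations: Days 6/8 or 2 h/4 h of OGD); this is the
#' convention that reproduces the published star grades.
#'
#' @param obs numeric observations (>= 2).
#' @param mu null value.
#' @param tail `"one"` (default) or `"two"`.
#' @param alphas,symbols grading convention, see [grade_significance()].
#' @return list of class `t_result` with `t`, `df`, `p`, `grade`, `tail`.
#' @export
one_sample_t <- function(obs, mu = 0, tail = c("one", "two"),
                         alphas = c(0.10, 0.05), symbols = c("*", "**")) {
  tail <- match.arg(tail)
  n <- length(obs)
  if (n < 2L) stop("need >= 2 observations")
  if (!is.finite(mu)) stop("'mu' must be finite")
  s <- stats::sd(obs)
  m <- mean(obs)
  if (s == 0) {
    if (m == mu) {
      t <- 0; p <- 1
    } else {
      t <- sign(m - mu) * Inf
      p <- .Machine$double.xmin
      warning("zero spread with mean != mu; p reported at machine floor")
    }
  } else {
    t <- (m - mu) / (s / sqrt(n))
    p <- stats::pt(-abs(t), df = n - 1L)
    if (tail == "two") p <- 2 * p
  }
  structure(list(t = t, df = n - 1L, p = p,
                 grade = grade_significance(p, alphas, symbols), tail = tail),
            class = "t_result")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student t computed from per-group mean, SD and n — the
#' form needed when only published mean +/- SD values are available (the
#' 2 h vs 4 h OGD comparison). Two-tailed, df = n1 + n2 - 2. Grades use the
#' hash convention by default.
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 second group summary.
#' @param alphas,symbols grading convention, see [grade_significance()].
#' @return list of class `t_result` with `t`, `df`, `p`, `grade`, `tail`.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 alphas = c(0.10, 0.05),
                                 symbols = c("#", "##")) {
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (mean1 == mean2) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean2 - mean1) * Inf
      p <- .Machine$double.xmin
      warning("zero pooled spread with unequal means; p at machine floor")
    }
  } else {
    t <- (mean2 - mean1) / se
    p <- 2 * stats::pt(-abs(t), df = df)
  }
  structure(list(t = t, df = df, p = p,
                 grade = grade_significance(p, alphas, symbols), tail = "two"),
            class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("<t_result> t = %.3f, df = %d, %s-tailed p = %.4g %s\n",
              x$t, x$df, x$tail, x$p, x$grade))
  invisible(x)
}
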