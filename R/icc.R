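#' Two-way ANOVA without replication
#'
#' Decomposes a complete n x k response grid (cases in rows, items/months
#' in columns, one observation per cell) into row, column, and residual
#' sums of squares: `ss_rows = k * sum((rowmean - grand)^2)`,
#' `ss_cols = n * sum((colmean - grand)^2)`, `ss_error` by subtraction
#' from the total. F ratios test rows and columns against the residual
#' mean square; p-values are upper-tail F probabilities.
#'
#' @param x Complete numeric matrix, n >= 2 rows and k >= 2 columns, no
#'   missing cells.
#' @return An object of class `anova_decomposition`: list with `ss_rows`,
#'   `ss_cols`, `ss_error`, `ss_total`, the matching `df_*` and `ms_*`,
#'   `f_rows`, `f_cols`, `p_rows`, `p_cols`, `n_cases`, `k_items`, and a
#'   `degenerate` flag (TRUE when the grid is constant so no F exists).
#' @export
two_way_anova <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("two-way ANOVA requires a complete matrix (no NA)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 columns")
  grand <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - grand)^2)
  ss_cols <- n * sum((colMeans(x) - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ss_error <- max(ss_error, 0)  # guard tiny negative rounding
  df_rows <- n - 1L; df_cols <- k - 1L; df_error <- (n - 1L) * (k - 1L)
  ms_rows <- ss_rows / df_rows
  ms_cols <- ss_cols / df_cols
  ms_error <- ss_error / df_error
  degenerate <- ms_error == 0 && ms_rows == 0 && ms_cols == 0
  f_rows <- if (ms_error > 0) ms_rows / ms_error else NA_real_
  f_cols <- if (ms_error > 0) ms_cols / ms_error else NA_real_
  structure(list(
    ss_rows = ss_rows, ss_cols = ss_cols, ss_error = ss_error,
    ss_total = ss_total,
    df_rows = df_rows, df_cols = df_cols, df_error = df_error,
    ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error,
    f_rows = f_rows, f_cols = f_cols,
    p_rows = if (is.na(f_rows)) NA_real_ else
      stats::pf(f_rows, df_rows, df_error, lower.tail = FALSE),
    p_cols = if (is.na(f_cols)) NA_real_ else
      stats::pf(f_cols, df_cols, df_error, lower.tail = FALSE),
    n_cases = n, k_items = k, degenerate = degenerate
  ), class = "anova_decomposition")
}

#' Assemble an ANOVA decomposition from printed sums of squares
#'
#' Convenience constructor for re-analyzing published two-way ANOVA
#' tables: supply the row (cases) and error sums of squares with their
#' degrees of freedom and, optionally, the column SS.
#'
#' @param ss_rows,df_rows Between-case sum of squares and df (n - 1).
#' @param ss_error,df_error Residual sum of squares and df (n-1)(k-1).
#' @param ss_cols,df_cols Optional between-column (month) SS and df.
#' @return An `anova_decomposition` (column entries NA when not supplied).
#' @export
anova_from_ss <- function(ss_rows, df_rows, ss_error, df_error,
                          ss_cols = NA_real_, df_cols = NA_integer_) {
  ms_rows <- ss_rows / df_rows
  ms_error <- ss_error / df_error
  ms_cols <- if (is.na(ss_cols)) NA_real_ else ss_cols / df_cols
  n <- df_rows + 1L
  k <- df_error / df_rows + 1L
  structure(list(
    ss_rows = ss_rows, ss_cols = ss_cols, ss_error = ss_error,
    ss_total = ss_rows + ifelse(is.na(ss_cols), 0, ss_cols) + ss_error,
    df_rows = as.integer(df_rows), df_cols = df_cols,
    df_error = as.integer(df_error),
    ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error,
    f_rows = ms_rows / ms_error,
    f_cols = if (is.na(ms_cols)) NA_real_ else ms_cols / ms_error,
    p_rows = stats::pf(ms_rows / ms_error, df_rows, df_error,
                       lower.tail = FALSE),
    p_cols = if (is.na(ms_cols)) NA_real_ else
      stats::pf(ms_cols / ms_error, df_cols, df_error, lower.tail = FALSE),
    n_cases = as.integer(n), k_items = as.integer(round(k)),
    degenerate = ms_rows == 0 && ms_error == 0
  ), class = "anova_decomposition")
}

#' Consistency average-measure ICC from a two-way ANOVA
#'
#' The two-way, consistency-type, average-measure intraclass correlation
#' ICC(C,k) -- numerically equal to Cronbach's alpha -- computed as
#' `(MS_rows - MS_error) / MS_rows`, with `F = MS_rows / MS_error` and its
#' upper-tail p-value, plus the F-based 95% confidence interval.
#'
#' @param anova An `anova_decomposition`.
#' @param alpha Confidence level complement for the interval (default
#'   0.05 for a 95% CI).
#' @return An `icc_estimate`: list with `icc`, `ci_low`, `ci_high`,
#'   `f_obs`, `p`, `n_cases`, `k_items`, `degenerate`.
#' @export
icc_from_anova <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_decomposition"))
  if (anova$ms_rows == 0) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, f_obs = NA_real_,
                          p = NA_real_, n_cases = anova$n_cases,
                          k_items = anova$k_items, degenerate = TRUE),
                     class = "icc_estimate"))
  }
  icc <- if (anova$ms_error == 0) 1 else
    (anova$ms_rows - anova$ms_error) / anova$ms_rows
  est <- structure(list(
    icc = icc,
    ci_low = NA_real_, ci_high = NA_real_,
    f_obs = anova$f_rows, p = anova$p_rows,
    n_cases = anova$n_cases, k_items = anova$k_items,
    degenerate = FALSE
  ), class = "icc_estimate")
  ci <- icc_confidence_interval(est, alpha = alpha)
  est$ci_low <- ci[[1L]]
  est$ci_high <- ci[[2L]]
  est
}

#' @export
print.icc_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("ICC(C,k) = %.*f  95%% CI [%.*f, %.*f]  F = %.*f  p = %.3g  (n = %d, k = %d)\n",
              digits, x$icc, digits, x$ci_low, digits, x$ci_high,
              digits, x$f_obs, x$p, x$n_cases, x$k_items))
  invisible(x)
}

#' F-based confidence interval for the average-measure consistency ICC
#'
#' Feldt-type bounds: with `F_obs = 1 / (1 - ICC)` (equivalently
#' `MS_rows / MS_error`), the lower bound is
#' `1 - 1 / (F_obs / qF(1 - alpha/2; n-1, (n-1)(k-1)))` and the upper bound
#' `1 - 1 / (F_obs * qF(1 - alpha/2; (n-1)(k-1), n-1))`.
#'
#' @param est An `icc_estimate`, or a bare ICC value if `n` and `k` are
#'   given.
#' @param alpha Two-sided error rate (default 0.05).
#' @param n,k Dimensions, needed when `est` is a bare number.
#' @return Named numeric vector `c(low, high)`.
#' @export
icc_confidence_interval <- function(est, alpha = 0.05, n = NULL, k = NULL) {
  if (inherits(est, "icc_estimate")) {
    icc <- est$icc; n <- est$n_cases; k <- est$k_items
    f_obs <- est$f_obs
  } else {
    icc <- est
    if (is.null(n) || is.null(k)) stop("n and k are required")
    f_obs <- NA_real_
  }
  if (is.null(n) || is.null(k) || n < 2 || k < 2) stop("invalid dimensions")
  if (is.na(f_obs)) {
    if (icc >= 1) stop("ICC must be below 1 to recover F")
    f_obs <- 1 / (1 - icc)
  }
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
  c(low = 1 - 1 / fl, high = 1 - 1 / fu)
}

#' Standard error of measurement
#'
#' `SEM = SD_x * sqrt(1 - r_xx)`: the within-case measurement error implied
#' by the observed spread `SD_x` and reliability `r_xx`. In cost-containment
#' monitoring a *larger* SEM (relative to the spread) signals greater
#' homogeneity of providers, i.e. better collective control.
#'
#' @param sd_x Observed sample SD of the raw scores (>= 0).
#' @param r_xx Reliability estimate (<= 1; negative values are allowed, as
#'   consistency ICCs can be negative).
#' @return SEM in the units of the raw scores.
#' @export
sem <- function(sd_x, r_xx) {
  if (any(sd_x < 0)) stop("sd_x must be non-negative")
  if (any(r_xx > 1)) stop("reliability cannot exceed 1")
  sd_x * sqrt(1 - r_xx)
}

#' Separation index and strata count from a reliability
#'
#' `G_p = sqrt(r / (1 - r))` and `strata = (4 * G_p + 1) / 3`: the number
#' of statistically distinct performance levels the measure can resolve.
#' At r = 0.5 the separation is 1 and strata = 1.67, i.e. effectively a
#' single stratum; reliabilities below 0.5 cannot distinguish cases.
#'
#' @param r_xx Reliability in [0, 1).
#' @return List with `g_p` and `strata`.
#' @export
strata_index <- function(r_xx) {
  if (any(r_xx < 0) || any(r_xx >= 1)) stop("reliability must be in [0, 1)")
  g_p <- sqrt(r_xx / (1 - r_xx))
  list(g_p = g_p, strata = (4 * g_p + 1) / 3)
}

#' Yearly ICC series from a score matrix
#'
#' Runs the two-way ANOVA / ICC(C,k) analysis on each calendar-year block
#' of band codes (default) or continuous SD values.
#'
#' @param scores An `xmr_scores` object.
#' @param blocks Year blocks from [yearly_blocks()].
#' @param use Which score layer the ANOVA consumes: `"bands"` (ordinal
#'   codes treated as numeric, the default) or `"sd"`.
#' @param alpha CI error rate.
#' @return Named list (names = years) of `icc_estimate`s; each carries the
#'   underlying `anova_decomposition` as attribute `"anova"` and derived
#'   indices (`sem`, `g_p`, `strata`) as attribute `"derived"`.
#' @export
yearly_icc_series <- function(scores, blocks, use = c("bands", "sd"),
                              alpha = 0.05) {
  stopifnot(inherits(scores, "xmr_scores"))
  use <- match.arg(use)
  layer <- scores[[if (use == "bands") "bands" else "sd"]]
  out <- lapply(blocks, function(b) {
    block <- layer[, b$columns, drop = FALSE]
    if (anyNA(block)) {
      stop("year ", b$year, " contains unscored (burn-in) cells")
    }
    an <- two_way_anova(block)
    est <- icc_from_anova(an, alpha = alpha)
    attr(est, "anova") <- an
    if (!est$degenerate && est$icc < 1) {
      r <- max(0, min(est$icc, 1 - 1e-12))
      si <- strata_index(r)
      attr(est, "derived") <- list(
        sem = sem(stats::sd(as.vector(block)), est$icc),
        g_p = si$g_p, strata = si$strata
      )
    }
    est
  })
  names(out) <- vapply(blocks, function(b) as.character(b$year), "")
  out
}

#' Linear trend statistics of a yearly ICC series
#'
#' Pearson correlation of ICC against calendar year, its t statistic
#' (`|r| * sqrt(n-2) / sqrt(1-r^2)`, df = n - 2) with two-sided p,
#' the explained variance r^2, and the least-squares slope (ICC change
#' per year).
#'
#' @param yearly Either the list returned by [yearly_icc_series()] or a
#'   named numeric vector of ICCs (names = years).
#' @return List with `yearly_icc`, `r`, `t_stat`, `p`, `r_squared`,
#'   `slope`, `n_years`; `r` is `NA` (flagged) when the ICCs are constant.
#' @export
trend_stats <- function(yearly) {
  if (is.list(yearly) && !is.numeric(yearly)) {
    icc <- vapply(yearly, function(e) e$icc, 0)
  } else {
    icc <- yearly
  }
  years <- as.numeric(names(icc))
  if (anyNA(years)) stop("yearly ICCs must be named by calendar year")
  n <- length(icc)
  if (n < 3L) stop("trend needs at least 3 yearly values")
  if (stats::sd(icc) == 0 || stats::sd(years) == 0) {
    return(list(yearly_icc = icc, r = NA_real_, t_stat = NA_real_,
                p = NA_real_, r_squared = NA_real_, slope = 0,
                n_years = n, degenerate = TRUE))
  }
  r <- stats::cor(years, icc)
  t_stat <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
  list(yearly_icc = icc,
       r = r,
       t_stat = t_stat,
       p = 2 * stats::pt(t_stat, df = n - 2, lower.tail = FALSE),
       r_squared = r^2,
       slope = unname(stats::coef(stats::lm(icc ~ years))[2L]),
       n_years = n, degenerate = FALSE)
}

#' Pearson chi-square test of an r x c contingency table
#'
#' Standard Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the margins, df = (r-1)(c-1), no continuity correction.
#'
#' @param observed Matrix of non-negative counts, at least 2 x 2.
#' @return List with `chi2`, `df`, `p`.
#' @export
chisq_table <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L) stop("need at least 2x2")
  if (any(observed < 0)) stop("counts must be non-negative")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0)) {
    stop("zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
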