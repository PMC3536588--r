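#' Baseline statistics for an XmR individuals chart
#'
#' Computes the central line and process sigma of a trailing baseline
#' window using the individuals/moving-range convention: the central line
#' is the arithmetic mean of the window and sigma is the mean moving range
#' (mean absolute successive difference) divided by the bias constant
#' d2 = 1.128 for subgroups of size 2.
#'
#' @param window Ordered numeric vector of at least 2 baseline values.
#' @return A list with `center_line`, `sigma`, `window_length`.
#' @examples
#' baseline_stats(rep(c(10, 12), 6))  # center 11, sigma 2/1.128
#' @export
baseline_stats <- function(window) {
  window <- as.numeric(window)
  if (length(window) < 2L) stop("baseline window needs at least 2 values")
  if (anyNA(window)) stop("baseline window contains missing values")
  list(center_line = mean(window),
       sigma = mean(abs(diff(window))) / 1.128,
       window_length = length(window))
}

#' Signed SD distance of one observation from its baseline
#'
#' Returns `(value - center_line) / sigma`. A degenerate baseline
#' (sigma = 0, e.g. a constant series) does not abort the scan: the score
#' is 0 when the value sits on the central line and otherwise the band cap
#' with the sign of the deviation.
#'
#' @param value Observed amount.
#' @param baseline A list from [baseline_stats()].
#' @param cap Magnitude assigned when sigma is 0 and the value is off the
#'   central line (default 4, the outermost band).
#' @return Signed distance in sigma units.
#' @export
xmr_score <- function(value, baseline, cap = 4) {
  d <- value - baseline$center_line
  if (baseline$sigma > 0) return(d / baseline$sigma)
  ifelse(d == 0, 0, sign(d) * cap)
}

#' Sequentially score an expenditure matrix against trailing baselines
#'
#' For each case (row) and each month index `t > baseline_length`, the
#' month's value is scored against the window of the `baseline_length`
#' months immediately before it (the moving baseline excludes the scored
#' point). The first `baseline_length` months are burn-in and produce no
#' scores; rows are scored independently.
#'
#' @param matrix An [expenditure_matrix()] (or plain numeric matrix with
#'   `"YYYY-MM"` colnames) with at least `baseline_length + 1` columns.
#' @param baseline_length Trailing window length in months (default 12).
#' @param scheme Band scheme for the discretized codes: `"ten_band"`
#'   (signed codes -4..-1, +1..+4) or `"five_band"` (codes 0..4).
#' @param zero_band Ten-band code assigned to a distance of exactly 0
#'   (default `+1L`; the bands below/above the central line exclude 0, so a
#'   tie rule is needed).
#' @return An `xmr_scores` object: list with `sd` and `bands` matrices
#'   (cases x scored months), `scheme`, `baseline_length`.
#' @export
sequential_scan <- function(matrix, baseline_length = 12L,
                            scheme = c("ten_band", "five_band"),
                            zero_band = 1L) {
  scheme <- match.arg(scheme)
  m <- unclass(matrix)
  if (!is.matrix(m) || !is.numeric(m)) stop("input must be a numeric matrix")
  b <- as.integer(baseline_length)
  if (b < 2L) stop("baseline_length must be at least 2")
  n_col <- ncol(m)
  if (n_col < b + 1L) {
    stop("need at least baseline_length + 1 = ", b + 1L,
         " columns, got ", n_col)
  }
  scored_idx <- (b + 1L):n_col
  sd_m <- base::matrix(NA_real_, nrow(m), length(scored_idx),
                       dimnames = list(rownames(m), colnames(m)[scored_idx]))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    mr <- abs(diff(x))
    for (j in seq_along(scored_idx)) {
      t <- scored_idx[j]
      cl <- mean(x[(t - b):(t - 1L)])
      # moving ranges internal to the window [t-b, t-1]
      sig <- mean(mr[(t - b):(t - 2L)]) / 1.128
      d <- x[t] - cl
      sd_m[i, j] <- if (sig > 0) d / sig else if (d == 0) 0 else sign(d) * 4
    }
  }
  bands <- discretize(sd_m, scheme = scheme, zero_band = zero_band)
  new_xmr_scores(sd_m, bands, scheme = scheme, baseline_length = b)
}

new_xmr_scores <- function(sd, bands, scheme, baseline_length) {
  stopifnot(identical(dim(sd), dim(bands)),
            identical(is.na(sd), is.na(bands)))
  structure(list(sd = sd, bands = bands, scheme = scheme,
                 baseline_length = baseline_length),
            class = "xmr_scores")
}

#' @export
print.xmr_scores <- function(x, ...) {
  cat("<xmr_scores> ", nrow(x$sd), " cases x ", ncol(x$sd),
      " scored months, scheme = ", x$scheme,
      ", baseline = ", x$baseline_length, " months\n", sep = "")
  invisible(x)
}

#' Discretize SD distances into ordinal band codes
#'
#' Two schemes are supported. `ten_band` mirrors the chart's cumulative
#' band labels below/above the central line: `code = sign(sd) *
#' min(4, ceiling(|sd|))`, so distances in (0,1] map to +1 ("above CL"),
#' (1,2] to +2, and anything beyond 4 sigma is capped at +/-4; an exact 0
#' belongs to neither side, and the tie goes to `zero_band` (default +1).
#' `five_band` rounds to the nearest integer, clips to [-2, 2], and shifts
#' to the 0..4 ordinal scale used for 5-category rating-scale comparisons.
#'
#' @param sd Numeric vector or matrix of signed SD distances (`NA`
#'   passes through).
#' @param scheme `"ten_band"` or `"five_band"`.
#' @param zero_band Code for sd exactly 0 under `ten_band`.
#' @return Integer codes with the same shape (and missingness) as `sd`.
#' @export
discretize <- function(sd, scheme = c("ten_band", "five_band"),
                       zero_band = 1L) {
  scheme <- match.arg(scheme)
  out <- if (scheme == "ten_band") {
    code <- sign(sd) * pmin(ceiling(abs(sd)), 4)
    code[!is.na(sd) & sd == 0] <- zero_band
    code
  } else {
    pmin(pmax(round(sd), -2), 2) + 2
  }
  storage.mode(out) <- "integer"
  out
}
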