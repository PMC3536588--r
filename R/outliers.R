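#' Bubble-chart points for one scored month
#'
#' One point per case: current-month SD distance on the x-axis, previous
#' month's on the y-axis, bubble size `|sd_current|`. This is the
#' plot-ready dataset behind the consecutive-deviation bubble chart used
#' to triage providers.
#'
#' @param scores An `xmr_scores` object.
#' @param month A scored month label (`"YYYY-MM"`); its predecessor must
#'   also be scored, so the first scored month is rejected.
#' @return Data frame with columns `case_id`, `sd_current`, `sd_previous`,
#'   `size`, `flag` (initialized to `"none"`; see [flag_outliers()]).
#' @export
bubble_points <- function(scores, month) {
  stopifnot(inherits(scores, "xmr_scores"))
  labels <- colnames(scores$sd)
  j <- match(month, labels)
  if (is.na(j)) stop("month ", month, " is not a scored month")
  if (j == 1L) stop("month ", month,
                    " is the first scored month; no previous score exists")
  data.frame(case_id = rownames(scores$sd),
             sd_current = scores$sd[, j],
             sd_previous = scores$sd[, j - 1L],
             size = abs(scores$sd[, j]),
             flag = "none",
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Flag consecutively out-of-control cases on a bubble set
#'
#' Applies the quadrant rule over the rectangular control area
#' `[-t, t] x [-t, t]`: a case is an `outlier` when both the current and
#' previous SD distances strictly exceed the threshold in magnitude *with
#' the same sign* (top-right or bottom-left quadrant — a sustained
#' deviation over two consecutive months); `watch` when exactly one of the
#' two months exceeds it, or both do with mixed signs; `none` otherwise.
#' Boundary equality does not trigger a flag.
#'
#' @param points Data frame from [bubble_points()].
#' @param threshold Positive SD threshold (default 2).
#' @return The data frame with `flag` filled in.
#' @export
flag_outliers <- function(points, threshold = 2) {
  if (threshold <= 0) stop("threshold must be positive")
  cur <- points$sd_current
  prev <- points$sd_previous
  out <- abs(cur) > threshold & abs(prev) > threshold &
    sign(cur) == sign(prev)
  watch <- (abs(cur) > threshold | abs(prev) > threshold) & !out
  points$flag <- ifelse(out, "outlier", ifelse(watch, "watch", "none"))
  points
}
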