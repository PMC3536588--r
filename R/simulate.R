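#' Scenario specification for calibration datasets
#'
#' Builds the specification for one of the calibration scenarios used to
#' interpret the ICC scale: an iid standard-normal continuous matrix
#' (`random_normal`) or a Rasch rating-scale ordinal matrix whose person
#' measures and item difficulties encode a monitoring situation:
#'
#' * `increasing`  — dispersed persons ~N(0,1), difficulties falling from
#'   2.0 to -1.0 across items (expenditures drifting up over time);
#' * `decreasing`  — persons ~N(0,1), difficulties rising from -2.0 to 1.0;
#' * `out_of_control` — persons ~N(0,1), flat difficulty 0 (cases differ,
#'   months don't);
#' * `in_control`  — every person measure 0, every difficulty 0 (all cases
#'   behave identically up to category noise).
#'
#' @param name One of `"increasing"`, `"decreasing"`, `"out_of_control"`,
#'   `"in_control"`, `"random_normal"`.
#' @param n_persons,n_items Matrix dimensions (defaults 421 x 13).
#' @param n_categories Rating-scale categories (default 5, codes 0..4).
#' @param thresholds Ordered category thresholds in logits; default equally
#'   spaced `(-1.5, -0.5, 0.5, 1.5)` for 5 categories.
#' @return A `scenario_spec` list: `name`, `n_persons`, `n_items`,
#'   `n_categories`, `thresholds`, `person_dist` (`"normal"` or `"zero"`),
#'   `difficulty` (length `n_items`, endpoints interpolated linearly).
#' @export
scenario_spec <- function(name = c("increasing", "decreasing",
                                   "out_of_control", "in_control",
                                   "random_normal"),
                          n_persons = 421L, n_items = 13L,
                          n_categories = 5L,
                          thresholds = NULL) {
  name <- match.arg(name)
  if (is.null(thresholds)) {
    m <- n_categories
    thresholds <- seq(-(m - 2) / 2, (m - 2) / 2, length.out = m - 1)
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  if (length(thresholds) != n_categories - 1L) {
    stop("need n_categories - 1 thresholds")
  }
  difficulty <- switch(name,
    increasing = seq(2, -1, length.out = n_items),
    decreasing = seq(-2, 1, length.out = n_items),
    rep(0, n_items))
  person_dist <- if (name == "in_control") "zero" else "normal"
  structure(list(name = name, n_persons = as.integer(n_persons),
                 n_items = as.integer(n_items),
                 n_categories = as.integer(n_categories),
                 thresholds = thresholds, difficulty = difficulty,
                 person_dist = person_dist),
            class = "scenario_spec")
}

#' Rating-scale model category probabilities
#'
#' Probability of each of the m ordered categories 0..m-1 under the Rasch
#' rating-scale model: `P(X = j)` is proportional to
#' `exp(sum_{l <= j} (theta - delta - tau_l))`, with the empty sum for
#' j = 0, where `theta` is the person measure, `delta` the item difficulty,
#' and `tau` the shared category thresholds (all in logits).
#'
#' @param theta Person measure.
#' @param delta Item difficulty.
#' @param thresholds Strictly increasing vector of m - 1 thresholds.
#' @return Numeric vector of m probabilities summing to 1.
#' @export
rsm_probabilities <- function(theta, delta, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  # cumulative log-numerators; subtract max for numerical stability
  eta <- c(0, cumsum(theta - delta - thresholds))
  w <- exp(eta - max(eta))
  w / sum(w)
}

# derive a per-row RNG seed so earlier rows are unaffected by row count
row_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 1009) %% 2147483647
}

#' Generate one scenario matrix
#'
#' `random_normal` draws an iid standard-normal continuous grid. The Rasch
#' scenarios draw each person's measure from the spec's person
#' distribution and sample every cell from [rsm_probabilities()]. Each row
#' uses a seed substream derived from `(seed, row)`, so generation is a
#' pure function of `(spec, seed)` and adding rows never reshuffles
#' earlier ones.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer RNG seed.
#' @param pipeline How the matrix feeds the ICC analysis: `"direct"`
#'   (default) returns the categories/draws themselves as the n x k
#'   analysis matrix; `"xmr"` treats the Rasch categories as a monthly
#'   series of length `baseline_length + n_items`, runs [sequential_scan()]
#'   and returns the five-band codes of the `n_items` scored months (an
#'   exploratory alternative reading of the design).
#' @param baseline_length Baseline window for `pipeline = "xmr"`.
#' @return Numeric matrix `n_persons x n_items` with attributes `spec` and
#'   `seed`; ordinal scenarios use codes `0..n_categories-1`.
#' @export
generate_scenario_matrix <- function(spec, seed,
                                     pipeline = c("direct", "xmr"),
                                     baseline_length = 12L) {
  stopifnot(inherits(spec, "scenario_spec"))
  pipeline <- match.arg(pipeline)
  n <- spec$n_persons
  k <- if (pipeline == "xmr") spec$n_items + baseline_length else spec$n_items
  out <- matrix(NA_real_, n, k)
  if (spec$name == "random_normal") {
    for (i in seq_len(n)) {
      set.seed(row_seed(seed, i))
      out[i, ] <- stats::rnorm(k)
    }
  } else {
    delta <- if (length(spec$difficulty) == k) spec$difficulty else
      switch(spec$name,
             increasing = seq(2, -1, length.out = k),
             decreasing = seq(-2, 1, length.out = k),
             rep(0, k))
    m <- spec$n_categories
    for (i in seq_len(n)) {
      set.seed(row_seed(seed, i))
      theta <- if (spec$person_dist == "zero") 0 else stats::rnorm(1)
      for (j in seq_len(k)) {
        p <- rsm_probabilities(theta, delta[j], spec$thresholds)
        out[i, j] <- sample.int(m, 1L, prob = p) - 1L
      }
    }
  }
  rownames(out) <- paste0("case_", seq_len(n))
  if (pipeline == "xmr") {
    colnames(out) <- month_sequence("2000-01", k)
    # categories become the monitored monthly series; shift to positive
    scan <- sequential_scan(expenditure_matrix(out + 1),
                            baseline_length = baseline_length,
                            scheme = "five_band")
    out <- scan$bands
    storage.mode(out) <- "double"
  } else {
    colnames(out) <- paste0("item_", seq_len(k))
  }
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

#' Stack two scenario populations half and half
#'
#' Draws `ceiling(n/2)` rows from scenario A and `floor(n/2)` from B (the
#' extra row goes to A when n is odd), stacks them A-over-B, and records
#' provenance. Both specs must share `n_items`.
#'
#' @param spec_a,spec_b [scenario_spec()]s with equal `n_items`.
#' @param seed Integer seed; B's substream is offset so the halves are
#'   independent.
#' @param n_persons Total rows of the combined matrix (default
#'   `spec_a$n_persons`).
#' @return Combined matrix with attributes `spec_a`, `spec_b`, `split`.
#' @export
combine_scenarios <- function(spec_a, spec_b, seed,
                              n_persons = spec_a$n_persons) {
  if (spec_a$n_items != spec_b$n_items) stop("n_items must match")
  n_a <- ceiling(n_persons / 2)
  n_b <- n_persons - n_a
  a <- spec_a; a$n_persons <- as.integer(n_a)
  b <- spec_b; b$n_persons <- as.integer(n_b)
  ma <- generate_scenario_matrix(a, seed)
  mb <- generate_scenario_matrix(b, seed + 1e6)
  out <- rbind(ma, mb)
  rownames(out) <- paste0("case_", seq_len(nrow(out)))
  attr(out, "spec") <- NULL
  attr(out, "spec_a") <- spec_a
  attr(out, "spec_b") <- spec_b
  attr(out, "split") <- c(n_a = n_a, n_b = n_b)
  attr(out, "seed") <- seed
  out
}

# consecutive "YYYY-MM" labels starting at `from`
month_sequence <- function(from, n) {
  yr <- as.integer(substr(from, 1L, 4L))
  mo <- as.integer(substr(from, 6L, 7L))
  idx <- (yr * 12L + mo - 1L) + seq_len(n) - 1L
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

#' Generate a plausible monthly expenditure panel
#'
#' End-to-end demo input emulating monthly reimbursement series: each
#' case gets a lognormal base level, a multiplicative per-month drift, and
#' additive Gaussian noise with a fixed coefficient of variation relative
#' to the base level. Optional shocks inject known out-of-control months
#' (ground truth for outlier-recovery tests): a shock of `size` adds
#' `size * base * noise_cv` to the cell, i.e. `size` is approximately the
#' XmR SD distance the shock produces against a clean baseline.
#'
#' @param n_cases,n_months Panel dimensions (`n_months >= 13`).
#' @param drift Per-month multiplicative growth (e.g. 0.002 = +0.2%/month;
#'   default 0).
#' @param noise_cv Noise SD as a fraction of the case's base level
#'   (default 0.05).
#' @param outliers Optional data frame with columns `case` (row index),
#'   `month` (column index), `size` (shock in noise-SD units).
#' @param seed Integer seed.
#' @param start_month First column label (default `"1999-01"`).
#' @param base_meanlog,base_sdlog Lognormal parameters of the base levels.
#' @return An [expenditure_matrix()] with attribute `outliers` echoing the
#'   injected shocks.
#' @export
generate_expenditure_series <- function(n_cases, n_months, drift = 0,
                                        noise_cv = 0.05, outliers = NULL,
                                        seed = 1L, start_month = "1999-01",
                                        base_meanlog = log(1000),
                                        base_sdlog = 0.5) {
  if (n_months < 13L) stop("need at least 13 months")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  vals <- matrix(NA_real_, n_cases, n_months)
  for (i in seq_len(n_cases)) {
    set.seed(row_seed(seed, i))
    base <- stats::rlnorm(1, base_meanlog, base_sdlog)
    trendline <- base * (1 + drift)^(seq_len(n_months) - 1L)
    vals[i, ] <- trendline + stats::rnorm(n_months, 0, base * noise_cv)
  }
  if (!is.null(outliers)) {
    stopifnot(all(c("case", "month", "size") %in% names(outliers)))
    for (r in seq_len(nrow(outliers))) {
      i <- outliers$case[r]; j <- outliers$month[r]
      set.seed(row_seed(seed, i))
      base <- stats::rlnorm(1, base_meanlog, base_sdlog)
      vals[i, j] <- vals[i, j] + outliers$size[r] * base * noise_cv
    }
  }
  vals <- pmax(vals, 0)  # reimbursements are non-negative
  em <- expenditure_matrix(vals,
                           case_ids = paste0("case_", seq_len(n_cases)),
                           month_labels = month_sequence(start_month,
                                                         n_months))
  attr(em, "outliers") <- outliers
  attr(em, "seed") <- seed
  em
}
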