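# shared fixtures and independent oracles

# write a wide expenditure CSV (cells as given, "" for NA) and return path
write_wide_csv <- function(values, month_labels, ids = NULL,
                           path = tempfile(fileext = ".csv")) {
  if (is.null(ids)) ids <- paste0("h", seq_len(nrow(values)))
  chr <- matrix(as.character(values), nrow = nrow(values))
  chr[is.na(chr)] <- ""
  df <- data.frame(id = ids, chr, check.names = FALSE)
  colnames(df) <- c("id", month_labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

months_from <- function(start, n) xmricc:::month_sequence(start, n)

# Cronbach's alpha straight from its defining formula -- independent of
# the ANOVA route used by the package
alpha_oracle <- function(x) {
  k <- ncol(x)
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / var(rowSums(x)))
}

# brute-force two-way ANOVA by definition sums (no shortcuts shared with
# the implementation beyond arithmetic)
anova_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(x[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(x[, j]) - grand)^2
  ss_total <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_total <- ss_total + (x[i, j] - grand)^2
  list(ss_rows = ss_rows, ss_cols = ss_cols,
       ss_error = ss_total - ss_rows - ss_cols, ss_total = ss_total)
}
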