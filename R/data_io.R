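#' Read a wide expenditure matrix from CSV
#'
#' Reads a wide-format table of monthly monetary amounts: the first column
#' holds case (provider) identifiers, the remaining column headers are ISO
#' `"YYYY-MM"` month labels, one per consecutive calendar month. Rows with
#' any missing, blank, or non-numeric cell are dropped (whole-row exclusion,
#' never imputation) and the drop count is reported via a message and the
#' `"n_dropped"` attribute.
#'
#' @param path Path to a UTF-8 CSV file with header row `id,YYYY-MM,...`.
#' @param min_columns Minimum number of month columns required
#'   (default 13 = one baseline year plus one scored month).
#' @return An `expenditure_matrix`: a numeric matrix, cases in rows
#'   (rownames = case ids), months in columns (colnames = `"YYYY-MM"`
#'   labels), with attributes `n_dropped` and `n_input`.
#' @details Month headers must be strictly increasing consecutive calendar
#'   months with no gaps; cells must parse as plain decimal numbers
#'   (thousands separators are rejected); negative amounts are rejected.
#' @export
read_expenditure_matrix <- function(path, min_columns = 13L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2L) stop("expected an id column plus month columns")
  labels <- colnames(raw)[-1L]
  validate_month_labels(labels)
  if (length(labels) < min_columns) {
    stop("need at least ", min_columns, " month columns, got ", length(labels))
  }
  ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad_parse <- !is.na(cells) & nzchar(cells) & is.na(vals)
  if (any(bad_parse & grepl(",", cells))) {
    stop("thousands separators are not accepted; cells must be plain decimals")
  }
  complete <- rowSums(is.na(vals) | !nzchar(cells)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " of ", length(ids),
            " rows dropped for missing or unparseable cells")
  }
  vals <- vals[complete, , drop = FALSE]
  ids <- ids[complete]
  if (nrow(vals) == 0L) stop("no complete rows remain after filtering")
  if (any(vals < 0)) stop("negative monetary amounts are not allowed")
  dimnames(vals) <- list(ids, labels)
  new_expenditure_matrix(vals, n_dropped = n_dropped,
                         n_input = n_dropped + nrow(vals))
}

new_expenditure_matrix <- function(values, n_dropped = 0L,
                                   n_input = nrow(values)) {
  stopifnot(is.matrix(values), is.numeric(values))
  structure(values, n_dropped = as.integer(n_dropped),
            n_input = as.integer(n_input),
            class = c("expenditure_matrix", "matrix", "array"))
}

#' Construct an expenditure matrix from values in memory
#'
#' @param values Numeric cases x months matrix, no missing cells,
#'   non-negative.
#' @param case_ids Optional case identifiers (default taken from rownames,
#'   or `case_1..case_n`).
#' @param month_labels `"YYYY-MM"` labels, consecutive calendar months
#'   (default taken from colnames).
#' @return An `expenditure_matrix`.
#' @export
expenditure_matrix <- function(values, case_ids = rownames(values),
                               month_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(nrow(values)))
  if (is.null(month_labels)) stop("month_labels are required")
  validate_month_labels(month_labels)
  if (length(month_labels) != ncol(values)) {
    stop("month_labels length does not match column count")
  }
  if (anyNA(values)) stop("missing cells are not allowed; drop rows instead")
  if (any(values < 0)) stop("negative monetary amounts are not allowed")
  dimnames(values) <- list(as.character(case_ids), month_labels)
  new_expenditure_matrix(values)
}

#' @export
print.expenditure_matrix <- function(x, ...) {
  cat("<expenditure_matrix> ", nrow(x), " cases x ", ncol(x), " months (",
      colnames(x)[1L], " .. ", colnames(x)[ncol(x)], ")\n", sep = "")
  if (attr(x, "n_dropped") > 0L) {
    cat("  ", attr(x, "n_dropped"), " of ", attr(x, "n_input"),
        " input rows dropped for missing cells\n", sep = "")
  }
  invisible(x)
}

# "YYYY-MM": strictly increasing, consecutive, valid month numbers
validate_month_labels <- function(labels) {
  if (!all(grepl("^[0-9]{4}-[0-9]{2}$", labels))) {
    stop("month headers must be 'YYYY-MM'")
  }
  yr <- as.integer(substr(labels, 1L, 4L))
  mo <- as.integer(substr(labels, 6L, 7L))
  if (any(mo < 1L | mo > 12L)) stop("month number out of 01..12 in headers")
  idx <- yr * 12L + (mo - 1L)
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    stop("month headers must be consecutive calendar months with no gaps")
  }
  invisible(idx)
}

# successor of a "YYYY-MM" label
next_month_label <- function(label) {
  yr <- as.integer(substr(label, 1L, 4L))
  mo <- as.integer(substr(label, 6L, 7L))
  if (mo == 12L) sprintf("%04d-01", yr + 1L) else sprintf("%04d-%02d", yr, mo + 1L)
}

#' Split a scored region into calendar-year blocks
#'
#' Given the full month labels of an input series and the index of the first
#' scored month, returns one block per complete calendar year in the scored
#' region. Each block carries the year and the 12 column indices of that
#' year *within the score matrix* (whose columns are the scored months
#' only).
#'
#' @param month_labels All `"YYYY-MM"` labels of the input series.
#' @param first_scored_index Index (1-based, within `month_labels`) of the
#'   first scored month; with a 12-month baseline this is 13.
#' @return A list of `year_block` objects, each `list(year=, columns=)`.
#' @export
yearly_blocks <- function(month_labels, first_scored_index) {
  validate_month_labels(month_labels)
  n <- length(month_labels)
  if (first_scored_index < 1L || first_scored_index > n) {
    stop("first_scored_index out of range")
  }
  scored <- month_labels[first_scored_index:n]
  mo <- as.integer(substr(scored, 6L, 7L))
  if (mo[1L] != 1L || length(scored) %% 12L != 0L) {
    stop("scored region must span whole calendar years: it starts at ",
         scored[1L], " and holds ", length(scored),
         " months; align the baseline so scoring begins in January and",
         " covers complete years")
  }
  years <- as.integer(substr(scored, 1L, 4L))
  lapply(unique(years), function(y) {
    structure(list(year = y, columns = which(years == y)),
              class = "year_block")
  })
}

#' Write XmR scores to a pair of CSV files
#'
#' Serializes an [xmr_scores] object as two wide CSVs of identical shape:
#' signed SD distances (6 decimals) and integer band codes. Missing cells
#' are written as empty strings and restored as `NA` on read.
#'
#' @param scores An `xmr_scores` object.
#' @param sd_path Destination for the continuous SD values.
#' @param bands_path Destination for the ordinal band codes.
#' @return Invisibly, the two paths.
#' @seealso [read_scores()]
#' @export
write_scores <- function(scores, sd_path, bands_path) {
  stopifnot(inherits(scores, "xmr_scores"))
  if (nrow(scores$sd) == 0L || ncol(scores$sd) == 0L) {
    stop("refusing to write an empty score matrix")
  }
  write_wide <- function(m, path, fmt) {
    chr <- matrix(ifelse(is.na(m), "", sprintf(fmt, m)), nrow = nrow(m))
    df <- data.frame(id = rownames(m), chr, check.names = FALSE)
    colnames(df) <- c("id", colnames(m))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_wide(scores$sd, sd_path, "%.6f")
  write_wide(scores$bands, bands_path, "%d")
  invisible(c(sd = sd_path, bands = bands_path))
}

#' Read XmR scores written by [write_scores()]
#'
#' @param sd_path CSV of SD values.
#' @param bands_path CSV of band codes.
#' @param scheme Band scheme recorded in the object (`"ten_band"` or
#'   `"five_band"`); serialization does not carry it.
#' @param baseline_length Baseline window length to record.
#' @return An `xmr_scores` object.
#' @export
read_scores <- function(sd_path, bands_path, scheme = "ten_band",
                        baseline_length = 12L) {
  read_wide <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(out <- matrix(as.numeric(m), nrow = nrow(m)))
    out[!nzchar(m)] <- NA_real_
    dimnames(out) <- list(df[[1L]], colnames(df)[-1L])
    out
  }
  sd_m <- read_wide(sd_path)
  bd_m <- read_wide(bands_path)
  if (!identical(dim(sd_m), dim(bd_m))) {
    stop("SD and band files disagree in shape")
  }
  storage.mode(bd_m) <- "integer"
  new_xmr_scores(sd_m, bd_m, scheme = scheme,
                 baseline_length = as.integer(baseline_length))
}
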