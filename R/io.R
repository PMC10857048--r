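#' Write a labeled frame dataset to CSV
#'
#' Serializes the canonical tabular layout: 64 pixel columns `p00`..`p63`
#' plus the `state` label column, comma-delimited with a mandatory header
#' row, `.` decimal separator and LF line endings. Pixel values are
#' written with 17 significant digits so the write/read round trip is
#' lossless.
#'
#' @param dataset a data frame satisfying the canonical schema (see
#'   [read_frames()]); extra columns such as `timestamp` or `thermistor`
#'   are preserved.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(dataset, path) {
  check_dataset_schema(dataset)
  out <- dataset
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con, sep = "\n")
  lines <- do.call(paste, c(unname(as.list(out)), list(sep = ",")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a labeled frame dataset from CSV
#'
#' Parses a CSV file in the canonical layout (64 pixel columns
#' `p00`..`p63` row-major from the 8x8 grid, plus a `state` label column;
#' optional `timestamp`/`thermistor` columns from raw logs are kept).
#' Schema violations — missing pixel columns, a missing label column,
#' non-numeric pixel cells, labels outside the vocabulary — raise errors
#' naming the offending column or row.
#'
#' @param path CSV file path.
#' @param states label vocabulary to validate against; `NULL` skips the
#'   check.
#' @return A data frame in canonical form.
#' @export
read_frames <- function(path, states = .known_states) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE)
  pcols <- sprintf("p%02d", 0:63)
  missing_p <- setdiff(pcols, names(d))
  if (length(missing_p)) {
    stop("schema error: missing pixel column(s) ",
         paste(utils::head(missing_p, 3), collapse = ", "),
         if (length(missing_p) > 3) ", ...", call. = FALSE)
  }
  if (!"state" %in% names(d)) {
    stop("schema error: missing label column 'state'", call. = FALSE)
  }
  for (nm in pcols) {
    if (!is.numeric(d[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[nm]]))))[1]
      stop("schema error: non-numeric value in column '", nm,
           "', row ", bad, call. = FALSE)
    }
  }
  if (!is.null(states)) {
    bad <- which(!d$state %in% states)
    if (length(bad)) {
      stop("schema error: unknown label '", d$state[bad[1]],
           "' in row ", bad[1], call. = FALSE)
    }
  }
  d
}

check_dataset_schema <- function(dataset) {
  pcols <- sprintf("p%02d", 0:63)
  if (!all(pcols %in% names(dataset)) || !"state" %in% names(dataset)) {
    stop("dataset must carry pixel columns p00..p63 and a 'state' column",
         call. = FALSE)
  }
  invisible(dataset)
}

#' Reproducible train/test split
#'
#' Partitions a labeled dataset into disjoint, exhaustive training and
#' test sets. The test size is the nearest integer to
#' `total * test_fraction` (the rounding that reproduces the reference
#' splits: 752 rows at 1/5 give 602 train / 150 test; 1542 give
#' 1234 / 308). Rows are shuffled under the seed before cutting, so test
#' rows are never in the training set by construction; `shuffle = FALSE`
#' preserves the original order and takes the test set from the tail.
#'
#' @param dataset data frame to split.
#' @param test_fraction fraction of rows assigned to the test set,
#'   in (0, 1); default 1/5.
#' @param seed integer seed for the shuffle.
#' @param shuffle shuffle before cutting (default `TRUE`).
#' @return A list with data frames `train` and `test`.
#' @examples
#' d <- data.frame(x = 1:10)
#' s <- split_dataset(d, seed = 1)
#' nrow(s$train); nrow(s$test)  # 8, 2
#' @export
split_dataset <- function(dataset, test_fraction = 0.2, seed = 42,
                          shuffle = TRUE) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("'test_fraction' must lie in (0, 1)", call. = FALSE)
  }
  n <- nrow(dataset)
  if (n < 2L) stop("dataset must have at least 2 rows", call. = FALSE)
  n_test <- max(1L, min(n - 1L, as.integer(round(n * test_fraction))))
  ord <- if (shuffle) {
    with_scene_seed(seed, sample.int(n))
  } else seq_len(n)
  test_idx <- ord[seq.int(n - n_test + 1L, n)]
  train_idx <- ord[seq_len(n - n_test)]
  list(train = dataset[train_idx, , drop = FALSE],
       test = dataset[test_idx, , drop = FALSE])
}
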