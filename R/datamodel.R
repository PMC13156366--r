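#' Incomplete survival dataset
#'
#' Container for right-censored survival data with incompletely observed
#' covariates. Missing entries are kept as `NA` in the covariate matrix and
#' mirrored by a binary mask (`1` = observed), so downstream code never has to
#' guess which entries were filled. Nothing is imputed here.
#'
#' @param x Numeric matrix (n x p) of covariates, `NA` marking missing entries.
#' @param time Non-negative numeric vector of event/censoring times.
#' @param event Integer/numeric vector in \{0, 1\}; 1 = event, 0 = censored.
#' @param feature_names Optional character vector of column names.
#' @param observed_flags Optional logical vector marking columns that are
#'   always observed; defaults to the columns with no `NA`.
#'
#' @return An object of class `incomplete_dataset` with elements `x_tilde`,
#'   `mask`, `time`, `event`, `feature_names`, `observed_flags`.
#' @export
incomplete_dataset <- function(x, time, event, feature_names = NULL,
                               observed_flags = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (length(time) != n || length(event) != n) {
    stopf("time/event length (%d/%d) must match nrow(x) = %d",
          length(time), length(event), n)
  }
  if (anyNA(time) || anyNA(event)) stopf("time/event must not contain NA")
  if (any(time < 0)) stopf("time must be non-negative")
  check_binary(event, "event")
  if (is.null(feature_names)) {
    feature_names <- colnames(x)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(p))
  }
  if (length(feature_names) != p) stopf("feature_names must have length %d", p)
  mask <- 1 - is.na(x)
  storage.mode(mask) <- "double"
  if (is.null(observed_flags)) observed_flags <- colSums(mask) == n
  if (length(observed_flags) != p) stopf("observed_flags must have length %d", p)
  if (any(observed_flags & colSums(mask) < n)) {
    stopf("columns flagged always-observed contain NA")
  }
  colnames(x) <- feature_names
  colnames(mask) <- feature_names
  structure(
    list(x_tilde = x, mask = mask, time = as.numeric(time),
         event = as.numeric(event), feature_names = feature_names,
         observed_flags = as.logical(observed_flags)),
    class = "incomplete_dataset"
  )
}

#' @export
print.incomplete_dataset <- function(x, ...) {
  cat(sprintf(
    "incomplete_dataset: %d subjects, %d features (%d always observed)\n",
    nrow(x$x_tilde), ncol(x$x_tilde), sum(x$observed_flags)))
  cat(sprintf("  observed entries: %.1f%%; events: %.1f%%\n",
              100 * mean(x$mask), 100 * mean(x$event)))
  invisible(x)
}

#' @export
dim.incomplete_dataset <- function(x) dim(x$x_tilde)

#' Subset an incomplete dataset by rows
#' @param x An `incomplete_dataset`.
#' @param i Row index vector.
#' @param ... Unused.
#' @export
`[.incomplete_dataset` <- function(x, i, ...) {
  incomplete_dataset(x$x_tilde[i, , drop = FALSE], x$time[i], x$event[i],
                     x$feature_names, x$observed_flags)
}

#' Read an incomplete survival dataset from CSV
#'
#' Expects an RFC-4180 style CSV with a header row. Missing covariate values
#' are written with an explicit token (default `"NA"`); the time and event
#' columns must be complete.
#'
#' @param path File path.
#' @param time_col,event_col Names of the outcome columns.
#' @param na_token String marking missing values on disk.
#' @param feature_cols Optional character vector selecting/ordering covariate
#'   columns; defaults to every non-outcome column in file order.
#' @return An [incomplete_dataset()].
#' @export
load_table <- function(path, time_col = "time", event_col = "event",
                       na_token = "NA", feature_cols = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = na_token,
                        colClasses = NA)
  for (cc in c(time_col, event_col)) {
    if (!cc %in% names(df)) stopf("required column '%s' missing from %s", cc, path)
    if (anyNA(df[[cc]])) stopf("column '%s' contains missing values", cc)
  }
  if (is.null(feature_cols)) feature_cols <- setdiff(names(df), c(time_col, event_col))
  missing_feats <- setdiff(feature_cols, names(df))
  if (length(missing_feats)) stopf("feature columns not in file: %s",
                                   paste(missing_feats, collapse = ", "))
  x <- as.matrix(df[feature_cols])
  storage.mode(x) <- "double"
  incomplete_dataset(x, df[[time_col]], df[[event_col]], feature_cols)
}

#' Write an incomplete survival dataset to CSV
#'
#' Inverse of [load_table()]: missing entries become the NA token, outcome
#' columns are appended after the covariates. Round-trips exactly (mask
#' bitwise, values to full double precision).
#'
#' @param ds An `incomplete_dataset`.
#' @param path Output file path.
#' @param na_token Missing-value token.
#' @export
write_table <- function(ds, path, na_token = "NA") {
  df <- as.data.frame(ds$x_tilde)
  df$time <- ds$time
  df$event <- ds$event
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = na_token)
  invisible(path)
}

#' Fit a covariate standardiser on observed training entries
#'
#' Computes per-column location (mean) and scale (sample standard deviation,
#' n-1 convention) from the observed training entries only, plus per-column
#' min/max for the [0, 1] rescaling used by the out-of-range (-1) encoding.
#' Masked entries never influence the statistics.
#'
#' @param train An `incomplete_dataset`.
#' @return An object of class `standardiser`.
#' @export
fit_standardiser <- function(train) {
  x <- train$x_tilde
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2)) {
    stopf("columns with <2 observed training values: %s",
          paste(train$feature_names[n_obs < 2], collapse = ", "))
  }
  location <- colMeans(x, na.rm = TRUE)
  scale <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(scale <= 0 | !is.finite(scale))) {
    stopf("degenerate scale (constant observed column): %s",
          paste(train$feature_names[scale <= 0 | !is.finite(scale)], collapse = ", "))
  }
  structure(
    list(location = location, scale = scale,
         min = apply(x, 2, min, na.rm = TRUE),
         max = apply(x, 2, max, na.rm = TRUE),
         feature_names = train$feature_names),
    class = "standardiser"
  )
}

#' Apply (or invert) a fitted standardiser
#'
#' @param std A `standardiser` from [fit_standardiser()].
#' @param ds An `incomplete_dataset` with the same feature schema.
#' @param inverse If `TRUE`, undo the standardisation.
#' @return A transformed `incomplete_dataset`; NAs stay exactly where they were.
#' @export
standardise <- function(std, ds, inverse = FALSE) {
  if (!identical(std$feature_names, ds$feature_names)) {
    stopf("feature schema mismatch between standardiser and dataset")
  }
  x <- ds$x_tilde
  x <- if (inverse) {
    sweep(sweep(x, 2, std$scale, `*`), 2, std$location, `+`)
  } else {
    sweep(sweep(x, 2, std$location, `-`), 2, std$scale, `/`)
  }
  incomplete_dataset(x, ds$time, ds$event, ds$feature_names, ds$observed_flags)
}

#' Random train/validation/test split
#'
#' Uniform row-wise partition (no stratification) reproducible from a seed.
#'
#' @param ds An `incomplete_dataset`.
#' @param fractions Length-3 numeric summing to 1; default `c(0.64, 0.16, 0.20)`.
#' @param seed Integer seed.
#' @return A `split_bundle`: list with `train`, `validation`, `test` datasets,
#'   the index sets, `fractions` and `seed`.
#' @export
split_dataset <- function(ds, fractions = c(0.64, 0.16, 0.20), seed = 1) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stopf("fractions must be 3 values summing to 1")
  }
  n <- nrow(ds$x_tilde)
  perm <- with_stream(seed, "split", sample.int(n))
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  idx <- list(train = sort(perm[seq_len(n_train)]),
              validation = sort(perm[n_train + seq_len(n_val)]),
              test = sort(perm[(n_train + n_val + 1):n]))
  structure(
    list(train = ds[idx$train], validation = ds[idx$validation],
         test = ds[idx$test], indices = idx, fractions = fractions, seed = seed),
    class = "split_bundle"
  )
}

#' Integer code of a missingness pattern
#'
#' Maps a binary mask row m to `1 + sum_j 2^(p-j) m_j`, a bijection between
#' the 2^p patterns and \{1, ..., 2^p\}. The first feature is the most
#' significant bit. The all-missing pattern codes to 1.
#'
#' @param mask_row Binary vector (or matrix, coded row-wise) of missingness
#'   indicators, 1 = observed.
#' @return Positive number(s) in \{1, ..., 2^p\}. Exact as a double for
#'   p <= 52; p beyond that is rejected.
#' @export
pattern_code <- function(mask_row) {
  if (is.matrix(mask_row)) return(apply(mask_row, 1, pattern_code))
  check_binary(mask_row, "mask")
  p <- length(mask_row)
  if (p > 52) stopf("pattern codes are exact only up to p = 52 features")
  1 + sum(2^((p - 1):0) * mask_row)
}
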