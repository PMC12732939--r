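#' Construct a spectral dataset
#'
#' The container consumed by every other function in the package: a wide
#' absorbance matrix (rows = samples, columns = channels), a strictly
#' monotone wavelength/wavenumber axis, and a single continuous reference
#' property per sample.
#'
#' @param X Numeric matrix of absorbances, `n_samples x n_channels`.
#' @param wavelengths Numeric axis, strictly increasing (nm) or strictly
#'   decreasing (cm-1); one value per column of `X`. The unit tag is carried
#'   verbatim and never converted.
#' @param y Numeric reference property vector (one value per sample).
#' @param sample_ids Character vector of unique sample labels; defaults to
#'   `s1, s2, ...`.
#' @param unit Axis unit tag (opaque string, e.g. `"nm"` or `"cm-1"`).
#' @param y_unit Unit tag for the reference property (e.g. `"% protein"`).
#' @param meta Free-form provenance list.
#' @return An object of class `spectral_dataset` with fields `X`,
#'   `wavelengths`, `y`, `sample_ids`, `unit`, `y_unit`, `meta`.
#' @examples
#' ds <- spectral_dataset(matrix(rnorm(15), 3, 5), seq(1100, 1108, 2),
#'                        c(10, 11, 12))
#' ds
#' @export
spectral_dataset <- function(X, wavelengths, y, sample_ids = NULL,
                             unit = "nm", y_unit = "", meta = list()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  wavelengths <- as.numeric(wavelengths)
  y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(y) != n)
    stop("length(y) [", length(y), "] != nrow(X) [", n, "]")
  if (length(sample_ids) != n)
    stop("length(sample_ids) != nrow(X)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(wavelengths) != ncol(X))
    stop("length(wavelengths) [", length(wavelengths), "] != ncol(X) [",
         ncol(X), "]")
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop("non-finite absorbance at sample '", sample_ids[bad[1]],
         "', channel ", bad[2])
  }
  if (anyNA(y) || any(!is.finite(y)))
    stop("non-finite reference value for sample '",
         sample_ids[which(!is.finite(y))[1]], "'")
  if (length(wavelengths) > 1) {
    d <- diff(wavelengths)
    if (!(all(d > 0) || all(d < 0)))
      stop("wavelength axis must be strictly monotone")
  }
  structure(list(X = X, wavelengths = wavelengths, y = y,
                 sample_ids = sample_ids, unit = unit, y_unit = y_unit,
                 meta = meta),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("spectral_dataset: ", nrow(x$X), " samples x ", ncol(x$X),
      " channels\n", sep = "")
  cat("  axis: ", format(min(x$wavelengths)), " .. ",
      format(max(x$wavelengths)), " ", x$unit,
      if (x$wavelengths[1] > x$wavelengths[length(x$wavelengths)])
        " (descending)" else "", "\n", sep = "")
  cat("  y: ", format(min(x$y)), " .. ", format(max(x$y)),
      if (nzchar(x$y_unit)) paste0(" ", x$y_unit) else "", "\n", sep = "")
  invisible(x)
}

#' Number of samples / channels in a spectral dataset
#' @param ds A `spectral_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$X)

#' @rdname n_samples
#' @export
n_channels <- function(ds) ncol(ds$X)

#' Build an inclusive arithmetic wavelength grid
#'
#' Generates the sequence `start, start+step, ...` up to and including the
#' largest value not exceeding `stop` (a partial final step is dropped).
#' The NIR axis 1100-2500 nm at 2 nm spacing, for example, has 701 channels.
#'
#' @param start,stop Axis endpoints, same unit; `stop >= start`.
#' @param step Positive increment.
#' @return A `wavelength_grid` with fields `start`, `stop`, `step`, `values`.
#' @examples
#' length(make_wavelength_grid(1100, 2500, 2)$values)  # 701
#' @export
make_wavelength_grid <- function(start, stop, step) {
  if (!is.finite(step) || step <= 0) stop("step must be positive")
  if (stop < start) stop("stop must be >= start")
  # small relative tolerance so e.g. (1100, 2500, 2) is not off-by-one
  count <- floor((stop - start) / step + 1e-9) + 1L
  structure(list(start = start, stop = stop, step = step,
                 values = start + step * (seq_len(count) - 1)),
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat("wavelength_grid: ", x$start, " .. ", x$stop, " by ", x$step, " (",
      length(x$values), " channels)\n", sep = "")
  invisible(x)
}

#' Read a spectral dataset from wide CSV
#'
#' Expected layout: header row; first column the sample id, one named
#' response column, and every remaining column a channel whose header is the
#' literal wavelength value. Column order of the channels is preserved, so
#' both ascending-nm and descending-wavenumber axes survive a round trip.
#'
#' @param path CSV file path.
#' @param response_column Name of the reference-property column.
#' @param unit,y_unit Unit tags attached to the result (not stored in CSV).
#' @return A `spectral_dataset`.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, response_column = "y",
                         unit = "nm", y_unit = "") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("expected at least an id column, a response column and one channel")
  if (!response_column %in% names(df))
    stop("response column '", response_column, "' not found in ", path)
  ids <- as.character(df[[1]])
  y <- df[[response_column]]
  chan <- setdiff(names(df)[-1], response_column)
  wl <- suppressWarnings(as.numeric(chan))
  if (anyNA(wl))
    stop("non-numeric wavelength column name(s): ",
         paste(chan[is.na(wl)], collapse = ", "))
  Xdf <- df[, chan, drop = FALSE]
  for (j in seq_along(chan)) {
    col <- Xdf[[j]]
    if (!is.numeric(col))
      stop("non-numeric cell(s) in channel column '", chan[j], "'")
    if (anyNA(col))
      stop("missing/NaN value at row ", which(is.na(col))[1],
           " (sample '", ids[which(is.na(col))[1]], "'), column '",
           chan[j], "'")
  }
  if (!is.numeric(y))
    stop("response column '", response_column, "' is not numeric")
  spectral_dataset(as.matrix(Xdf), wl, y, sample_ids = ids,
                   unit = unit, y_unit = y_unit)
}

#' Write a spectral dataset to wide CSV
#'
#' Inverse of [read_dataset()]: values are written at full double precision
#' so that a read-back reproduces the dataset to float round-off.
#'
#' @param ds A `spectral_dataset`.
#' @param path Output file path.
#' @param response_column Header used for the response column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, response_column = "y") {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (nrow(ds$X) == 0) stop("refusing to write an empty dataset (0 samples)")
  wl_names <- formatC(ds$wavelengths, digits = 15, format = "g")
  if (response_column %in% wl_names)
    stop("response column name collides with a wavelength header")
  df <- data.frame(sample_id = ds$sample_ids, check.names = FALSE)
  df[[response_column]] <- ds$y
  X <- ds$X
  colnames(X) <- wl_names
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
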