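#' Preprocessing specification
#'
#' Describes one of the scatter/baseline pretreatments applied before
#' calibration: standard normal variate (SNV), multiplicative scatter
#' correction (MSC), or a Savitzky-Golay derivative.
#'
#' @param method One of `"none"`, `"snv"`, `"msc"`, `"sg_derivative"`.
#' @param window_length Odd window (channels) for the Savitzky-Golay fit.
#' @param poly_order Polynomial order of the Savitzky-Golay fit; must be
#'   less than `window_length` and at least `deriv_order`.
#' @param deriv_order Derivative order, 1 or 2.
#' @param msc_reference Either `"mean_of_training"` (the default; the
#'   reference is the mean spectrum of the calibration partition, applied
#'   unchanged to the prediction partition to avoid leakage) or an explicit
#'   numeric reference spectrum.
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(method = c("none", "snv", "msc", "sg_derivative"),
                            window_length = 11L, poly_order = 2L,
                            deriv_order = 1L,
                            msc_reference = "mean_of_training") {
  method <- match.arg(method)
  if (method == "sg_derivative") {
    if (window_length %% 2 == 0) stop("window_length must be odd")
    if (poly_order >= window_length) stop("poly_order must be < window_length")
    if (!deriv_order %in% c(1L, 2L)) stop("deriv_order must be 1 or 2")
    if (deriv_order > poly_order) stop("deriv_order must be <= poly_order")
  }
  structure(list(method = method, window_length = as.integer(window_length),
                 poly_order = as.integer(poly_order),
                 deriv_order = as.integer(deriv_order),
                 msc_reference = msc_reference),
            class = "preprocess_spec")
}

#' Standard normal variate
#'
#' Centers and scales each spectrum (row) to mean 0 and unit standard
#' deviation (sample sd, n-1 denominator). Removes additive offsets and
#' per-sample multiplicative scatter; idempotent.
#'
#' @param X Absorbance matrix, samples in rows.
#' @return Matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1))
  if (any(s < .Machine$double.eps * 100)) {
    bad <- which(s < .Machine$double.eps * 100)[1]
    nm <- if (!is.null(rownames(X))) rownames(X)[bad] else bad
    stop("constant spectrum (zero spread) for sample ", nm)
  }
  (X - m) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum x on a reference spectrum, x ~ a + b * reference
#' (ordinary least squares), and returns the corrected row (x - a) / b.
#' A row equal to `offset + slope * reference` is restored exactly to the
#' reference.
#'
#' @param X Absorbance matrix, samples in rows.
#' @param reference Reference spectrum; defaults to the column mean of `X`.
#'   For calibration work pass the training-set mean so the prediction set
#'   is corrected against the same reference (see [apply_preprocess()]).
#' @return Corrected matrix of the same shape.
#' @export
msc <- function(X, reference = colMeans(X)) {
  X <- as.matrix(X)
  if (length(reference) != ncol(X))
    stop("reference length != number of channels")
  r <- as.numeric(reference)
  rc <- r - mean(r)
  vr <- sum(rc^2)
  if (vr <= 0) stop("reference spectrum is constant")
  # per-row OLS slope/intercept against the reference
  b <- as.numeric(X %*% rc) / vr
  a <- rowMeans(X) - b * mean(r)
  if (any(abs(b) < 1e-12)) {
    bad <- which(abs(b) < 1e-12)[1]
    stop("zero MSC slope for sample ", bad,
         " (spectrum orthogonal to the reference trend)")
  }
  (X - a) / b
}

#' Savitzky-Golay derivative spectra
#'
#' Row-wise smoothed derivative via local polynomial fits
#' ([signal::sgolayfilt()]); boundary windows are handled by the polynomial
#' fit itself, so the output keeps the full channel count and selector masks
#' stay aligned with the wavelength axis. The derivative is per channel
#' index (unit axis step).
#'
#' @param X Absorbance matrix, samples in rows.
#' @param spec A `preprocess_spec` with `method = "sg_derivative"`, or the
#'   default window-11 / order-2 first derivative.
#' @return Derivative matrix, same shape as `X`.
#' @export
sg_derivative <- function(X, spec = preprocess_spec("sg_derivative")) {
  X <- as.matrix(X)
  if (spec$window_length %% 2 == 0) stop("window_length must be odd")
  if (spec$deriv_order > spec$poly_order)
    stop("deriv_order must be <= poly_order")
  if (ncol(X) < spec$window_length)
    stop("need at least window_length channels")
  t(apply(X, 1, function(row)
    signal::sgolayfilt(row, p = spec$poly_order, n = spec$window_length,
                       m = spec$deriv_order, ts = 1)))
}

#' Apply a preprocessing spec to calibration and prediction partitions
#'
#' Per-sample transforms (SNV, derivatives) are applied independently to
#' each partition; MSC uses the calibration-set mean spectrum as reference
#' for both partitions (no information leakage).
#'
#' @param train_X Calibration absorbance matrix.
#' @param test_X Optional prediction absorbance matrix.
#' @param spec A `preprocess_spec`.
#' @return List with elements `train`, `test` (or `NULL`) and, for MSC,
#'   `reference`.
#' @export
apply_preprocess <- function(train_X, test_X = NULL,
                             spec = preprocess_spec("none")) {
  stopifnot(inherits(spec, "preprocess_spec"))
  ref <- NULL
  fx <- switch(spec$method,
    none = identity,
    snv = snv,
    msc = {
      ref <- if (is.numeric(spec$msc_reference)) spec$msc_reference
             else colMeans(train_X)
      function(M) msc(M, reference = ref)
    },
    sg_derivative = function(M) sg_derivative(M, spec))
  list(train = fx(train_X),
       test = if (is.null(test_X)) NULL else fx(test_X),
       reference = ref)
}
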