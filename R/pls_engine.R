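#' Fit a PLS1 regression model (NIPALS)
#'
#' Single-response partial least squares on column-centered spectra and a
#' centered response. For one response the NIPALS weight for each latent
#' variable is the (normalized) covariance direction `X'y`; scores are
#' extracted and X deflated successively, so the score vectors are mutually
#' orthogonal. If the residual covariance vanishes before `n_lv` components
#' (rank-deficient data), extraction stops early and the attained count is
#' recorded in `n_lv_used`.
#'
#' @param X Predictor matrix (no NaN), samples in rows.
#' @param y Response vector.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param channel_mask Optional logical/integer mask recording which
#'   channels of a parent dataset `X` corresponds to (bookkeeping only).
#' @return A `pls_model`: centering vectors `x_mean`, `y_mean`; per-LV
#'   `weights`, `x_loadings`, `y_loadings`; the regression vector `b` on
#'   centered data; `n_lv`, `n_lv_used`, `channel_mask`.
#' @export
fit_pls <- function(X, y, n_lv, channel_mask = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X) || anyNA(y)) stop("NaN/NA in input")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop("n_lv must be in 1..min(n-1, p) = ", min(n - 1, p))
  if (stats::var(y) == 0) stop("zero-variance response")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  tol <- 1e-12 * sqrt(sum((crossprod(E, f))^2))
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)                   # covariance direction
    nw <- sqrt(sum(w^2))
    if (nw <= max(tol, 1e-300)) break      # residual rank exhausted
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt <= 1e-300) break
    p_a <- crossprod(E, t) / tt
    q_a <- sum(t * f) / tt
    E <- E - t %*% t(p_a)
    f <- f - as.numeric(t) * q_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) stop("no latent variable could be extracted (X'y = 0)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  structure(list(n_lv = as.integer(n_lv), n_lv_used = a_used,
                 x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q,
                 b = b, channel_mask = channel_mask),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' `y_hat = y_mean + (X - x_mean) b`.
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the model's channel count.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b))
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         length(object$b))
  as.numeric(sweep(newdata, 2, object$x_mean) %*% object$b) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model: ", length(x$b), " channels, ", x$n_lv_used,
      " latent variable(s)\n", sep = "")
  invisible(x)
}

#' Root mean square error
#' @param y Observed values.
#' @param y_hat Predicted values (same length).
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) == 0) stop("empty input")
  sqrt(mean((y - y_hat)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` — the sum-of-squares form, which is negative for a
#' predictor worse than the mean (not a squared correlation).
#'
#' @param y Observed values (nonzero variance).
#' @param y_hat Predicted values.
#' @return Real number `<= 1`.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("constant response")
  1 - sum((y - y_hat)^2) / ss_tot
}

# Pooled RMSECV over an explicit list of splits: squared validation errors
# accumulated across repeats, one sqrt at the end. Internal hot path shared
# by rmsecv(), select_lv_mccv() and the selector fitness functions.
rmsecv_over_splits <- function(X, y, n_lv, splits, mask = NULL) {
  if (!is.null(mask)) {
    if (is.logical(mask)) mask <- which(mask)
    X <- X[, mask, drop = FALSE]
  }
  if (ncol(X) < n_lv) stop("mask selects fewer channels than n_lv")
  sse <- 0; m <- 0L
  for (s in splits) {
    if (length(s$test_idx) == 0) stop("empty validation set in MCCV split")
    fit <- fit_pls(X[s$train_idx, , drop = FALSE], y[s$train_idx], n_lv)
    e <- y[s$test_idx] - predict(fit, X[s$test_idx, , drop = FALSE])
    sse <- sse + sum(e^2)
    m <- m + length(e)
  }
  sqrt(sse / m)
}

#' RMSECV by Monte Carlo cross-validation
#'
#' Root mean square error of validation-set predictions pooled across all
#' repeats of an MCCV plan, with the PLS model refit on every calibration
#' subset (restricted to `mask` when given). Reproducible from the plan's
#' seed; reusing one plan across candidate channel subsets makes their
#' comparison paired.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param n_lv Latent-variable count for every refit.
#' @param plan An [mccv_plan()].
#' @param mask Optional channel subset (logical or index vector).
#' @return Nonnegative pooled RMSE.
#' @export
rmsecv <- function(X, y, n_lv, plan, mask = NULL) {
  X <- as.matrix(X)
  rmsecv_over_splits(X, y, n_lv, mccv_splits(nrow(X), plan), mask)
}

#' Choose the latent-variable count by MCCV
#'
#' Computes the RMSECV curve over `1..max_lv` using one shared set of MCCV
#' splits (so the curve is paired across counts) and returns its argmin;
#' ties within 1e-12 of the minimum go to the smallest count (parsimony).
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param max_lv Largest count to consider.
#' @param plan An [mccv_plan()].
#' @return List with `n_lv` (selected count) and `curve` (RMSECV per count).
#' @export
select_lv_mccv <- function(X, y, max_lv, plan) {
  X <- as.matrix(X)
  if (max_lv < 1) stop("max_lv must be >= 1")
  splits <- mccv_splits(nrow(X), plan)
  max_fit <- min(vapply(splits, function(s) length(s$train_idx) - 1L,
                        integer(1)), ncol(X))
  if (max_lv > max_fit)
    stop("max_lv exceeds the fittable bound ", max_fit,
         " for these calibration sizes")
  curve <- vapply(seq_len(max_lv), function(a)
    rmsecv_over_splits(X, y, a, splits), numeric(1))
  best <- which(curve <= min(curve) + 1e-12)[1]
  list(n_lv = as.integer(best), curve = curve)
}
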