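#' Kennard-Stone calibration/prediction split
#'
#' Deterministic maximin-distance sample selection: the pair of samples at
#' maximal Euclidean distance seeds the calibration set, then the sample
#' whose minimum distance to the selected set is largest is added until the
#' calibration set holds `round(train_fraction * n)` samples (halves rounded
#' away from zero). Ties are broken by the lowest sample index, so the split
#' is a pure function of the matrix handed in — typically the preprocessed
#' spectra.
#'
#' @param X Numeric feature matrix, samples in rows (`n >= 2`).
#' @param train_fraction Fraction in (0, 1); the paper-style two-thirds
#'   split is `2/3`.
#' @return A `split_result` list with integer vectors `train_idx` (in
#'   selection order) and `test_idx` (ascending).
#' @examples
#' s <- kennard_stone_split(matrix(rnorm(200), 100), 2/3)
#' length(s$train_idx)  # 67
#' @export
kennard_stone_split <- function(X, train_fraction) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  k <- round_half_up(train_fraction * n)
  k <- max(2L, min(as.integer(k), n - 1L))
  D <- as.matrix(stats::dist(X))
  # seed pair: global max distance, lowest (i, j) on ties
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sel <- c(idx[1, 1], idx[1, 2])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)       # which.max returns the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  structure(list(train_idx = as.integer(sel),
                 test_idx = setdiff(seq_len(n), sel)),
            class = "split_result")
}

#' Monte Carlo cross-validation plan
#'
#' @param n_repeats Number of independent random calibration/validation
#'   splits (default 50).
#' @param calib_fraction Fraction of samples in each calibration subset,
#'   in (0, 1) (default 0.8).
#' @param seed Integer seed making the whole plan reproducible.
#' @return An `mccv_plan` list.
#' @export
mccv_plan <- function(n_repeats = 50L, calib_fraction = 0.8, seed = 1L) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (!(calib_fraction > 0 && calib_fraction < 1))
    stop("calib_fraction must be in (0, 1)")
  structure(list(n_repeats = as.integer(n_repeats),
                 calib_fraction = calib_fraction, seed = as.integer(seed)),
            class = "mccv_plan")
}

#' Realize the random splits of an MCCV plan
#'
#' Each repeat samples `round(calib_fraction * n)` calibration indices
#' without replacement; the remainder is the validation set. Repeats are
#' independent; the whole sequence is a pure function of (`n`, plan).
#'
#' @param n Sample count (`n >= 5`).
#' @param plan An [mccv_plan()].
#' @return List of `split_result`s, one per repeat.
#' @export
mccv_splits <- function(n, plan) {
  stopifnot(inherits(plan, "mccv_plan"))
  if (n < 5) stop("need at least 5 samples for MCCV")
  k <- round_half_up(plan$calib_fraction * n)
  if (k >= n) stop("calib_fraction leaves an empty validation set")
  if (k < 1) stop("calib_fraction leaves an empty calibration set")
  with_local_seed(plan$seed, lapply(seq_len(plan$n_repeats), function(i) {
    tr <- sort(sample.int(n, k))
    structure(list(train_idx = tr, test_idx = setdiff(seq_len(n), tr)),
              class = "split_result")
  }))
}
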