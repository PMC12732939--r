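#' @title Comparator variable selectors: UVE, MC-UVE and the randomization
#'   test
#' @description Three classical wavelength-selection methods used as
#'   baselines for the swarm-based selector: uninformative variable
#'   elimination (UVE) judges each channel by the stability of its PLS
#'   coefficient against that of appended tiny noise channels; MC-UVE
#'   estimates the same stability over Monte Carlo subsampled fits; the
#'   randomization test (RT) scores each channel by a permutation p-value of
#'   its coefficient under a shuffled response.
#' @name baseline_selectors
NULL

# Shared container for every selector's output.
selection_result <- function(mask, method, score, threshold, seed,
                             fitness_curve = NULL, extra = list()) {
  mask <- as.logical(mask)
  if (!any(mask))
    stop(structure(class = c("dbwopls_empty_selection", "error", "condition"),
                   list(message = paste0(
                     method, " selected no channels; relax the threshold ",
                     "(an empty model is a configuration error, ",
                     "not a result)"), call = NULL)))
  structure(c(list(mask = mask, method = method,
                   score_per_channel = as.numeric(score),
                   threshold = threshold, seed = as.integer(seed),
                   fitness_curve = fitness_curve), extra),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$method, "]: ", sum(x$mask), " of ",
      length(x$mask), " channels selected\n", sep = "")
  invisible(x)
}

# Append p i.i.d. uniform(0,1) noise channels scaled by `amplitude` — the
# classic UVE construction: small enough not to perturb the fit, nonzero so
# their coefficients exist and calibrate the stability threshold.
append_noise_channels <- function(X, amplitude) {
  p <- ncol(X)
  cbind(X, matrix(stats::runif(nrow(X) * p), nrow(X), p) * amplitude)
}

# Stability = mean / sd of each coefficient over a list of resampled fits.
coefficient_stability <- function(X, y, n_lv, train_sets) {
  B <- vapply(train_sets, function(idx)
    fit_pls(X[idx, , drop = FALSE], y[idx], n_lv)$b, numeric(ncol(X)))
  mu <- rowMeans(B)
  sdv <- apply(B, 1, stats::sd)
  sdv[sdv == 0] <- .Machine$double.xmin   # constant coefficient: +/- Inf score
  mu / sdv
}

#' Uninformative variable elimination (UVE)
#'
#' Appends one artificial uniform-noise channel per real channel, computes
#' each coefficient's stability `mean(b_j)/sd(b_j)` over the n leave-one-out
#' PLS fits, and keeps the real channels whose absolute stability exceeds
#' the largest absolute stability seen among the noise channels.
#'
#' @param X Predictor matrix (`n >= n_lv + 2`).
#' @param y Response vector.
#' @param n_lv Latent variables for every refit.
#' @param noise_amplitude Scale of the artificial channels (default 1e-10).
#' @param seed Integer seed (noise channels are random).
#' @return A `selection_result` with the per-channel stability in
#'   `score_per_channel` and the noise cutoff in `threshold`.
#' @export
uve_select <- function(X, y, n_lv, noise_amplitude = 1e-10, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < n_lv + 2) stop("need at least n_lv + 2 samples for leave-one-out")
  with_local_seed(seed, {
    Xa <- append_noise_channels(X, noise_amplitude)
    loo <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
    stab <- coefficient_stability(Xa, y, n_lv, loo)
    cutoff <- max(abs(stab[(p + 1):(2 * p)]))
    selection_result(abs(stab[1:p]) > cutoff, "UVE", stab[1:p], cutoff, seed)
  })
}

#' Monte Carlo UVE (MC-UVE)
#'
#' UVE with the coefficient stability estimated over `n_mc` PLS fits on
#' random subsamples (fraction `calib_fraction`, without replacement)
#' instead of leave-one-out — the more robust variant for small-sample
#' data. Channels are kept either above the noise-channel cutoff
#' (`keep_rule = "noise_max"`) or as the `k` highest-stability channels
#' (`keep_rule = "top_k"`).
#'
#' @inheritParams uve_select
#' @param n_mc Number of Monte Carlo subsamples (`>= 2`; default 500).
#' @param calib_fraction Subsample fraction in (0, 1).
#' @param keep_rule `"noise_max"` or `"top_k"`.
#' @param k Channel count for `keep_rule = "top_k"`.
#' @return A `selection_result`.
#' @export
mcuve_select <- function(X, y, n_lv, n_mc = 500L, calib_fraction = 0.8,
                         keep_rule = c("noise_max", "top_k"), k = NULL,
                         noise_amplitude = 1e-10, seed = 1L) {
  X <- as.matrix(X)
  keep_rule <- match.arg(keep_rule)
  n <- nrow(X); p <- ncol(X)
  if (n_mc < 2) stop("n_mc must be >= 2 (a single split is not supported)")
  m <- round_half_up(calib_fraction * n)
  if (m < n_lv + 1 || m >= n) stop("calib_fraction infeasible for this n")
  with_local_seed(seed, {
    Xa <- append_noise_channels(X, noise_amplitude)
    sets <- lapply(seq_len(n_mc), function(i) sample.int(n, m))
    stab <- coefficient_stability(Xa, y, n_lv, sets)
    if (keep_rule == "noise_max") {
      cutoff <- max(abs(stab[(p + 1):(2 * p)]))
      mask <- abs(stab[1:p]) > cutoff
    } else {
      if (is.null(k) || k < 1 || k > p) stop("top_k rule needs 1 <= k <= p")
      cutoff <- sort(abs(stab[1:p]), decreasing = TRUE)[k]
      mask <- rank(-abs(stab[1:p]), ties.method = "first") <= k
    }
    selection_result(mask, "MC-UVE", stab[1:p], cutoff, seed)
  })
}

#' Randomization test selector (RT)
#'
#' Builds a per-channel null distribution for the PLS regression
#' coefficient by refitting on `n_perm` permutations of the response, and
#' keeps channels whose permutation p-value
#' `(1 + #\{|b_perm| >= |b_obs|\}) / (n_perm + 1)` is below `alpha`.
#' The smallest attainable p-value is `1 / (n_perm + 1)`, which bounds the
#' resolution: with `n_perm = 19` selection is only possible at the
#' `alpha = 0.05` boundary itself.
#'
#' @inheritParams uve_select
#' @param n_perm Number of permutations (`>= 19`; default 499).
#' @param alpha Significance level for retention.
#' @return A `selection_result` with p-values in `score_per_channel`.
#' @export
rt_select <- function(X, y, n_lv, n_perm = 499L, alpha = 0.05, seed = 1L) {
  X <- as.matrix(X)
  if (n_perm < 19) stop("n_perm must be >= 19")
  if (stats::var(y) == 0) stop("constant response")
  b_obs <- abs(fit_pls(X, y, n_lv)$b)
  with_local_seed(seed, {
    exceed <- integer(ncol(X))
    for (r in seq_len(n_perm)) {
      b_perm <- abs(fit_pls(X, sample(y), n_lv)$b)
      exceed <- exceed + (b_perm >= b_obs)
    }
    pval <- (1 + exceed) / (n_perm + 1)
    selection_result(pval < alpha, "RT", pval, alpha, seed)
  })
}
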