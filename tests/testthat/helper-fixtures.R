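# Small fixtures and independent oracles shared across test files.

# A tiny valid dataset built in code.
tiny_dataset <- function(n = 3, p = 5, seed = 42) {
  set.seed(seed)
  spectral_dataset(matrix(rnorm(n * p), n, p),
                   wavelengths = seq(1100, by = 2, length.out = p),
                   y = rnorm(n))
}

# Independent brute-force maximin oracle for the Kennard-Stone procedure:
# explicit loops and fresh distance computations, no shared code with the
# package implementation.
ks_oracle <- function(X, k) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- -Inf; pair <- c(1L, 2L)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dij <- d(i, j)
    if (dij > best) { best <- dij; pair <- c(i, j) }
  }
  sel <- pair
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    scores <- vapply(cand, function(c)
      min(vapply(sel, function(s) d(c, s), numeric(1))), numeric(1))
    sel <- c(sel, cand[which.max(scores)])
  }
  sel
}

# Naive per-row least-squares (normal equations via lm) oracle for MSC.
msc_oracle <- function(X, ref) {
  t(apply(X, 1, function(x) {
    co <- stats::coef(stats::lm(x ~ ref))
    (x - co[1]) / co[2]
  }))
}

# Naively-looped RMSECV oracle: refit per repeat, pool squared errors.
rmsecv_oracle <- function(X, y, n_lv, splits, mask = NULL) {
  if (!is.null(mask)) X <- X[, mask, drop = FALSE]
  errs <- c()
  for (s in splits) {
    fit <- fit_pls(X[s$train_idx, , drop = FALSE], y[s$train_idx], n_lv)
    errs <- c(errs, y[s$test_idx] -
                predict(fit, X[s$test_idx, , drop = FALSE]))
  }
  sqrt(mean(errs^2))
}

# Planted-signal problem: channel 1 equals the response, the rest is noise.
planted_signal <- function(n = 30, p_noise = 200, seed = 1) {
  set.seed(seed)
  y <- rnorm(n)
  list(X = cbind(y, matrix(rnorm(n * p_noise), n, p_noise)), y = y)
}
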