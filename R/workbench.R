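#' Experiment configuration for the method-comparison workbench
#'
#' Bundles everything needed to reproduce one full comparison run:
#' the dataset (a `spectral_dataset` or a synthetic preset), the
#' preprocessing spec, the calibration fraction for the Kennard-Stone
#' split, the latent-variable policy, the selector list with per-selector
#' parameters, and the master seed.
#'
#' @param dataset A `spectral_dataset`, or the string
#'   `"planted_band_benchmark"` for the built-in synthetic preset.
#' @param preprocess A [preprocess_spec()].
#' @param train_fraction Kennard-Stone calibration fraction.
#' @param n_lv `"auto"` (choose by MCCV on the calibration partition) or a
#'   fixed integer.
#' @param max_lv Upper bound when `n_lv = "auto"`.
#' @param selectors Character vector drawn from
#'   `c("full", "uve", "mcuve", "rt", "dbwo")`.
#' @param selector_args Named list of per-selector argument lists (e.g.
#'   `list(dbwo = list(cfg = bwo_config(pop_size = 20, max_iter = 100)))`).
#' @param plan [mccv_plan()] used for LV choice and the DBWO fitness.
#' @param seed Master seed for every stochastic stage.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(dataset, preprocess = preprocess_spec("none"),
                              train_fraction = 2 / 3, n_lv = "auto",
                              max_lv = 10L,
                              selectors = c("full", "uve", "mcuve", "rt",
                                            "dbwo"),
                              selector_args = list(),
                              plan = mccv_plan(seed = seed), seed = 1L) {
  selectors <- match.arg(selectors, several.ok = TRUE)
  if (length(selectors) == 0) stop("need at least one selector or 'full'")
  if (is.character(dataset) && identical(dataset, "planted_band_benchmark"))
    dataset <- planted_band_benchmark(seed)$dataset
  stopifnot(inherits(dataset, "spectral_dataset"))
  structure(list(dataset = dataset, preprocess = preprocess,
                 train_fraction = train_fraction, n_lv = n_lv,
                 max_lv = as.integer(max_lv), selectors = selectors,
                 selector_args = selector_args, plan = plan,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full method comparison
#'
#' The protocol behind the paper-style comparison table: preprocess (per-
#' sample transforms before the split; MSC referenced to the calibration
#' mean), Kennard-Stone split, latent-variable choice by MCCV on the
#' calibration partition, then for each requested method select channels
#' on the calibration partition only, refit the final PLS on those
#' channels, and evaluate RMSEP and R-squared on the held-out prediction
#' partition. A selector failure is recorded in its row and the run
#' continues. Fully reproducible from the config.
#'
#' @param cfg An [experiment_config()].
#' @return A `comparison_report` list: `table` (data.frame with columns
#'   `method`, `n_variables`, `rmsep`, `r2`, `rmsecv`,
#'   `rmsecv_reduction_pct`, `error`), `n_lv`, `split`, and `selections`
#'   (the raw `selection_result`s, including DBWO's convergence curve).
#' @export
run_comparison <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  ds <- cfg$dataset
  # per-sample transforms are leakage-free, so they may precede the split;
  # MSC needs the calibration mean, so split first on the raw spectra then
  # correct both partitions against the calibration reference
  if (cfg$preprocess$method %in% c("none", "snv", "sg_derivative")) {
    Xp <- apply_preprocess(ds$X, spec = cfg$preprocess)$train
    split <- kennard_stone_split(Xp, cfg$train_fraction)
    Xtr <- Xp[split$train_idx, , drop = FALSE]
    Xte <- Xp[split$test_idx, , drop = FALSE]
  } else {
    split <- kennard_stone_split(ds$X, cfg$train_fraction)
    pp <- apply_preprocess(ds$X[split$train_idx, , drop = FALSE],
                           ds$X[split$test_idx, , drop = FALSE],
                           cfg$preprocess)
    Xtr <- pp$train; Xte <- pp$test
  }
  ytr <- ds$y[split$train_idx]
  yte <- ds$y[split$test_idx]
  p <- ncol(Xtr)
  n_lv <- if (identical(cfg$n_lv, "auto")) {
    select_lv_mccv(Xtr, ytr, cfg$max_lv, cfg$plan)$n_lv
  } else as.integer(cfg$n_lv)
  splits <- mccv_splits(nrow(Xtr), cfg$plan)

  arg <- function(m) cfg$selector_args[[m]] %||% list()
  selections <- list()
  rows <- lapply(cfg$selectors, function(m) {
    res <- tryCatch({
      sel <- switch(m,
        full = NULL,
        uve = do.call(uve_select, c(list(X = Xtr, y = ytr, n_lv = n_lv,
                                         seed = cfg$seed), arg(m))),
        mcuve = do.call(mcuve_select, c(list(X = Xtr, y = ytr, n_lv = n_lv,
                                             seed = cfg$seed), arg(m))),
        rt = do.call(rt_select, c(list(X = Xtr, y = ytr, n_lv = n_lv,
                                       seed = cfg$seed), arg(m))),
        dbwo = {
          a <- arg(m)
          a$cfg <- a$cfg %||% bwo_config(seed = cfg$seed)
          do.call(dbwo_select, c(list(x = Xtr, y = ytr, n_lv = n_lv,
                                      plan = cfg$plan), a))
        })
      mask <- if (is.null(sel)) rep(TRUE, p) else sel$mask
      if (!is.null(sel)) selections[[m]] <<- sel
      fit <- fit_pls(Xtr[, mask, drop = FALSE], ytr, n_lv,
                     channel_mask = mask)
      yhat <- predict(fit, Xte[, mask, drop = FALSE])
      cv <- rmsecv_over_splits(Xtr, ytr, n_lv, splits, mask = mask)
      data.frame(method = if (is.null(sel)) "PLS" else
                   paste0(sel$method, "-PLS"),
                 n_variables = sum(mask), rmsep = rmse(yte, yhat),
                 r2 = r_squared(yte, yhat), rmsecv = cv,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(method = toupper(m), n_variables = NA_integer_,
                 rmsep = NA_real_, r2 = NA_real_, rmsecv = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  tab <- do.call(rbind, rows)
  full_cv <- tab$rmsecv[tab$method == "PLS"]
  tab$rmsecv_reduction_pct <- if (length(full_cv) == 1 && !is.na(full_cv))
    100 * (full_cv - tab$rmsecv) / full_cv else NA_real_
  structure(list(table = tab, n_lv = n_lv, split = split,
                 selections = selections, seed = cfg$seed),
            class = "comparison_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.comparison_report <- function(x, ...) {
  cat("Method comparison (", x$n_lv, " latent variables, ",
      length(x$split$train_idx), " calibration / ",
      length(x$split$test_idx), " prediction samples)\n\n", sep = "")
  tab <- x$table
  tab$rmsep <- round(tab$rmsep, 4)
  tab$r2 <- round(tab$r2, 4)
  tab$rmsecv <- round(tab$rmsecv, 4)
  tab$rmsecv_reduction_pct <- round(tab$rmsecv_reduction_pct, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Summarize optimizer convergence curves
#'
#' One row per curve: initial fitness, final fitness, and the iteration of
#' the last improvement. Curves must be monotone non-increasing (a rising
#' best-so-far curve indicates broken greedy acceptance and is a hard
#' failure).
#'
#' @param curves Named list of numeric best-fitness-so-far curves (e.g.
#'   one per transfer function; element 1 is the initial population's
#'   best).
#' @return data.frame with columns `kind`, `initial`, `final`,
#'   `last_improvement_iter`.
#' @export
convergence_report <- function(curves) {
  if (length(curves) < 1) stop("need at least one curve")
  if (is.null(names(curves))) names(curves) <- seq_along(curves)
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    if (any(diff(cv) > 1e-12))
      stop("curve '", nm, "' is not monotone non-increasing: ",
           "greedy acceptance is broken")
    drops <- which(diff(cv) < 0)
    data.frame(kind = nm, initial = cv[1], final = cv[length(cv)],
               last_improvement_iter = if (length(drops)) max(drops) else 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
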