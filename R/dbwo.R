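#' @title Discretized beluga whale optimization for wavelength selection
#' @description Beluga whale optimization (BWO) is a population
#'   metaheuristic built from three behaviours: exploration (swimming,
#'   paired-dimension sine/cosine moves toward a random whale),
#'   exploitation (preying, a Levy-flight-assisted move toward the
#'   incumbent best) and whale fall (re-seeding of poorly balanced whales).
#'   A per-whale balance factor drawn each generation,
#'   `B_f = B0 (1 - T / (2 T_max))` with `B0 ~ U(0,1)`, routes each whale:
#'   exploration when `B_f > 0.5`, exploitation otherwise, and the whale
#'   fall stage when the (linearly decaying) fall probability `W_f`
#'   satisfies `W_f >= B_f`. For wavelength selection the continuous
#'   positions are mapped to binary include/exclude masks through an S- or
#'   V-shaped transfer function, and each mask's fitness is the MCCV
#'   RMSECV of a PLS model on the selected channels.
#' @name dbwo
NULL

#' Transfer functions for discretization
#'
#' Maps a continuous position to `[0, 1]`. The S-shaped `sigmoid`
#' (`1/(1+exp(-x))`) is read as the probability that a bit is set; the
#' V-shaped `V1` (`|erf(sqrt(pi)/2 x)|`, error function) and `V2`
#' (`|tanh(x)|`, hyperbolic tangent) are even functions vanishing at the
#' origin and are read as the probability that a bit flips.
#'
#' @param x Finite numeric vector.
#' @param kind `"sigmoid"`, `"V1"` or `"V2"`.
#' @return Values in `[0, 1]`, same length as `x`.
#' @examples
#' transfer(0, "sigmoid")  # 0.5
#' transfer(0, "V2")       # 0
#' @export
transfer <- function(x, kind = c("V2", "V1", "sigmoid")) {
  kind <- match.arg(kind)
  if (any(!is.finite(x))) stop("non-finite transfer input")
  switch(kind,
         sigmoid = 1 / (1 + exp(-x)),
         V1 = abs(2 * stats::pnorm(sqrt(pi) / 2 * x * sqrt(2)) - 1),
         V2 = abs(tanh(x)))
}

#' Mantegna scale for a Levy-stable step
#'
#' The numerator standard deviation of the Mantegna construction,
#' `sigma_u = [Gamma(1+beta) sin(pi beta / 2) /
#' (Gamma((1+beta)/2) beta 2^((beta-1)/2))]^(1/beta)`.
#'
#' @param beta Stability exponent in (1, 2].
#' @return Positive scalar.
#' @export
mantegna_sigma <- function(beta) {
  if (!(beta > 1 && beta <= 2)) stop("beta must be in (1, 2]")
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Draw a Levy-flight step vector
#'
#' Mantegna construction: `step = scale * u / |v|^(1/beta)` with
#' `u ~ N(0, sigma_u^2)` and `v ~ N(0, 1)`. Heavy-tailed, so occasional
#' long jumps let the exploitation phase escape local optima. Draws from
#' the ambient RNG stream (seed it, or call inside a seeded optimizer run,
#' for reproducibility).
#'
#' @param dim Vector length.
#' @param beta Stability exponent in (1, 2].
#' @param scale Step multiplier.
#' @return Numeric vector of length `dim`.
#' @export
levy_step <- function(dim, beta = 1.5, scale = 0.05) {
  sigma_u <- mantegna_sigma(beta)
  u <- stats::rnorm(dim, 0, sigma_u)
  v <- stats::rnorm(dim)
  scale * u / abs(v)^(1 / beta)
}

#' BWO configuration
#'
#' @param pop_size Whale count (`>= 2`).
#' @param max_iter Iteration budget `T_max` (the convergence studies on the
#'   real NIR datasets stabilize by 500 iterations, the default).
#' @param lower,upper Continuous position bounds. The default `[-1, 1]`
#'   keeps positions in the responsive region of the transfer functions:
#'   under a V-shaped rule the transfer value is the per-channel flip
#'   (mutation) probability, so typical position magnitudes set the
#'   mutation rate of the discrete search — with wide bounds (e.g.
#'   `[-6, 6]`) almost every channel flips every generation and the
#'   V-shaped search degenerates to density-preserving noise that cannot
#'   settle on a small variable subset.
#' @param levy_beta,levy_scale Levy-flight stability exponent and
#'   multiplier.
#' @param wf_start,wf_end Whale-fall probability at the first and last
#'   iteration (linear decay, default 0.1 to 0.05).
#' @param seed Integer seed governing the whole optimizer run.
#' @return A `bwo_config` list.
#' @export
bwo_config <- function(pop_size = 30L, max_iter = 500L,
                       lower = -1, upper = 1,
                       levy_beta = 1.5, levy_scale = 0.05,
                       wf_start = 0.1, wf_end = 0.05, seed = 1L) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (!(lower < upper)) stop("lower must be < upper")
  if (!(levy_beta > 1 && levy_beta <= 2)) stop("levy_beta must be in (1, 2]")
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 lower = lower, upper = upper,
                 levy_beta = levy_beta, levy_scale = levy_scale,
                 wf_start = wf_start, wf_end = wf_end,
                 seed = as.integer(seed)),
            class = "bwo_config")
}

# Ensure a mask keeps at least n_lv channels active: activate
# uniformly-random additional channels among the zeros.
guard_min_ones <- function(bits, n_lv) {
  need <- n_lv - sum(bits)
  if (need > 0) {
    zeros <- which(!bits)
    bits[zeros[sample.int(length(zeros))[seq_len(need)]]] <- TRUE
  }
  bits
}

#' Binarize a continuous whale position
#'
#' S-shaped rule (`sigmoid`): `bit_j = 1` iff `rand_j < transfer(x_j)`.
#' V-shaped rule (`V1`/`V2`): `bit_j` is the previous bit, flipped iff
#' `rand_j < transfer(x_j)`. If fewer than `n_lv` bits survive, random
#' additional channels are activated so the PLS fitness stays defined.
#' Consumes the ambient RNG stream.
#'
#' @param position_row Continuous position vector.
#' @param previous_bits Logical vector, same length (used by V-shaped
#'   rules).
#' @param tf Transfer kind, see [transfer()].
#' @param n_lv Minimum number of active channels.
#' @return Logical mask.
#' @export
binarize <- function(position_row, previous_bits, tf, n_lv) {
  if (length(position_row) != length(previous_bits))
    stop("position and previous bits differ in length")
  pr <- transfer(position_row, tf)
  r <- stats::runif(length(pr))
  bits <- if (tf == "sigmoid") r < pr
          else ifelse(r < pr, !previous_bits, as.logical(previous_bits))
  guard_min_ones(bits, n_lv)
}

#' Advance the whale population by one generation
#'
#' Draws a balance factor per whale, applies the exploration
#' (`B_f > 0.5`) or exploitation move to the continuous positions, applies
#' whale-fall replacement to whales with `B_f <= W_f`, clamps to bounds,
#' binarizes each row, and accepts each whale's new position greedily (kept
#' only if its fitness is not worse). The incumbent best is therefore
#' monotone non-increasing. Consumes the ambient RNG stream.
#'
#' @param state Whale state as produced by [dbwo_select()]'s initializer
#'   (fields `positions`, `bits`, `fitness`, `best_bits`, `best_position`,
#'   `best_fitness`, `iteration`, `n_lv`, `wf_count`).
#' @param cfg A [bwo_config()].
#' @param fitness_fn Function mapping a logical mask (`>= n_lv` ones) to a
#'   finite fitness (lower is better).
#' @param tf Transfer kind.
#' @return The updated state.
#' @export
bwo_iterate <- function(state, cfg, fitness_fn, tf = "V2") {
  pos <- state$positions
  pop <- nrow(pos); p <- ncol(pos)
  T_cur <- state$iteration + 1L
  T_max <- cfg$max_iter
  B0 <- stats::runif(pop)
  Bf <- B0 * (1 - T_cur / (2 * T_max))
  Wf <- cfg$wf_start - (cfg$wf_start - cfg$wf_end) * T_cur / T_max
  newpos <- pos
  trig <- ifelse(seq_len(p) %% 2 == 0, 1, 0)  # even slots sine, odd cosine
  for (i in seq_len(pop)) {
    if (Bf[i] > 0.5) {                      # exploration: swim with a peer
      r_w <- sample.int(pop, 1)
      pj <- sample.int(p)                   # random pairing of dimensions
      r1 <- stats::runif(1); r2 <- stats::runif(1)
      s <- ifelse(trig == 1, sin(2 * pi * r2), cos(2 * pi * r2))
      newpos[i, pj] <- pos[i, pj] +
        (pos[r_w, pj[1]] - pos[i, pj]) * (1 + r1) * s
    } else {                                # exploitation: prey near best
      r3 <- stats::runif(1); r4 <- stats::runif(1)
      C1 <- 2 * r4 * (1 - T_cur / T_max)
      lf <- levy_step(p, cfg$levy_beta, cfg$levy_scale)
      r_w <- sample.int(pop, 1)
      newpos[i, ] <- r3 * state$best_position - r4 * pos[i, ] +
        C1 * lf * (pos[r_w, ] - pos[i, ])
    }
  }
  fall <- which(Bf <= Wf)                   # whale fall: re-seed the weak
  if (length(fall) > 0) {
    C2 <- 2 * Wf * pop
    x_step <- (cfg$upper - cfg$lower) * exp(-C2 * T_cur / T_max)
    for (i in fall) {
      r567 <- stats::runif(3)
      r_w <- sample.int(pop, 1)
      newpos[i, ] <- r567[1] * newpos[i, ] - r567[2] * newpos[r_w, ] +
        r567[3] * x_step
    }
    state$wf_count <- state$wf_count + length(fall)
  }
  newpos <- pmin(pmax(newpos, cfg$lower), cfg$upper)
  for (i in seq_len(pop)) {
    nb <- binarize(newpos[i, ], state$bits[i, ], tf, state$n_lv)
    f <- tryCatch(fitness_fn(nb), error = function(e)
      stop("fitness evaluation failed for whale ", i, ": ",
           conditionMessage(e)))
    if (!is.finite(f)) stop("non-finite fitness for whale ", i)
    if (f <= state$fitness[i]) {            # greedy elitist acceptance
      state$positions[i, ] <- newpos[i, ]
      state$bits[i, ] <- nb
      state$fitness[i] <- f
      if (f < state$best_fitness) {
        state$best_fitness <- f
        state$best_bits <- nb
        state$best_position <- newpos[i, ]
      }
    }
  }
  state$iteration <- T_cur
  state
}

#' DBWO-PLS wavelength selection
#'
#' The full discretized-BWO driver: initializes `pop_size` whales at
#' uniform-random continuous positions (and random initial masks), then for
#' `max_iter` generations updates positions by BWO, maps them to masks
#' through the chosen transfer function, scores each mask by the MCCV
#' RMSECV of a PLS model restricted to it (a fixed latent-variable count
#' and one shared MCCV plan, so all subset comparisons are paired), and
#' accepts greedily. Fitness values are cached per mask, so re-visited
#' masks cost nothing. The incumbent mask, its fitness, and the
#' per-generation best-fitness curve are returned; the curve is monotone
#' non-increasing by construction.
#'
#' @param x A `spectral_dataset` (its `X`/`y` are used) or a predictor
#'   matrix.
#' @param y Response vector (ignored when `x` is a dataset).
#' @param n_lv Latent-variable count used in every fitness evaluation.
#' @param cfg A [bwo_config()]; its `seed` fixes the whole run.
#' @param tf Transfer kind (`"V2"` default — the tanh-based V-shape, the
#'   best performer of the three).
#' @param plan [mccv_plan()] shared by every fitness evaluation.
#' @return A `selection_result` with `method = "DBWO"`, the best mask, the
#'   incumbent continuous position as `score_per_channel`, the per-
#'   iteration best-RMSECV `fitness_curve` (length `max_iter + 1`,
#'   starting at the initial population's best), `best_fitness`, and the
#'   whale-fall event count `wf_count`.
#' @export
dbwo_select <- function(x, y = NULL, n_lv, cfg = bwo_config(),
                        tf = c("V2", "V1", "sigmoid"),
                        plan = mccv_plan(n_repeats = 10, seed = cfg$seed)) {
  tf <- match.arg(tf)
  if (inherits(x, "spectral_dataset")) {
    y <- x$y
    x <- x$X
  }
  X <- as.matrix(x)
  n <- nrow(X); p <- ncol(X)
  if (n_lv < 1 || n_lv > min(n - 1, p)) stop("infeasible n_lv")
  splits <- mccv_splits(n, plan)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fitness_fn <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- rmsecv_over_splits(X, y, n_lv, splits, mask = bits)
    cache[[key]] <- val
    val
  }
  with_local_seed(cfg$seed, {
    positions <- matrix(stats::runif(cfg$pop_size * p, cfg$lower, cfg$upper),
                        cfg$pop_size, p)
    bits <- matrix(FALSE, cfg$pop_size, p)
    for (i in seq_len(cfg$pop_size))
      bits[i, ] <- guard_min_ones(stats::runif(p) < 0.5, n_lv)
    fitness <- vapply(seq_len(cfg$pop_size),
                      function(i) fitness_fn(bits[i, ]), numeric(1))
    ib <- which.min(fitness)
    state <- list(positions = positions, bits = bits, fitness = fitness,
                  best_bits = bits[ib, ], best_position = positions[ib, ],
                  best_fitness = fitness[ib], iteration = 0L,
                  n_lv = as.integer(n_lv), wf_count = 0L)
    curve <- numeric(cfg$max_iter + 1)
    curve[1] <- state$best_fitness
    for (t in seq_len(cfg$max_iter)) {
      state <- bwo_iterate(state, cfg, fitness_fn, tf)
      curve[t + 1] <- state$best_fitness
    }
    selection_result(state$best_bits, "DBWO", state$best_position,
                     threshold = NA_real_, seed = cfg$seed,
                     fitness_curve = curve,
                     extra = list(best_fitness = state$best_fitness,
                                  wf_count = state$wf_count,
                                  tf = tf, n_lv = as.integer(n_lv)))
  })
}
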