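test_that("transfer functions hit their closed-form anchors", {
  expect_equal(transfer(0, "sigmoid"), 0.5)
  expect_equal(transfer(0, "V1"), 0)
  expect_equal(transfer(0, "V2"), 0)
  expect_equal(transfer(1, "V2"), abs(tanh(1)))     # ~0.76159
  expect_equal(transfer(1, "V1"),
               abs(2 * pnorm(sqrt(pi) / 2 * sqrt(2)) - 1))
  x <- seq(-8, 8, length.out = 101)
  for (k in c("sigmoid", "V1", "V2")) {
    v <- transfer(x, k)
    expect_true(all(v >= 0 & v <= 1))
  }
  # V-shapes are even, sigmoid is not
  expect_equal(transfer(x, "V1"), transfer(-x, "V1"))
  expect_equal(transfer(x, "V2"), transfer(-x, "V2"))
  expect_error(transfer(Inf, "V2"), "finite")
})

test_that("mantegna levy steps have the right scale and heavy tails", {
  expect_equal(mantegna_sigma(1.5), 0.6966, tolerance = 1e-4)
  set.seed(61)
  a <- levy_step(10, 1.5, 0.05)
  set.seed(61)
  expect_identical(levy_step(10, 1.5, 0.05), a)
  expect_error(levy_step(10, beta = 2.5), "beta")
  set.seed(62)
  draws <- levy_step(1e5, 1.5, 1)
  z <- (draws - mean(draws)) / sd(draws)
  excess_kurtosis <- mean(z^4) - 3
  expect_gt(excess_kurtosis, 10)   # far beyond any Gaussian sample
})

test_that("binarize follows the S/V semantics and the minimum guard", {
  set.seed(63)
  prev <- rep(c(TRUE, FALSE), 10)
  # V-shape at the origin: transfer = 0, no flips possible
  expect_identical(binarize(rep(0, 20), prev, "V2", 1), prev)
  # S-shape saturated positive: all ones
  expect_true(all(binarize(rep(50, 20), prev, "sigmoid", 1)))
  # all-zero outcome triggers the guard with exactly n_lv random bits
  b <- binarize(rep(0, 20), rep(FALSE, 20), "V1", 5)
  expect_equal(sum(b), 5)
  expect_error(binarize(rep(0, 3), prev, "V2", 1), "length")
})

test_that("bwo_iterate keeps invariants under a cheap fitness", {
  # fitness = number of active channels: a pure minimization toy that lets
  # the population iterate many generations instantly
  fit_ones <- function(bits) sum(bits) + 0.001
  cfg <- bwo_config(pop_size = 8, max_iter = 50, seed = 5)
  set.seed(cfg$seed)
  p <- 30
  positions <- matrix(runif(8 * p, cfg$lower, cfg$upper), 8, p)
  bits <- matrix(runif(8 * p) < 0.5, 8, p)
  for (i in 1:8) bits[i, ] <- bits[i, ] | (seq_len(p) <= 2)
  fitness <- apply(bits, 1, fit_ones)
  ib <- which.min(fitness)
  state <- list(positions = positions, bits = bits, fitness = fitness,
                best_bits = bits[ib, ], best_position = positions[ib, ],
                best_fitness = fitness[ib], iteration = 0L, n_lv = 2L,
                wf_count = 0L)
  prev_best <- state$best_fitness
  for (t in 1:50) {
    state <- bwo_iterate(state, cfg, fit_ones, "V2")
    expect_lte(state$best_fitness, prev_best)
    prev_best <- state$best_fitness
    expect_true(all(state$positions >= cfg$lower &
                      state$positions <= cfg$upper))
    expect_true(all(rowSums(state$bits) >= 2))
  }
  expect_equal(state$iteration, 50L)
  # the toy optimum (n_lv ones) should be nearly reached
  expect_lte(state$best_fitness, 6)
})

test_that("a zero whale-fall schedule never triggers replacements", {
  fit_ones <- function(bits) sum(bits) + 0.001
  cfg <- bwo_config(pop_size = 6, max_iter = 30, wf_start = 0,
                    wf_end = 0, seed = 2)
  set.seed(2)
  p <- 20
  bits <- matrix(runif(6 * p) < 0.5, 6, p)
  bits[, 1] <- TRUE
  state <- list(positions = matrix(runif(6 * p, -1, 1), 6, p), bits = bits,
                fitness = apply(bits, 1, fit_ones),
                best_bits = bits[1, ], best_position = runif(p, -1, 1),
                best_fitness = fit_ones(bits[1, ]), iteration = 0L,
                n_lv = 1L, wf_count = 0L)
  for (t in 1:30) state <- bwo_iterate(state, cfg, fit_ones, "V2")
  expect_equal(state$wf_count, 0L)
})

test_that("dbwo_select is reproducible and monotone on real fitness", {
  b <- planted_band_benchmark(3)
  ds <- b$dataset
  X <- ds$X[1:30, seq(1, 200, by = 4)]     # 30 x 50 subproblem for speed
  y <- ds$y[1:30]
  cfg <- bwo_config(pop_size = 5, max_iter = 8, seed = 11)
  plan <- mccv_plan(3, 0.8, seed = 11)
  r1 <- dbwo_select(X, y, 3, cfg, "V2", plan)
  r2 <- dbwo_select(X, y, 3, cfg, "V2", plan)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$fitness_curve, r2$fitness_curve)
  expect_length(r1$fitness_curve, 9)
  expect_true(all(diff(r1$fitness_curve) <= 0))
  expect_gte(sum(r1$mask), 3)
  expect_equal(r1$method, "DBWO")
  expect_equal(r1$best_fitness, min(r1$fitness_curve))
  # dataset-flavored call agrees with the matrix call
  sub <- spectral_dataset(X, ds$wavelengths[seq(1, 200, by = 4)], y)
  r3 <- dbwo_select(sub, n_lv = 3, cfg = cfg, tf = "V2", plan = plan)
  expect_identical(r3$mask, r1$mask)
  expect_error(dbwo_select(X, y, 60, cfg, "V2", plan), "n_lv")
})
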