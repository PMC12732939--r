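test_that("the noiseless artifact-free limit is exactly linear", {
  grid <- make_wavelength_grid(1100, 1298, 2)
  spec <- synthetic_spec(30L, grid,
                         band_centers = list(1150, 1220, 1270),
                         band_widths = list(20, 25, 15),
                         band_heights = list(1, 0.8, 1.2),
                         target_component = 2L, seed = 10)
  out <- generate_spectra(spec)
  ds <- out$dataset
  expect_lt(rmsecv(ds$X, ds$y, 3, mccv_plan(5, 0.8, 1)), 1e-6)
  # rank equals component count: LV selection recovers it
  expect_equal(select_lv_mccv(ds$X, ds$y, 5, mccv_plan(5, 0.8, 2))$n_lv, 3L)
})

test_that("generation is a pure function of the spec", {
  a <- planted_band_benchmark(7)
  b <- planted_band_benchmark(7)
  expect_identical(a$dataset$X, b$dataset$X)
  expect_identical(a$dataset$y, b$dataset$y)
  expect_identical(a$informative_mask, b$informative_mask)
  expect_false(identical(a$dataset$X, planted_band_benchmark(8)$dataset$X))
})

test_that("snv preprocessing pays off on scatter-corrupted spectra", {
  # dominant-scatter regime: constituent concentrations vary a few percent
  # around a typical composition while baseline and multiplicative scatter
  # are the main between-sample variation — the setting snv exists for
  grid <- make_wavelength_grid(1100, 1298, 2)
  wins <- vapply(1:10, function(s) {
    spec <- synthetic_spec(40L, grid,
                           band_centers = list(1150, 1220, 1270),
                           band_widths = list(20, 25, 15),
                           band_heights = list(1, 0.8, 1.2),
                           target_component = 2L,
                           conc_range = c(0.95, 1.05),
                           baseline_amp = 0.5, scatter_slope_sd = 0.2,
                           noise_sd = 0, seed = s)
    ds <- generate_spectra(spec)$dataset
    plan <- mccv_plan(8, 0.8, s)
    rmsecv(snv(ds$X), ds$y, 3, plan) < rmsecv(ds$X, ds$y, 3, plan)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("the planted-band benchmark has its documented geometry", {
  b <- planted_band_benchmark(1)
  expect_equal(n_channels(b$dataset), 200)
  expect_equal(n_samples(b$dataset), 60)
  expect_gte(sum(b$informative_mask), 10)
  expect_lte(sum(b$informative_mask), 20)
  # informative channels sit within two widths of the 1300 nm target band
  wl <- b$dataset$wavelengths
  expect_true(all(abs(wl[b$informative_mask] - 1300) <= 16))
})

test_that("the benchmark supports a strong full-spectrum calibration", {
  r2 <- vapply(1:10, function(s) {
    b <- planted_band_benchmark(s)
    ds <- b$dataset
    sp <- kennard_stone_split(ds$X, 2 / 3)
    fit <- fit_pls(ds$X[sp$train_idx, ], ds$y[sp$train_idx], 4)
    r_squared(ds$y[sp$test_idx],
              predict(fit, ds$X[sp$test_idx, ]))
  }, numeric(1))
  expect_true(all(r2 > 0.8))
})

test_that("spec validation catches out-of-range bands and bad magnitudes", {
  grid <- make_wavelength_grid(1100, 1200, 2)
  expect_error(synthetic_spec(10, grid, band_centers = list(1500),
                              band_widths = list(10),
                              band_heights = list(1)), "outside")
  expect_error(synthetic_spec(10, grid, band_centers = list(1150),
                              band_widths = list(10),
                              band_heights = list(1), noise_sd = -1),
               ">= 0")
  expect_error(synthetic_spec(10, grid, band_centers = list(1150),
                              band_widths = list(10),
                              band_heights = list(1),
                              target_component = 3), "target_component")
})
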