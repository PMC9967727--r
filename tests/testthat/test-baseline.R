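test_that("a flat spectrum is reduced to (numerically) nothing", {
  s <- spectrum(default_grid(), rep(5, length(default_grid())))
  out <- subtract_baseline(s)
  expect_lt(max(abs(out$intensity)), 1e-6 * 5)
})

test_that("a slowly varying quadratic background is removed almost completely", {
  grid <- default_grid()
  bg <- 10 + 5e-6 * (grid - 400)^2   # max ~ 19.8 a.u.
  out <- subtract_baseline(spectrum(grid, bg))
  expect_lt(max(abs(out$intensity)), 0.02 * max(bg))
})

test_that("a Lorentzian peak survives baseline removal within 5% of its height", {
  grid <- default_grid()
  peak <- 2 * peak_profile(peak_spec(1000, fwhm = 12), grid)
  bg <- 10 + 5e-6 * (grid - 400)^2
  out <- subtract_baseline(spectrum(grid, peak + bg))
  recovered <- max(out$intensity[abs(grid - 1000) <= 10])
  expect_lt(abs(recovered - 2) / 2, 0.05)
})

test_that("baseline subtraction of compact bands is idempotent within 1% RMS", {
  # idempotence holds where the residual consists of bands much narrower
  # than the smoother's stiffness scale; Lorentzian tails and broad
  # organics structure keep being shaved slightly on re-application
  # (see the methods vignette)
  grid <- default_grid()
  y <- 2 * peak_profile(peak_spec(1000, fwhm = 12, shape = "gaussian"), grid) + 1
  once <- subtract_baseline(spectrum(grid, y))
  twice <- subtract_baseline(once)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(twice$intensity - once$intensity), 0.01 * rms(once$intensity))
})

test_that("baseline parameters are validated", {
  s <- spectrum(seq(400, 500, 2), rnorm(51))
  expect_error(subtract_baseline(s, lambda = -1), "lambda")
  expect_error(subtract_baseline(s, p = 0), "p must")
  expect_error(subtract_baseline(s, p = 1), "p must")
  expect_error(baseline_als(rnorm(5)), ">= 10")
})

test_that("the effective reference stays unit-max and keeps the band positions", {
  ref <- antibiotic_references()$enrofloxacin
  eff <- effective_reference(ref)
  expect_equal(max(eff$intensity), 1)
  expect_true(all(eff$intensity >= 0))
  raw <- build_reference_spectrum(ref)
  keep <- raw$intensity > 0.2
  expect_gt(cor(eff$intensity[keep], raw$intensity[keep]), 0.99)
})
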