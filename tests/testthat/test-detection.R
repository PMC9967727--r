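refs <- antibiotic_references()

test_that("noiseless high-concentration spectra fire both enrofloxacin bands", {
  mm <- water_matrix_model()
  mm$noise_sigma <- 0; mm$fluor_sdlog <- 0; mm$matrix_sdlog <- 0
  s <- subtract_baseline(simulate_spectrum(refs$enrofloxacin, 50, mm, seed = 1))
  calls <- call_peaks(s, refs$enrofloxacin)
  expect_true(all(calls$found))
  expect_true(attr(calls, "identified"))
  expect_setequal(calls$center, c(1390, 1624))
})

test_that("an all-zero spectrum yields no peak calls", {
  s <- spectrum(default_grid(), rep(0, length(default_grid())))
  calls <- call_peaks(s, refs$neomycin)
  expect_false(any(calls$found))
  expect_false(attr(calls, "identified"))
})

test_that("the MAD-based SNR is calibrated: a 10-sigma peak reads near 10", {
  grid <- default_grid()
  ref <- reference_definition("probe", list(peak_spec(1000, fwhm = 12)),
                              identification_peaks = 1000)
  snrs <- vapply(1:100, function(i) {
    withr::with_seed(i, y <- rnorm(length(grid), sd = 0.02))
    y <- y + 0.2 * peak_profile(peak_spec(1000, fwhm = 12), grid)
    call_peaks(spectrum(grid, y), ref, known_bands = numeric(0))$snr
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 10) / 10, 0.2)
})

test_that("a window wider than the grid is rejected", {
  s <- spectrum(seq(990, 1010, 2), rep(0, 11))
  ref <- reference_definition("probe", list(peak_spec(1000, fwhm = 6)),
                              identification_peaks = 1000)
  expect_error(call_peaks(s, ref, window_cm1 = 50), "window")
})

test_that("zero-noise dilution series detects down to the lowest tested level", {
  mm <- water_matrix_model()
  mm$noise_sigma <- 0; mm$fluorescence <- list(); mm$matrix_peaks <- list()
  mm$baseline_offset <- 0; mm$baseline_slope <- 0
  cond <- data.frame(label = sprintf("c%g", c(0.01, 0.1, 1)),
                     analyte = "enrofloxacin",
                     concentration_ppm = c(0.01, 0.1, 1), n_replicates = 2)
  ds <- generate_dataset(dataset_design(cond, mm, seed = 1))
  lr <- lod_univariate(ds, refs$enrofloxacin)
  expect_equal(lr$lod, 0.01)
})

test_that("signal-free series never reach a detection and report so", {
  mm <- water_matrix_model()
  cond <- data.frame(label = sprintf("c%g", c(1, 10)), analyte = "none",
                     concentration_ppm = c(1, 10), n_replicates = 3)
  ds <- generate_dataset(dataset_design(cond, mm, seed = 1))
  lr <- lod_univariate(ds, refs$enrofloxacin)
  expect_false(lr$reached)
  expect_output(print(lr), "not reached")
})

test_that("a blanks-only pool gives an unreached unmixing LOD", {
  cond <- data.frame(label = "blank", analyte = "none",
                     concentration_ppm = 0, n_replicates = 12)
  ds <- generate_dataset(dataset_design(cond, water_matrix_model(), seed = 2))
  lr <- lod_mcr(ds, refs, config = mcr_config(3, max_iter = 200))
  expect_false(lr$reached)
})

test_that("raising the noise never lowers the univariate LOD", {
  lods <- vapply(c(0.02, 0.06, 0.18), function(sg) {
    mm <- water_matrix_model()
    mm$noise_sigma <- sg
    cond <- data.frame(label = sprintf("c%g", c(0.1, 0.5, 2, 10)),
                       analyte = "enrofloxacin",
                       concentration_ppm = c(0.1, 0.5, 2, 10),
                       n_replicates = 4)
    ds <- generate_dataset(dataset_design(cond, mm, seed = 6))
    lr <- lod_univariate(ds, refs$enrofloxacin)
    if (lr$reached) lr$lod else Inf
  }, numeric(1))
  expect_true(all(diff(lods) >= 0))
})

test_that("concentration trends handle ties through average ranks", {
  fit <- structure(list(C = cbind(c(1, 1.05, 2, 2.1, 5, 5.2)),
                        S = matrix(1, 1, 10), grid = 1:10,
                        config = mcr_config(1)), class = "mcr_result")
  asg <- data.frame(analyte = "enrofloxacin", component = 1L,
                    similarity = 1, assigned = TRUE)
  man <- data.frame(sample_id = letters[1:6], analyte = "enrofloxacin",
                    concentration_ppm = c(1, 1, 5, 5, 10, 10),
                    condition = "spiked", replicate = 1:6)
  tr <- concentration_trend(fit, asg, man)
  expect_equal(tr$spearman_rho, 1)
  asg$assigned <- FALSE
  expect_error(concentration_trend(fit, asg, man), "not assigned")
})

test_that("shuffled concentration labels destroy the rank correlation", {
  run <- spiked_mcr_run()
  lr <- run$lod
  man <- run$ds$manifest
  fit <- lr$details$fit
  asg <- lr$details$assignment
  tr <- concentration_trend(fit, asg, man, intensity = lr$details$intensity)
  expect_equal(tr$spearman_rho, 1)
  # per-sample rank correlation under label permutation collapses to noise
  test <- man$concentration_ppm > 0 & man$condition != "standard"
  int <- lr$details$intensity[test]
  conc <- man$concentration_ppm[test]
  rhos <- vapply(1:100, function(i) {
    withr::with_seed(i, perm <- sample(conc))
    suppressWarnings(cor(rank(perm), rank(int)))
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.3)
})

test_that("identical conditions are flagged as not separable", {
  withr::with_seed(1, intensity <- rnorm(30, mean = 5))
  fit <- structure(list(C = cbind(intensity), S = matrix(1, 1, 4),
                        grid = 1:4, config = mcr_config(1)),
                   class = "mcr_result")
  asg <- data.frame(analyte = "enrofloxacin", component = 1L,
                    similarity = 1, assigned = TRUE)
  man <- data.frame(sample_id = as.character(1:30), analyte = "enrofloxacin",
                    concentration_ppm = 1,
                    condition = rep(c("control", "day1", "day7"), each = 10),
                    replicate = 1:30)
  cc <- compare_conditions(fit, asg, man)
  expect_false(cc$separable)
  expect_error(compare_conditions(fit, asg, man,
                                  conditions = c("control", "day9")),
               "absent")
})

test_that("screening at MRL 100 ppm calls 10-100 ppm compliant and 10,000 ppm positive", {
  run <- spiked_mcr_run()
  lr <- run$lod
  rep <- screen_samples(lr$details$fit, lr$details$assignment,
                        run$ds$manifest, mrl = 100,
                        intensity = lr$details$intensity)
  low <- rep$concentration_ppm <= 100
  expect_true(all(rep$call[low] != "positive"))
  expect_true(all(rep$detected[rep$concentration_ppm >= 10]))
  expect_true(all(rep$call[rep$concentration_ppm == 10000] == "positive"))
  expect_equal(attr(rep, "mrl"), 100)
})

test_that("pooling never hurts: unmixing LOD <= univariate LOD in water", {
  run <- water_mcr_run()
  uni <- lod_univariate(run$ds, refs$enrofloxacin)
  expect_true(uni$reached && run$lod$reached)
  expect_lte(run$lod$lod, uni$lod)
})
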