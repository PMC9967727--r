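refs <- antibiotic_references()

test_that("identical seeds give bit-identical spectra and datasets", {
  mm <- urine_matrix_model()
  s1 <- simulate_spectrum(refs$enrofloxacin, 5, mm, seed = 42)
  s2 <- simulate_spectrum(refs$enrofloxacin, 5, mm, seed = 42)
  expect_identical(s1$intensity, s2$intensity)

  des <- scenario_design("water_dilution", seed = 7)
  d1 <- generate_dataset(des)
  d2 <- generate_dataset(des)
  dir1 <- tempfile(); dir2 <- tempfile()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("zero concentration with a silent matrix gives the zero spectrum", {
  mm <- matrix_model(noise_sigma = 0, response_coeff = 1)
  s <- simulate_spectrum(refs$enrofloxacin, 0, mm, seed = 1)
  expect_true(all(s$intensity == 0))
})

test_that("doubling the concentration doubles the analyte signal in the linear regime", {
  mm <- matrix_model(noise_sigma = 0, response_coeff = 1,
                     saturation_conc = NULL)
  s1 <- simulate_spectrum(refs$enrofloxacin, 1, mm, seed = 1)
  s2 <- simulate_spectrum(refs$enrofloxacin, 2, mm, seed = 1)
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-12)
})

test_that("noiseless analyte peak height is non-decreasing in concentration", {
  mm <- water_matrix_model()
  mm$noise_sigma <- 0
  mm$fluor_sdlog <- 0
  mm$matrix_sdlog <- 0
  heights <- vapply(c(0.01, 0.1, 0.5, 1, 5, 20, 100, 1000, 5000), function(cc) {
    s <- simulate_spectrum(refs$enrofloxacin, cc, mm, seed = 3)
    s$intensity[s$wavenumber == 1390]
  }, numeric(1))
  expect_true(all(diff(heights) >= 0))
})

test_that("the saturating response keeps 10,000 ppm in the supra-linear regime", {
  g <- response_curve(c(10, 10000), saturation_conc = 2000)
  expect_equal(g[1], 10 / 1.005)
  expect_lt(g[2] / g[1], 1000)   # far below the linear 1000x ratio
  expect_identical(response_curve(7, NULL), 7)
})

test_that("scenario designs generate the packaged row counts", {
  water <- generate_dataset(scenario_design("water_dilution", seed = 1))
  expect_equal(nrow(water$intensities), 59)

  spiked <- generate_dataset(scenario_design("spiked_urine", seed = 1))
  spk <- spiked$manifest$condition %in% sprintf("spiked%g", c(10, 20, 50, 100, 10000))
  expect_equal(sum(spk), 250)   # 5 levels x 50 replicates
  expect_equal(sort(unique(spiked$manifest$concentration_ppm[spk])),
               c(10, 20, 50, 100, 10000))

  vivo <- generate_dataset(scenario_design("in_vivo", seed = 1))
  expect_equal(nrow(vivo$intensities), 53)
  expect_setequal(unique(vivo$manifest$condition), c("control", "day1", "day7"))
})

test_that("row count equals the sum of replicates for arbitrary designs", {
  cond <- data.frame(label = c("a", "b"), analyte = c("none", "neomycin"),
                     concentration_ppm = c(0, 5), n_replicates = c(3, 4))
  ds <- generate_dataset(dataset_design(cond, water_matrix_model(), seed = 2))
  expect_equal(nrow(ds$intensities), 7)
  one <- generate_dataset(dataset_design(
    data.frame(label = "x", analyte = "none", concentration_ppm = 0,
               n_replicates = 1), water_matrix_model(), seed = 2))
  expect_equal(nrow(one$intensities), 1)
})

test_that("invalid designs and parameters are rejected", {
  expect_error(simulate_spectrum(refs$enrofloxacin, -1, water_matrix_model(),
                                 seed = 1), "concentration")
  expect_error(matrix_model(noise_sigma = -1), "noise_sigma")
  expect_error(matrix_model(response_coeff = 0), "response_coeff")
  expect_error(matrix_model(fluorescence = list(peak_spec(900, fwhm = 50))),
               "broad")
  cond <- data.frame(label = "x", analyte = "none",
                     concentration_ppm = -2, n_replicates = 1)
  expect_error(dataset_design(cond, water_matrix_model()), "concentrations")
  cond$concentration_ppm <- 1; cond$n_replicates <- 0
  expect_error(dataset_design(cond, water_matrix_model()), "n_replicates")
  expect_error(generate_dataset(dataset_design(
    data.frame(label = "x", analyte = "nosuchdrug", concentration_ppm = 1,
               n_replicates = 1), water_matrix_model())), "nosuchdrug")
})

test_that("the water calibration contract brackets the per-spectrum detection threshold", {
  # all replicates identified at 0.5 ppm, (almost) none at 0.1 ppm
  ref <- refs$enrofloxacin
  mm <- water_matrix_model()
  hits <- function(conc) mean(vapply(1:20, function(i) {
    s <- simulate_spectrum(ref, conc, mm, seed = 1000 + i)
    is_identified(subtract_baseline(s), ref)
  }, logical(1)))
  expect_gte(hits(0.5), 0.95)
  expect_lte(hits(0.1), 0.2)
})
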