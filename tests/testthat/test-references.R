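test_that("reference spectra place their dominant band at the printed centre", {
  refs <- antibiotic_references()
  grid <- default_grid()
  step <- diff(grid)[1]
  expected <- c(enrofloxacin = 1390, oxytetracycline = 1315, neomycin = 977)
  for (an in names(expected)) {
    s <- build_reference_spectrum(refs[[an]], grid)
    expect_lte(abs(s$wavenumber[which.max(s$intensity)] - expected[[an]]),
               step / 2 + 1e-9)
    expect_equal(max(s$intensity), 1)
    expect_true(all(s$intensity >= 0))
    # identification peaks must be near-maximal bands
    for (ctr in refs[[an]]$identification_peaks) {
      idx <- which(abs(s$wavenumber - ctr) <= step)
      expect_gte(max(s$intensity[idx]), 0.9)
    }
  }
})

test_that("an empty peak list yields the all-zero spectrum", {
  ref <- reference_definition("blankref", peaks = list(peak_spec(800)),
                              identification_peaks = 800)
  ref$peaks <- list()
  s <- build_reference_spectrum(ref)
  expect_true(all(s$intensity == 0))
})

test_that("two well-separated unit Lorentzians both reach height 1 after normalization", {
  # closed form: at 500 cm-1 apart with fwhm 10 the mutual tail contribution
  # at each centre is (5^2)/(5^2 + 500^2) < 1e-4
  ref <- reference_definition(
    "pair", peaks = list(peak_spec(600, fwhm = 10), peak_spec(1100, fwhm = 10)),
    identification_peaks = c(600, 1100))
  s <- build_reference_spectrum(ref)
  h1 <- s$intensity[s$wavenumber == 600]
  h2 <- s$intensity[s$wavenumber == 1100]
  expect_equal(h1, 1, tolerance = 1e-3)
  expect_equal(h2, 1, tolerance = 1e-3)
})

test_that("construction validates peak geometry and identification subsets", {
  expect_error(peak_spec(800, fwhm = 0), "fwhm")
  expect_error(peak_spec(800, rel_amplitude = -1), "rel_amplitude")
  expect_error(reference_definition("x", list(peak_spec(800)),
                                    identification_peaks = c(800, 999)),
               "identification")
  expect_error(reference_definition("x", list(peak_spec(800)),
                                    identification_peaks = numeric(0)),
               "identification")
  ref <- antibiotic_references()$enrofloxacin
  expect_error(build_reference_spectrum(ref, grid = seq(400, 800, 2)),
               "enrofloxacin")
})

test_that("the enrofloxacin 1387 literature alias is recorded for the 1390 band", {
  ref <- antibiotic_references()$enrofloxacin
  expect_equal(unname(ref$aliases["1390"]), 1387)
})
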