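#' Describe the sample matrix and instrument response of a scenario
#'
#' Everything in a simulated spectrum that is not the analyte: broad
#' autofluorescence humps with per-sample log-normal amplitude jitter, sharp
#' matrix bands (e.g. the urea-region band near 1000 cm-1 in urine), a linear
#' instrument baseline, additive Gaussian channel noise, and the SERS
#' concentration response (linear at low concentration, Langmuir-saturating
#' around `saturation_conc`).
#'
#' @param fluorescence list of broad [peak_spec()] objects (fwhm >= 200 cm-1);
#'   `rel_amplitude` is the median amplitude in a.u.
#' @param fluor_sdlog log-normal sd of the per-sample fluorescence amplitude
#'   jitter (0 = fixed amplitudes).
#' @param matrix_peaks list of sharp matrix [peak_spec()] objects (a.u.),
#'   e.g. the urea-region band near 1000 cm-1 in urine or the carbonaceous
#'   substrate bands near 1350/1580 cm-1 on silver nanorod substrates.
#' @param matrix_sdlog log-normal sd of the per-sample matrix-band amplitude
#'   jitter (0 = fixed amplitudes).
#' @param organics list of medium-width [peak_spec()] objects representing
#'   the organic band pattern of the sample matrix (urine metabolites);
#'   all organics bands scale together with one common per-sample factor.
#' @param organics_sdlog log-normal sd of the shared organics scale factor
#'   (urine concentration varies between animals and days).
#' @param baseline_offset,baseline_slope linear baseline, a.u. and a.u. per
#'   cm-1 (slope applied relative to the grid minimum).
#' @param noise_sigma additive i.i.d. Gaussian noise SD, a.u. (>= 0).
#' @param response_coeff SERS response for a unit-response-factor analyte,
#'   a.u. per ppm (> 0).
#' @param saturation_conc Langmuir saturation scale in ppm, or `NULL` for a
#'   purely linear response.
#' @return An object of class `matrix_model`.
#' @export
matrix_model <- function(fluorescence = list(), fluor_sdlog = 0,
                         matrix_peaks = list(), matrix_sdlog = 0,
                         organics = list(), organics_sdlog = 0,
                         baseline_offset = 0, baseline_slope = 0,
                         noise_sigma = 0, response_coeff = 1,
                         saturation_conc = NULL) {
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop_sersmcr("noise_sigma must be >= 0")
  if (!is.finite(response_coeff) || response_coeff <= 0)
    stop_sersmcr("response_coeff must be > 0")
  for (p in fluorescence)
    if (p$fwhm < 200)
      stop_sersmcr("fluorescence components must be broad (fwhm >= 200 cm-1)")
  structure(list(fluorescence = fluorescence, fluor_sdlog = fluor_sdlog,
                 matrix_peaks = matrix_peaks, matrix_sdlog = matrix_sdlog,
                 organics = organics, organics_sdlog = organics_sdlog,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope,
                 noise_sigma = noise_sigma, response_coeff = response_coeff,
                 saturation_conc = saturation_conc),
            class = "matrix_model")
}

#' Concentration response with optional Langmuir saturation
#'
#' Effective (ppm-equivalent) signal level: `c / (1 + c / c_sat)`, linear for
#' `c << c_sat`.  With `saturation_conc = NULL` the response is the identity.
#'
#' @param conc concentration, ppm.
#' @param saturation_conc saturation scale, ppm, or `NULL`.
#' @return Effective concentration, ppm.
#' @export
response_curve <- function(conc, saturation_conc = NULL) {
  if (is.null(saturation_conc)) conc else conc / (1 + conc / saturation_conc)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Simulate one SERS spectrum
#'
#' The intensity model is
#' `response_coeff * response_factor * g(conc) * reference + fluorescence +
#' matrix peaks + linear baseline + Gaussian noise`, where `g` is
#' [response_curve()] and the reference is the unit-max spectrum built from
#' `ref`.  Identical seeds give bit-identical traces; the caller's RNG state
#' is untouched.
#'
#' @param ref a [reference_definition()], or `NULL` for a blank (no analyte).
#' @param conc nominal concentration, ppm (>= 0).
#' @param matrix a [matrix_model()].
#' @param seed integer seed for this spectrum.
#' @param grid wavenumber grid.
#' @param matrix_peak_scale multiplier on the sharp matrix-band amplitudes
#'   (per-condition variation, e.g. the stronger 1000 cm-1 band on day 7).
#' @param fluor_scale multiplier on the fluorescence amplitudes (0 turns the
#'   matrix background off, e.g. for standards measured in water).
#' @param response_scale extra multiplier on the concentration response.
#' @param ... metadata passed to [spectrum()].
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(ref, conc, matrix, seed, grid = default_grid(),
                              matrix_peak_scale = 1, fluor_scale = 1,
                              response_scale = 1, ...) {
  stopifnot(inherits(matrix, "matrix_model"))
  if (!is.finite(conc) || conc < 0)
    stop_sersmcr("concentration must be >= 0 ppm, got %s", format(conc))
  y <- rep(0, length(grid))
  if (!is.null(ref) && conc > 0) {
    refspec <- build_reference_spectrum(ref, grid)
    amp <- matrix$response_coeff * ref$response_factor * response_scale *
      response_curve(conc, matrix$saturation_conc)
    y <- y + amp * refspec$intensity
  }
  with_seed(seed, {
    for (p in matrix$fluorescence) {
      a <- p$rel_amplitude * fluor_scale
      if (matrix$fluor_sdlog > 0 && a > 0)
        a <- a * rlnorm(1, meanlog = -matrix$fluor_sdlog^2 / 2,
                        sdlog = matrix$fluor_sdlog)
      if (a > 0) {
        q <- p; q$rel_amplitude <- 1
        y <- y + a * peak_profile(q, grid)
      }
    }
    if (length(matrix$organics) && fluor_scale > 0) {
      a <- 1
      if (matrix$organics_sdlog > 0)
        a <- rlnorm(1, meanlog = -matrix$organics_sdlog^2 / 2,
                    sdlog = matrix$organics_sdlog)
      for (p in matrix$organics) y <- y + a * peak_profile(p, grid)
    }
    sdlogs <- rep(matrix$matrix_sdlog, length.out = length(matrix$matrix_peaks))
    for (pi in seq_along(matrix$matrix_peaks)) {
      p <- matrix$matrix_peaks[[pi]]
      a <- matrix_peak_scale
      if (sdlogs[pi] > 0 && a > 0)
        a <- a * rlnorm(1, meanlog = -sdlogs[pi]^2 / 2, sdlog = sdlogs[pi])
      if (a > 0) y <- y + a * peak_profile(p, grid)
    }
    y <- y + matrix$baseline_offset +
      matrix$baseline_slope * (grid - min(grid))
    if (matrix$noise_sigma > 0)
      y <- y + rnorm(length(grid), sd = matrix$noise_sigma)
  })
  spectrum(grid, y, analyte = if (is.null(ref)) "none" else ref$analyte,
           concentration_ppm = conc, ...)
}

#' Design a synthetic dataset
#'
#' `conditions` is a data frame with one row per experimental condition:
#' columns `label`, `analyte` (`"none"` for blanks), `concentration_ppm`,
#' `n_replicates`, and optionally `matrix_peak_scale`, `fluor_scale`,
#' `response_scale` (defaults 1).
#'
#' @param conditions condition table (see Details).
#' @param matrix a [matrix_model()].
#' @param grid wavenumber grid (strictly increasing).
#' @param seed master integer seed.
#' @return An object of class `dataset_design`.
#' @export
dataset_design <- function(conditions, matrix, grid = default_grid(),
                           seed = 1L) {
  conditions <- as.data.frame(conditions)
  req <- c("label", "analyte", "concentration_ppm", "n_replicates")
  missing <- setdiff(req, names(conditions))
  if (length(missing))
    stop_sersmcr("conditions lack columns: %s", paste(missing, collapse = ", "))
  if (any(conditions$concentration_ppm < 0))
    stop_sersmcr("concentrations must be >= 0")
  if (any(conditions$n_replicates < 1))
    stop_sersmcr("n_replicates must be >= 1")
  if (any(diff(grid) <= 0)) stop_sersmcr("grid must be strictly increasing")
  for (col in c("matrix_peak_scale", "fluor_scale", "response_scale"))
    if (is.null(conditions[[col]])) conditions[[col]] <- 1
  structure(list(conditions = conditions, matrix = matrix, grid = grid,
                 seed = as.integer(seed)),
            class = "dataset_design")
}

#' Generate the dataset described by a design
#'
#' One spectrum per (condition, replicate); the per-spectrum seed is derived
#' deterministically from the design seed and the row index, so the same
#' design always yields a byte-identical dataset.  The manifest records the
#' seed used for every spectrum.
#'
#' @param design a [dataset_design()].
#' @param references reference library used to draw analyte signal; defaults
#'   to [antibiotic_references()].
#' @return A [spectral_dataset()] whose manifest carries `label`, `analyte`,
#'   `concentration_ppm`, `condition`, `replicate` and `seed`.
#' @export
generate_dataset <- function(design, references = antibiotic_references()) {
  stopifnot(inherits(design, "dataset_design"))
  cond <- design$conditions
  rows <- list(); metas <- list()
  idx <- 0L
  for (ci in seq_len(nrow(cond))) {
    analyte <- cond$analyte[ci]
    ref <- if (identical(analyte, "none")) NULL else references[[analyte]]
    if (!identical(analyte, "none") && is.null(ref))
      stop_sersmcr("no reference definition for analyte '%s'", analyte)
    for (r in seq_len(cond$n_replicates[ci])) {
      idx <- idx + 1L
      sub_seed <- (design$seed + 7919L * idx) %% .Machine$integer.max
      s <- simulate_spectrum(
        ref, cond$concentration_ppm[ci], design$matrix, seed = sub_seed,
        grid = design$grid,
        matrix_peak_scale = cond$matrix_peak_scale[ci],
        fluor_scale = cond$fluor_scale[ci],
        response_scale = cond$response_scale[ci],
        sample_id = sprintf("%s_r%02d", cond$label[ci], r),
        condition = cond$label[ci], replicate = r)
      rows[[idx]] <- s$intensity
      metas[[idx]] <- data.frame(
        sample_id = s$meta$sample_id, analyte = analyte,
        concentration_ppm = cond$concentration_ppm[ci],
        condition = cond$label[ci], replicate = r, seed = sub_seed,
        stringsAsFactors = FALSE)
    }
  }
  spectral_dataset(do.call(rbind, rows), design$grid,
                   do.call(rbind, metas))
}

#' Packaged scenario designs
#'
#' Three study designs with frozen matrix-model calibrations:
#'
#' * `water_dilution`: ten blanks + ten concentrations (0.01--100 ppm) with
#'   four replicates each plus nine high-concentration standard spectra (59
#'   in total); quiet water matrix whose noise is calibrated so the
#'   per-spectrum peak signal-to-noise ratio of each analyte crosses the
#'   detection threshold at its empirical water detection limit.
#' * `spiked_urine`: enrofloxacin spiked at 10, 20, 50, 100 and 10,000 ppm
#'   with 50 replicates per level (250 spiked spectra), plus ten control-urine
#'   blanks and four standards; two broad jittering fluorescence humps mask
#'   the analyte bands in single spectra.
#' * `in_vivo`: control (13), day-1 (20) and day-7 (20) urine; day 7 carries a
#'   3x effective analyte level and a doubled 1000 cm-1 matrix band.
#'
#' @param scenario one of `"water_dilution"`, `"spiked_urine"`, `"in_vivo"`.
#' @param analyte analyte of the dilution/spiking series.
#' @param seed master seed.
#' @return A [dataset_design()].
#' @export
scenario_design <- function(scenario = c("water_dilution", "spiked_urine",
                                         "in_vivo"),
                            analyte = "enrofloxacin", seed = 1L) {
  scenario <- match.arg(scenario)
  switch(scenario,
    water_dilution = {
      concs <- c(0.01, 0.1, 0.5, 1, 2, 5, 10, 20, 50, 100)
      cond <- rbind(
        data.frame(label = "blank", analyte = "none", concentration_ppm = 0,
                   n_replicates = 10),
        data.frame(label = sprintf("c%g", concs), analyte = analyte,
                   concentration_ppm = concs, n_replicates = 4),
        data.frame(label = "standard", analyte = analyte,
                   concentration_ppm = 100, n_replicates = 9))
      dataset_design(cond, water_matrix_model(), seed = seed)
    },
    spiked_urine = {
      concs <- c(10, 20, 50, 100, 10000)
      cond <- rbind(
        data.frame(label = "blank", analyte = "none", concentration_ppm = 0,
                   n_replicates = 10, matrix_peak_scale = 1, fluor_scale = 1,
                   response_scale = 1),
        data.frame(label = sprintf("spiked%g", concs), analyte = analyte,
                   concentration_ppm = concs, n_replicates = 50,
                   matrix_peak_scale = 1, fluor_scale = 1, response_scale = 1),
        data.frame(label = "standard", analyte = analyte,
                   concentration_ppm = 100, n_replicates = 4,
                   matrix_peak_scale = 0, fluor_scale = 0,
                   response_scale = 8))
      dataset_design(cond, urine_matrix_model(), seed = seed)
    },
    in_vivo = {
      cond <- rbind(
        data.frame(label = "control", analyte = "none",
                   concentration_ppm = 0, n_replicates = 13,
                   matrix_peak_scale = 1),
        data.frame(label = "day1", analyte = analyte,
                   concentration_ppm = 50, n_replicates = 20,
                   matrix_peak_scale = 1),
        data.frame(label = "day7", analyte = analyte,
                   concentration_ppm = 150, n_replicates = 20,
                   matrix_peak_scale = 2))
      dataset_design(cond, urine_matrix_model(), seed = seed)
    })
}

#' Default water matrix model
#'
#' Quiet aqueous background: gentle linear baseline, two weak broad
#' substrate-background humps and two narrow substrate bands with
#' per-sample jitter (the structure a six-component model separates
#' alongside the analyte), channel noise 0.02 a.u. and response 0.3 a.u.
#' per ppm.  The response and the per-analyte response factors place each
#' antibiotic's nominal identification-band signal-to-noise ratio at its
#' empirical water detection limit comfortably above the SNR-3 call
#' threshold (10 for enrofloxacin at 0.5 ppm, about 4.8 for oxytetracycline
#' at 2 ppm and 4.5 for neomycin at 100 ppm) and well below it one dilution
#' step earlier (2 for enrofloxacin at 0.1 ppm), while the pooled-unmixing
#' route still resolves 0.1 ppm of enrofloxacin against the blank null.
#'
#' @return A [matrix_model()].
#' @export
water_matrix_model <- function() {
  matrix_model(
    fluorescence = list(
      peak_spec(900, fwhm = 600, rel_amplitude = 0.25, shape = "gaussian"),
      peak_spec(1500, fwhm = 400, rel_amplitude = 0.15, shape = "gaussian")),
    fluor_sdlog = 0.3,
    matrix_peaks = list(
      peak_spec(1050, fwhm = 40, rel_amplitude = 0.4, shape = "gaussian"),
      peak_spec(1450, fwhm = 40, rel_amplitude = 0.3, shape = "gaussian")),
    matrix_sdlog = 0.4,
    baseline_offset = 0.2, baseline_slope = 2e-4,
    noise_sigma = 0.02, response_coeff = 0.4,
    saturation_conc = 2000)
}

#' Default urine matrix model
#'
#' Strong autofluorescence (two broad Gaussian humps of median amplitude 8
#' and 5 a.u. with log-normal per-sample jitter), a comb of medium-width
#' urine-organics bands that rise and fall together with the per-sample
#' organic load, a urea-region matrix band at 1000 cm-1, channel noise
#' 0.05 a.u. and a suppressed response of 0.02 a.u. per ppm.  The organics
#' residual survives baseline subtraction, so single-spectrum analyte bands
#' drown in it (masked below the saturating 10,000 ppm level), while its
#' one-factor structure lets the unmixing model separate it cleanly and
#' recover the analyte at >= 10 ppm.
#'
#' @return A [matrix_model()].
#' @export
urine_matrix_model <- function() {
  og <- function(center, amp) peak_spec(center, fwhm = 80,
                                        rel_amplitude = amp,
                                        shape = "gaussian")
  matrix_model(
    fluorescence = list(
      peak_spec(1100, fwhm = 500, rel_amplitude = 8, shape = "gaussian"),
      peak_spec(1500, fwhm = 700, rel_amplitude = 5, shape = "gaussian")),
    fluor_sdlog = 0.35,
    organics = list(og(640, 1.5), og(720, 2.0), og(880, 1.8), og(1130, 2.5),
                    og(1260, 2.2), og(1330, 2.8), og(1400, 2.4),
                    og(1460, 2.0), og(1560, 2.6), og(1640, 2.2)),
    organics_sdlog = 0.3,
    matrix_peaks = list(
      peak_spec(1000, fwhm = 20, rel_amplitude = 2),
      peak_spec(1050, fwhm = 40, rel_amplitude = 0.4, shape = "gaussian"),
      peak_spec(1450, fwhm = 40, rel_amplitude = 0.3, shape = "gaussian")),
    matrix_sdlog = 0,
    baseline_offset = 0.5, baseline_slope = 1e-4,
    noise_sigma = 0.05, response_coeff = 0.02, saturation_conc = 2000)
}
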