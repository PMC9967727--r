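#' Describe a single Raman band
#'
#' A peak specification is the building block of a reference spectrum: a band
#' centre on the wavenumber axis, a full width at half maximum, a relative
#' amplitude and a line shape.  Solid-state Raman bands are near-Lorentzian,
#' so that is the default shape; broad fluorescence humps in matrix models use
#' the Gaussian shape.
#'
#' @param center band centre, cm-1.
#' @param fwhm full width at half maximum, cm-1 (> 0).
#' @param rel_amplitude dimensionless non-negative relative amplitude.
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @return An object of class `peak_spec`.
#' @examples
#' peak_spec(1390, fwhm = 12, rel_amplitude = 1)
#' @export
peak_spec <- function(center, fwhm = 12, rel_amplitude = 1,
                      shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (!is.finite(center)) stop_sersmcr("peak center must be finite")
  if (!is.finite(fwhm) || fwhm <= 0) stop_sersmcr("peak fwhm must be > 0")
  if (!is.finite(rel_amplitude) || rel_amplitude < 0)
    stop_sersmcr("rel_amplitude must be finite and >= 0")
  structure(list(center = center, fwhm = fwhm,
                 rel_amplitude = rel_amplitude, shape = shape),
            class = "peak_spec")
}

#' Define an analyte reference: peak table plus identification peaks
#'
#' The identification peaks are the subset of band centres whose joint
#' presence is required to call the analyte present in a spectrum.
#'
#' @param analyte analyte name.
#' @param peaks list of [peak_spec()] objects.
#' @param identification_peaks numeric centres, each matching one of `peaks`.
#' @param response_factor relative SERS response of this analyte (signal per
#'   ppm relative to enrofloxacin); captures the large differences in
#'   effective Raman cross-section between analytes.
#' @param aliases optional named numeric vector of alternative centre values
#'   seen in the literature for bands in `peaks`.
#' @return An object of class `reference_definition`.
#' @export
reference_definition <- function(analyte, peaks, identification_peaks,
                                 response_factor = 1, aliases = NULL) {
  if (!length(identification_peaks))
    stop_sersmcr("at least one identification peak is required for '%s'", analyte)
  centers <- vapply(peaks, function(p) p$center, numeric(1))
  missing <- setdiff(identification_peaks, centers)
  if (length(missing))
    stop_sersmcr("identification peaks not in peak list for '%s': %s",
                 analyte, paste(missing, collapse = ", "))
  structure(list(analyte = analyte, peaks = peaks,
                 identification_peaks = as.numeric(identification_peaks),
                 response_factor = response_factor, aliases = aliases),
            class = "reference_definition")
}

#' @export
print.reference_definition <- function(x, ...) {
  centers <- vapply(x$peaks, function(p) p$center, numeric(1))
  cat(sprintf("<reference_definition> %s\n", x$analyte))
  cat(sprintf("  peaks (cm-1): %s\n", paste(centers, collapse = ", ")))
  cat(sprintf("  identification: %s\n",
              paste(x$identification_peaks, collapse = ", ")))
  cat(sprintf("  response factor: %g\n", x$response_factor))
  invisible(x)
}

#' Built-in antibiotic reference library
#'
#' Peak tables for the three antibiotics screened by the platform.
#' Enrofloxacin shows bands at 752, 803, 835, 1252, 1390, 1552 and 1624 cm-1
#' and is identified by the 1390/1624 pair (the symmetric O-C-O stretch and
#' the C=O stretch); 1387 is a common literature alias for the 1390 band.
#' Oxytetracycline shows 803, 835, 1170, 1254, 1315 and 1620 cm-1, identified
#' by 1315/1620; the 803/835 bands are shared with enrofloxacin.  Neomycin has
#' a single dominant CH2-rocking band at 977 cm-1.
#'
#' Relative amplitudes follow the prominence ordering of the standard spectra:
#' primary identification band 1.0, secondary identification band 0.95,
#' remaining analyte bands 0.5, shared 803/835 bands 0.3.  Response factors
#' encode the relative per-ppm SERS sensitivity of each analyte
#' (enrofloxacin >> oxytetracycline >> neomycin), calibrated so the packaged
#' water scenario reproduces the platform's empirical detection limits.
#'
#' @param fwhm band width applied to every analyte peak, cm-1.
#' @return Named list of [reference_definition()] objects.
#' @examples
#' refs <- antibiotic_references()
#' names(refs)
#' @export
antibiotic_references <- function(fwhm = 12) {
  lp <- function(center, amp) peak_spec(center, fwhm = fwhm, rel_amplitude = amp)
  enro <- reference_definition(
    "enrofloxacin",
    peaks = list(lp(752, 0.5), lp(803, 0.3), lp(835, 0.3), lp(1252, 0.5),
                 lp(1390, 1.0), lp(1552, 0.5), lp(1624, 0.95)),
    identification_peaks = c(1390, 1624),
    response_factor = 1,
    aliases = c("1390" = 1387))
  oxy <- reference_definition(
    "oxytetracycline",
    peaks = list(lp(803, 0.3), lp(835, 0.3), lp(1170, 0.5), lp(1254, 0.5),
                 lp(1315, 1.0), lp(1620, 0.95)),
    identification_peaks = c(1315, 1620),
    response_factor = 0.12)
  neo <- reference_definition(
    "neomycin",
    peaks = list(lp(977, 1.0)),
    identification_peaks = 977,
    response_factor = 0.0023625)
  list(enrofloxacin = enro, oxytetracycline = oxy, neomycin = neo)
}

#' Default wavenumber grid
#'
#' 400--1800 cm-1 in 2 cm-1 steps, covering every band in the built-in
#' reference library.
#'
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(400, 1800, by = 2)

#' Evaluate a single band profile on a grid
#'
#' @param peak a [peak_spec()].
#' @param grid wavenumber grid.
#' @return Numeric intensity vector.
#' @export
peak_profile <- function(peak, grid) {
  d <- grid - peak$center
  if (peak$shape == "lorentzian") {
    g <- peak$fwhm / 2
    peak$rel_amplitude * g^2 / (g^2 + d^2)
  } else {
    peak$rel_amplitude * exp(-4 * log(2) * d^2 / peak$fwhm^2)
  }
}

#' Build a noiseless reference spectrum from a peak table
#'
#' Evaluates the sum of the band profiles on `grid` and normalizes the result
#' to unit maximum.  An empty peak list yields an all-zero spectrum.
#'
#' @param ref a [reference_definition()].
#' @param grid wavenumber grid; must cover every band centre.
#' @return A [spectrum()] with `analyte` metadata and condition `"reference"`.
#' @examples
#' s <- build_reference_spectrum(antibiotic_references()$neomycin)
#' s$wavenumber[which.max(s$intensity)]  # 977
#' @export
build_reference_spectrum <- function(ref, grid = default_grid()) {
  stopifnot(inherits(ref, "reference_definition"))
  for (p in ref$peaks) {
    if (p$center < min(grid) || p$center > max(grid))
      stop_sersmcr("peak %g cm-1 of '%s' lies outside the grid [%g, %g]",
                   p$center, ref$analyte, min(grid), max(grid))
  }
  y <- rep(0, length(grid))
  for (p in ref$peaks) y <- y + peak_profile(p, grid)
  if (max(y) > 0) y <- y / max(y)
  spectrum(grid, y,
           sample_id = paste0("ref_", ref$analyte), analyte = ref$analyte,
           condition = "reference")
}

#' Reference spectra as a matrix on a shared grid
#'
#' @param refs list of [reference_definition()] objects.
#' @param grid wavenumber grid.
#' @return Matrix with one row per reference, rownames = analyte names.
#' @export
reference_matrix <- function(refs, grid = default_grid()) {
  rows <- lapply(refs, function(r) build_reference_spectrum(r, grid)$intensity)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(refs, function(r) r$analyte, character(1))
  m
}
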