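#' Asymmetric-least-squares baseline estimate
#'
#' Eilers-style smoother: minimizes
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)` with
#' asymmetric weights `w = p` where `y > z` and `1 - p` elsewhere, so the
#' smooth curve `z` hugs the lower envelope of the signal -- the standard
#' treatment for broad fluorescence backgrounds under sharp Raman bands.
#'
#' @param y numeric intensity vector (length >= 10).
#' @param lambda smoothness penalty (> 0); larger values give stiffer
#'   baselines.
#' @param p asymmetry in (0, 1); small values let peaks stand above the
#'   baseline.
#' @param n_iter number of reweighting iterations.
#' @return Numeric baseline vector, same length as `y`.
#' @export
baseline_als <- function(y, lambda = 1e5, p = 0.01, n_iter = 10) {
  if (!is.finite(lambda) || lambda <= 0) stop_sersmcr("lambda must be > 0")
  if (!is.finite(p) || p <= 0 || p >= 1) stop_sersmcr("p must lie in (0, 1)")
  m <- length(y)
  if (m < 10) stop_sersmcr("baseline estimation needs >= 10 channels, got %d", m)
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(n_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w) && it > 1) break
    w <- w_new
  }
  z
}

#' Subtract a fluorescence baseline from a spectrum
#'
#' Returns the signal minus an asymmetric-least-squares baseline
#' ([baseline_als()]).  With `clip_negative = TRUE` the residual is clipped at
#' zero, which the unmixing pipeline uses to honour its non-negativity model;
#' peak calling keeps the signed residual so the noise estimate stays
#' unbiased.
#'
#' @param s a [spectrum()].
#' @inheritParams baseline_als
#' @param clip_negative clip negative residuals at 0?
#' @return A [spectrum()] with the baseline removed.
#' @examples
#' s <- spectrum(seq(400, 1800, 2), 5 + 0.001 * seq(0, 1400, 2))
#' out <- subtract_baseline(s)
#' max(abs(out$intensity)) < 1e-6 * 5
#' @export
subtract_baseline <- function(s, lambda = 1e5, p = 0.01, n_iter = 10,
                              clip_negative = FALSE) {
  stopifnot(inherits(s, "raman_spectrum"))
  z <- baseline_als(s$intensity, lambda = lambda, p = p, n_iter = n_iter)
  out <- s
  out$intensity <- s$intensity - z
  if (clip_negative) out$intensity <- pmax(out$intensity, 0)
  out
}

#' Baseline-subtract every spectrum of a dataset
#'
#' An asymmetric baseline runs along the lower envelope of the noise band,
#' which leaves each residual a small positive pedestal of random depth;
#' `center_offset` removes it by subtracting the per-spectrum median of the
#' residual (a robust zero-level estimate, since peaks occupy a minority of
#' channels) before any clipping.
#'
#' @param ds a [spectral_dataset()].
#' @inheritParams subtract_baseline
#' @param center_offset subtract the per-spectrum median residual?
#' @return A [spectral_dataset()].
#' @export
preprocess_dataset <- function(ds, lambda = 1e5, p = 0.01, n_iter = 10,
                               clip_negative = FALSE, center_offset = clip_negative) {
  stopifnot(inherits(ds, "spectral_dataset"))
  out <- ds
  for (i in seq_len(nrow(ds$intensities))) {
    z <- baseline_als(ds$intensities[i, ], lambda = lambda, p = p,
                      n_iter = n_iter)
    r <- ds$intensities[i, ] - z
    if (center_offset) r <- r - median(r)
    out$intensities[i, ] <- r
  }
  if (clip_negative) out$intensities[out$intensities < 0] <- 0
  out
}

#' Reference spectrum as seen through the baseline operator
#'
#' Builds the analyte's noiseless reference on `grid`, applies the same
#' asymmetric-least-squares baseline subtraction (and clipping) used on
#' measured spectra, and renormalizes to unit maximum.  Baseline subtraction
#' slightly reshapes real peaks (it bleeds into peak wings), so unmixing
#' components recovered from preprocessed data are compared against a
#' reference carrying the identical distortion.
#'
#' @param ref a [reference_definition()].
#' @param grid wavenumber grid.
#' @inheritParams baseline_als
#' @return A [spectrum()].
#' @export
effective_reference <- function(ref, grid = default_grid(), lambda = 1e5,
                                p = 0.01) {
  s <- build_reference_spectrum(ref, grid)
  out <- subtract_baseline(s, lambda = lambda, p = p, clip_negative = TRUE)
  if (max(out$intensity) > 0)
    out$intensity <- out$intensity / max(out$intensity)
  out
}

#' Optional median despiking filter
#'
#' Replaces isolated narrow spikes (cosmic rays) by the running median where
#' the deviation exceeds `k_sigma` robust standard deviations.  Off by
#' default throughout the pipeline.
#'
#' @param s a [spectrum()].
#' @param width odd window width in channels.
#' @param k_sigma replacement threshold in robust SD units.
#' @return A [spectrum()].
#' @export
despike_median <- function(s, width = 5, k_sigma = 8) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (width %% 2 == 0) stop_sersmcr("despike width must be odd")
  med <- stats::runmed(s$intensity, k = width, endrule = "median")
  resid <- s$intensity - med
  cut <- k_sigma * mad(resid)
  out <- s
  hit <- abs(resid) > cut & cut > 0
  out$intensity[hit] <- med[hit]
  out
}
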