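#' A single Raman spectrum
#'
#' One intensity trace on a strictly increasing wavenumber grid, with sample
#' metadata (id, analyte, nominal concentration, condition label, replicate).
#'
#' @param wavenumber numeric, cm-1, strictly increasing.
#' @param intensity numeric, arbitrary units, same length.
#' @param sample_id sample identifier.
#' @param analyte analyte name or `"unknown"`.
#' @param concentration_ppm nominal concentration in ppm, or `NA`.
#' @param condition condition label (e.g. `"water"`, `"blank"`, `"day7"`).
#' @param replicate replicate index.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity` and `meta`.
#' @examples
#' s <- spectrum(seq(400, 410, 2), c(0, 1, 4, 1, 0, 0))
#' length(s$wavenumber)
#' @export
spectrum <- function(wavenumber, intensity, sample_id = "s1",
                     analyte = "unknown", concentration_ppm = NA_real_,
                     condition = "unspecified", replicate = 1L) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop_sersmcr("wavenumber and intensity lengths differ (%d vs %d)",
                 length(wavenumber), length(intensity))
  if (!all(is.finite(wavenumber)) || !all(is.finite(intensity)))
    stop_sersmcr("spectrum '%s' contains non-finite values", sample_id)
  if (length(wavenumber) > 1 && any(diff(wavenumber) <= 0))
    stop_sersmcr("wavenumber grid of '%s' is not strictly increasing", sample_id)
  structure(list(
    wavenumber = wavenumber, intensity = intensity,
    meta = list(sample_id = sample_id, analyte = analyte,
                concentration_ppm = as.numeric(concentration_ppm),
                condition = condition, replicate = as.integer(replicate))),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s (%s, %s ppm, %s, rep %d)\n",
              x$meta$sample_id, x$meta$analyte,
              format(x$meta$concentration_ppm), x$meta$condition,
              x$meta$replicate))
  cat(sprintf("  %d channels, %g..%g cm-1, intensity range [%.4g, %.4g]\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...,
                                xlab = expression(paste("Raman shift (", cm^-1, ")")),
                                ylab = "Intensity (a.u.)", type = "l") {
  graphics::plot(x$wavenumber, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, main = x$meta$sample_id, ...)
  invisible(x)
}

#' Resample a spectrum onto a new grid by linear interpolation
#'
#' Channels of `grid` outside the spectrum's range are dropped, never
#' extrapolated.  Resampling onto the spectrum's own grid is the identity.
#'
#' @param s a [spectrum()].
#' @param grid target wavenumber grid.
#' @return A [spectrum()] on the (possibly truncated) target grid.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "raman_spectrum"))
  keep <- grid >= min(s$wavenumber) & grid <= max(s$wavenumber)
  if (!any(keep))
    stop_sersmcr("grid does not overlap spectrum '%s'", s$meta$sample_id)
  grid <- grid[keep]
  if (length(grid) == length(s$wavenumber) &&
      all(grid == s$wavenumber)) return(s)
  y <- approx(s$wavenumber, s$intensity, xout = grid)$y
  out <- s
  out$wavenumber <- grid
  out$intensity <- y
  out
}

#' A row-stacked collection of spectra on a shared grid
#'
#' The intensity matrix `D` (samples x channels) is the object factorized by
#' [mcr_fit()]; the manifest carries one metadata row per spectrum.
#'
#' @param intensities numeric matrix, one row per spectrum.
#' @param wavenumber shared grid, length `ncol(intensities)`.
#' @param manifest data frame with columns `sample_id`, `analyte`,
#'   `concentration_ppm`, `condition`, `replicate` (one row per spectrum).
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(intensities, wavenumber, manifest) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) < 1) stop_sersmcr("dataset needs at least one spectrum")
  if (ncol(intensities) != length(wavenumber))
    stop_sersmcr("intensity columns (%d) != grid length (%d)",
                 ncol(intensities), length(wavenumber))
  if (!all(is.finite(intensities)))
    stop_sersmcr("dataset intensities contain non-finite values")
  req <- c("sample_id", "analyte", "concentration_ppm", "condition", "replicate")
  missing <- setdiff(req, names(manifest))
  if (length(missing))
    stop_sersmcr("manifest lacks columns: %s", paste(missing, collapse = ", "))
  if (nrow(manifest) != nrow(intensities))
    stop_sersmcr("manifest rows (%d) != spectra (%d)",
                 nrow(manifest), nrow(intensities))
  rownames(intensities) <- manifest$sample_id
  structure(list(intensities = intensities, wavenumber = as.numeric(wavenumber),
                 manifest = as.data.frame(manifest)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d channels (%g..%g cm-1)\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$wavenumber), max(x$wavenumber)))
  tab <- table(x$manifest$condition)
  cat("  conditions: ",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Extract one spectrum from a dataset
#'
#' @param ds a [spectral_dataset()].
#' @param i row index.
#' @return A [spectrum()].
#' @export
get_spectrum <- function(ds, i) {
  stopifnot(inherits(ds, "spectral_dataset"))
  m <- ds$manifest[i, ]
  spectrum(ds$wavenumber, ds$intensities[i, ],
           sample_id = m$sample_id, analyte = m$analyte,
           concentration_ppm = m$concentration_ppm,
           condition = m$condition, replicate = m$replicate)
}

#' Subset a dataset by row
#'
#' @param ds a [spectral_dataset()].
#' @param i logical or integer row index.
#' @return A [spectral_dataset()].
#' @export
subset_dataset <- function(ds, i) {
  spectral_dataset(ds$intensities[i, , drop = FALSE], ds$wavenumber,
                   ds$manifest[i, , drop = FALSE])
}

#' Average replicate spectra within groups
#'
#' Computes one mean spectrum per group of the manifest column `by`
#' (typically `"condition"`).  The returned manifest keeps metadata columns
#' that are constant within a group and records the group size in `n`.
#'
#' @param ds a [spectral_dataset()].
#' @param by manifest column used for grouping.
#' @return A [spectral_dataset()] with one row per group.
#' @export
average_replicates <- function(ds, by = "condition") {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (!by %in% names(ds$manifest))
    stop_sersmcr("grouping column '%s' not present in manifest", by)
  g <- factor(ds$manifest[[by]], levels = unique(ds$manifest[[by]]))
  sums <- rowsum(ds$intensities, g, reorder = FALSE)
  n <- as.vector(table(g)[levels(g)])
  means <- sums / n
  one_or_na <- function(col) {
    vapply(levels(g), function(lv) {
      v <- unique(ds$manifest[[col]][g == lv])
      if (length(v) == 1) v else if (is.numeric(v)) NA_real_ else NA_character_
    }, ds$manifest[[col]][1])
  }
  man <- data.frame(sample_id = paste0("mean_", levels(g)),
                    analyte = one_or_na("analyte"),
                    concentration_ppm = as.numeric(one_or_na("concentration_ppm")),
                    condition = levels(g),
                    replicate = 1L, n = n,
                    stringsAsFactors = FALSE)
  spectral_dataset(means, ds$wavenumber, man)
}
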