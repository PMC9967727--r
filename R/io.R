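#' Read a two-column spectrum CSV
#'
#' Expects one header line and two numeric columns (wavenumber cm-1,
#' intensity a.u.).  Parse problems are reported with the file and the
#' offending line number.
#'
#' @param path file path.
#' @param ... metadata passed on to [spectrum()] (`sample_id`, `analyte`, ...).
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, ...) {
  if (!file.exists(path)) stop_sersmcr("spectrum file not found: %s", path)
  df <- tryCatch(read.csv(path, header = TRUE),
                 error = function(e) stop_sersmcr(
                   "cannot parse '%s' as CSV: %s", path, conditionMessage(e)))
  if (ncol(df) < 2)
    stop_sersmcr("'%s': expected two columns (wavenumber, intensity)", path)
  w <- suppressWarnings(as.numeric(df[[1]]))
  y <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(!is.finite(w) | !is.finite(y))
  if (length(bad))
    stop_sersmcr("'%s': non-numeric or non-finite value at line %d",
                 path, bad[1] + 1L)  # +1 for header
  nonmono <- which(diff(w) <= 0)
  if (length(nonmono))
    stop_sersmcr("'%s': wavenumber not strictly increasing at line %d",
                 path, nonmono[1] + 2L)
  args <- list(...)
  if (is.null(args$sample_id))
    args$sample_id <- tools::file_path_sans_ext(basename(path))
  do.call(spectrum, c(list(wavenumber = w, intensity = y), args))
}

#' Write a spectrum as a two-column CSV
#'
#' @param s a [spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  df <- data.frame(wavenumber_cm1 = s$wavenumber, intensity = s$intensity)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

manifest_columns <- c("file", "sample_id", "analyte", "concentration_ppm",
                      "condition", "replicate")

#' Read a dataset from a manifest CSV
#'
#' The manifest must contain the columns `file`, `sample_id`, `analyte`,
#' `concentration_ppm`, `condition`, `replicate`; `file` paths are resolved
#' relative to the manifest's directory.  All spectra are linearly
#' interpolated onto a common grid (by default the first spectrum's grid
#' restricted to the range shared by every file; out-of-range channels are
#' dropped, never extrapolated).
#'
#' @param manifest_path path to the manifest CSV.
#' @param grid optional target wavenumber grid.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(manifest_path, grid = NULL) {
  if (!file.exists(manifest_path))
    stop_sersmcr("manifest not found: %s", manifest_path)
  man <- tryCatch(read.csv(manifest_path, header = TRUE),
                  error = function(e) stop_sersmcr(
                    "cannot parse manifest '%s': %s", manifest_path,
                    conditionMessage(e)))
  missing <- setdiff(manifest_columns, names(man))
  if (length(missing))
    stop_sersmcr("manifest '%s' lacks columns: %s", manifest_path,
                 paste(missing, collapse = ", "))
  dir <- dirname(manifest_path)
  spectra <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$file[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(dir, p)
    read_spectrum(p, sample_id = man$sample_id[i], analyte = man$analyte[i],
                  concentration_ppm = man$concentration_ppm[i],
                  condition = man$condition[i], replicate = man$replicate[i])
  })
  lo <- max(vapply(spectra, function(s) min(s$wavenumber), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$wavenumber), numeric(1)))
  if (lo >= hi) stop_sersmcr("spectra in '%s' share no wavenumber range",
                             manifest_path)
  if (is.null(grid)) grid <- spectra[[1]]$wavenumber
  grid <- grid[grid >= lo & grid <= hi]
  rows <- lapply(spectra, function(s) resample_spectrum(s, grid)$intensity)
  spectral_dataset(do.call(rbind, rows), grid,
                   man[, setdiff(manifest_columns, "file")])
}

#' Write a dataset as per-spectrum CSVs plus a manifest
#'
#' @param ds a [spectral_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the spectrum CSVs.
#' @return Path to the written manifest, invisibly.
#' @export
write_dataset <- function(ds, dir, prefix = "spectrum") {
  stopifnot(inherits(ds, "spectral_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(ds$intensities)
  files <- sprintf("%s_%04d.csv", prefix, seq_len(n))
  for (i in seq_len(n)) write_spectrum(get_spectrum(ds, i),
                                       file.path(dir, files[i]))
  man <- cbind(data.frame(file = files),
               ds$manifest[, intersect(names(ds$manifest),
                                       setdiff(manifest_columns, "file"))])
  man_path <- file.path(dir, "manifest.csv")
  write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  invisible(man_path)
}
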