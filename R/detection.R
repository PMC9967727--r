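#' Call characteristic peaks in a baseline-subtracted spectrum
#'
#' For each identification peak of the reference the local maximum within
#' `+/- window_cm1` of the band centre is located; the noise level is the
#' MAD-based robust deviation over the signal-free region (channels more than
#' `exclude_cm1` away from every band of the reference) and the peak height
#' is measured from that region's median, which removes the small positive
#' offset an asymmetric-least-squares baseline leaves under the noise band;
#' the peak is `found` when its signal-to-noise ratio reaches
#' `snr_threshold`.  The analyte is
#' `identified` when ALL identification peaks are found (a single band
#' suffices for neomycin, whose reference lists only 977 cm-1).
#'
#' @param s a baseline-subtracted [spectrum()].
#' @param ref a [reference_definition()].
#' @param snr_threshold minimum SNR for a peak call.
#' @param window_cm1 half-width of the search window, cm-1.
#' @param exclude_cm1 half-width of the region around every reference band
#'   excluded from the noise estimate, cm-1.
#' @param known_bands centres of known non-analyte bands (substrate and
#'   matrix bands of the measurement platform) also excluded from the noise
#'   region; defaults to [platform_background_bands()].
#' @return Object of class `peak_calls`: data frame with one row per
#'   identification peak (`analyte`, `center`, `found`, `height`, `noise`,
#'   `snr`) and attribute `identified` (logical).
#' @export
call_peaks <- function(s, ref, snr_threshold = 3, window_cm1 = 8,
                       exclude_cm1 = 30,
                       known_bands = platform_background_bands()) {
  stopifnot(inherits(s, "raman_spectrum"), inherits(ref, "reference_definition"))
  w <- s$wavenumber; y <- s$intensity
  if (window_cm1 >= (max(w) - min(w)) / 2)
    stop_sersmcr("search window (%g cm-1) exceeds the grid span", window_cm1)
  centers_all <- c(vapply(ref$peaks, function(p) p$center, numeric(1)),
                   known_bands)
  free <- rep(TRUE, length(w))
  for (ctr in centers_all) free <- free & abs(w - ctr) > exclude_cm1
  if (sum(free) < 10)
    stop_sersmcr("too few signal-free channels for a noise estimate")
  noise <- mad(y[free])
  base_level <- median(y[free])
  calls <- do.call(rbind, lapply(ref$identification_peaks, function(ctr) {
    win <- which(abs(w - ctr) <= window_cm1)
    if (!length(win))
      stop_sersmcr("window around %g cm-1 lies outside the grid", ctr)
    i_max <- win[which.max(y[win])]
    height <- y[i_max] - base_level
    snr <- if (noise > 0) height / noise else ifelse(height > 0, Inf, 0)
    data.frame(analyte = ref$analyte, center = ctr,
               location = w[i_max], height = height, noise = noise,
               snr = snr, found = is.finite(snr) & snr >= snr_threshold |
                 (noise == 0 & height > 0))
  }))
  attr(calls, "identified") <- all(calls$found)
  class(calls) <- c("peak_calls", class(calls))
  calls
}

#' Known background bands of the measurement platform
#'
#' Band centres that belong to the platform or sample matrix rather than any
#' analyte -- the urea-region band near 1000 cm-1 in urine and the
#' carbonaceous bands of the silver nanorod substrate -- and are therefore
#' masked out of the signal-free region used for noise estimation.
#'
#' @return Numeric vector of centres, cm-1.
#' @export
platform_background_bands <- function() c(1000, 1050, 1450)

#' Is the analyte identified in a spectrum?
#'
#' @inheritParams call_peaks
#' @return Logical scalar.
#' @export
is_identified <- function(s, ref, snr_threshold = 3, window_cm1 = 8) {
  attr(call_peaks(s, ref, snr_threshold, window_cm1), "identified")
}

lod_result <- function(analyte, method, tested, fractions, lod, details = list()) {
  structure(list(analyte = analyte, method = method,
                 tested_concentrations = tested,
                 detection_fractions = fractions,
                 lod = lod, reached = is.finite(lod), details = details),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> %s (%s)\n", x$analyte, x$method))
  df <- data.frame(concentration_ppm = x$tested_concentrations,
                   detection_fraction = round(x$detection_fractions, 3))
  print(df, row.names = FALSE)
  cat(sprintf("  LOD: %s\n",
              if (x$reached) paste0(format(x$lod), " ppm") else "not reached"))
  invisible(x)
}

#' Per-spectrum (univariate) limit of detection
#'
#' The LOD is the lowest tested concentration whose replicate detection
#' fraction (spectra in which all identification peaks are called) reaches
#' `rule`; the default demands every replicate.  Blank and standard
#' conditions are excluded from the tested levels.
#'
#' @param ds a [spectral_dataset()] whose manifest carries nominal
#'   concentrations.
#' @param ref a [reference_definition()].
#' @param rule required detection fraction per level, in (0, 1].
#' @param snr_threshold,window_cm1 passed to [call_peaks()].
#' @param preprocess subtract the fluorescence baseline first (on by
#'   default; set `FALSE` if `ds` is already baseline-subtracted).
#' @param lambda,p baseline parameters, see [baseline_als()].
#' @return A `lod_result` with `method = "univariate"`.
#' @export
lod_univariate <- function(ds, ref, rule = 1, snr_threshold = 3,
                           window_cm1 = 8, preprocess = TRUE,
                           lambda = 1e5, p = 0.01) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (rule <= 0 || rule > 1) stop_sersmcr("rule must lie in (0, 1]")
  man <- ds$manifest
  test_rows <- man$concentration_ppm > 0 & man$condition != "standard"
  if (!any(test_rows)) stop_sersmcr("dataset has no nonzero test concentrations")
  if (preprocess) ds <- preprocess_dataset(ds, lambda = lambda, p = p)
  levels <- sort(unique(man$concentration_ppm[test_rows]))
  fractions <- vapply(levels, function(cc) {
    idx <- which(test_rows & man$concentration_ppm == cc)
    hits <- vapply(idx, function(i)
      is_identified(get_spectrum(ds, i), ref, snr_threshold, window_cm1),
      logical(1))
    mean(hits)
  }, numeric(1))
  reached <- which(fractions >= rule)
  lod <- if (length(reached)) levels[min(reached)] else NA_real_
  lod_result(ref$analyte, "univariate", levels, fractions, lod)
}

#' Unmixing-based limit of detection
#'
#' Pools the full dataset (test levels, blanks and standards), fits the
#' MCR-ALS model to the raw spectra (baseline, fluorescence and matrix
#' structure are low-rank in raw form and are separated as components),
#' assigns the analyte component by cosine matching against the reference,
#' and reads each sample's analyte intensity from the contribution matrix
#' after blank-calibrated leakage correction ([analyte_intensity()]).  A
#' sample is detected when its intensity exceeds the blank mean plus
#' `k_sd x` the blank standard deviation; the LOD is then the lowest tested
#' level whose detection fraction reaches `rule`.  If no component matches
#' the analyte the LOD is reported as not reached, with a diagnostic.
#'
#' @inheritParams lod_univariate
#' @param refs reference library (list of [reference_definition()]); the
#'   analyte entry seeds and identifies the component.
#' @param analyte analyte name (must exist in `refs`).
#' @param config an [mcr_config()]; defaults to a six-component model with
#'   an iteration budget large enough for the pooled urine runs.
#' @param threshold cosine threshold for component assignment.
#' @param k_sd multiple of the blank SD defining the detection cut.
#' @param preprocess baseline-subtract and clip before fitting.
#' @return A `lod_result` with `method = "mcr"`; details carry the fit,
#'   assignment, per-sample intensities and the detection cut.
#' @details Fitting raw spectra keeps every background structure exactly
#'   low-rank; subtracting a baseline first is a nonlinear operation that
#'   scatters background energy across many directions and degrades the
#'   factorization.  (The per-spectrum identification route,
#'   [lod_univariate()], does baseline-subtract: its noise estimate then
#'   sees the matrix residual as an elevated floor, which is exactly what
#'   masks single-spectrum peaks in urine.)  Set `preprocess = TRUE` to
#'   baseline-subtract, centre and clip before the fit instead; the
#'   reference is then distorted consistently via [effective_reference()].
#' @export
lod_mcr <- function(ds, refs = antibiotic_references(),
                    analyte = "enrofloxacin",
                    config = mcr_config(6, max_iter = 2000), rule = 1,
                    threshold = 0.7,
                    k_sd = 3, preprocess = FALSE, lambda = 1e5, p = 0.01) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(refs[[analyte]])) stop_sersmcr("no reference for '%s'", analyte)
  man <- ds$manifest
  blanks <- man$concentration_ppm == 0
  if (!any(blanks))
    stop_sersmcr("unmixing LOD needs blank samples for the detection null")
  if (preprocess) {
    ds <- preprocess_dataset(ds, lambda = lambda, p = p,
                             clip_negative = TRUE, center_offset = TRUE)
    ref_s <- effective_reference(refs[[analyte]], ds$wavenumber,
                                 lambda = lambda, p = p)
  } else {
    ref_s <- build_reference_spectrum(refs[[analyte]], ds$wavenumber)
  }
  eff_ref <- list(ref_s)
  names(eff_ref) <- analyte
  fit <- mcr_fit(ds, refs = eff_ref, config = config)
  assignment <- match_components(fit, eff_ref, threshold = threshold)
  row <- assignment[assignment$analyte == analyte, ]
  levels <- sort(unique(man$concentration_ppm[!blanks & man$condition != "standard"]))
  if (!row$assigned) {
    return(lod_result(analyte, "mcr", levels, rep(0, length(levels)),
                      NA_real_,
                      details = list(fit = fit, assignment = assignment,
                                     diagnostic = sprintf(
                                       "no component matched '%s' (best cosine %.3f < %.3f)",
                                       analyte, row$similarity, threshold))))
  }
  intensity <- analyte_intensity(fit, refs[[analyte]], ds,
                                 component = row$component, blanks = blanks)
  cut <- attr(intensity, "blank_mean") + k_sd * attr(intensity, "blank_sd")
  detected <- intensity > cut
  fractions <- vapply(levels, function(cc) {
    idx <- which(!blanks & man$condition != "standard" &
                   man$concentration_ppm == cc)
    mean(detected[idx])
  }, numeric(1))
  reached <- which(fractions >= rule)
  lod <- if (length(reached)) levels[min(reached)] else NA_real_
  lod_result(analyte, "mcr", levels, fractions, lod,
             details = list(fit = fit, assignment = assignment,
                            component = row$component,
                            intensity = as.numeric(intensity), cut = cut,
                            detected = detected))
}

#' Per-sample analyte intensity from an unmixing fit, with blank calibration
#'
#' The raw contribution column of the assigned analyte component is
#' contaminated by rotational ambiguity whenever a background structure
#' overlaps the analyte bands: the solver is free to park part of that
#' overlap in the analyte component, where it rises and falls with the
#' background level.  The blanks pin down exactly this leakage.  The
#' estimator therefore (1) estimates each sample's background factor levels
#' by ordinary least squares of the analyte-free channels (those farther
#' than `exclude_cm1` from every analyte band) onto the background
#' component spectra restricted to those channels, and (2) regresses the
#' analyte contribution of the blanks on those factors, subtracting the
#' fitted leakage from every sample.  Blanks then centre at zero and the
#' corrected intensity responds only to true analyte signal.
#'
#' The residual blank scale returned in `attr(,"blank_sd")` is the
#' degrees-of-freedom-corrected residual standard deviation of the
#' calibration regression, the appropriate scale for a
#' `mean + k * sd` detection cut.
#'
#' @param fit an [mcr_result()].
#' @param ref a [reference_definition()] for the analyte (band positions
#'   define the analyte-free channels).
#' @param ds the [spectral_dataset()] the model was fit to.
#' @param component index of the assigned analyte component (from
#'   [match_components()]).
#' @param blanks logical or integer index of known analyte-free samples; if
#'   `NULL` the uncorrected contribution column is returned.
#' @param exclude_cm1 half-width of the exclusion zone around each analyte
#'   band, cm-1.
#' @return Numeric vector of per-sample intensities (a.u.), with attributes
#'   `blank_sd` and `blank_mean`.
#' @export
analyte_intensity <- function(fit, ref, ds, component, blanks = NULL,
                              exclude_cm1 = 30) {
  stopifnot(inherits(fit, "mcr_result"), inherits(ref, "reference_definition"))
  cr <- fit$C[, component]
  if (is.null(blanks)) {
    attr(cr, "blank_mean") <- NA_real_
    attr(cr, "blank_sd") <- NA_real_
    return(cr)
  }
  if (is.logical(blanks)) blanks <- which(blanks)
  w <- ds$wavenumber
  M <- rep(TRUE, length(w))
  for (p in ref$peaks) M <- M & abs(w - p$center) > exclude_cm1
  G <- t(fit$S[-component, M, drop = FALSE])
  nrm <- sqrt(colSums(G^2))
  G <- G[, nrm > 1e-6 * max(nrm, .Machine$double.eps), drop = FALSE]
  gcoef <- if (ncol(G)) {
    GtG <- crossprod(G)
    GtG <- GtG + 1e-8 * mean(diag(GtG)) * diag(ncol(G))
    t(solve(GtG, crossprod(G, t(ds$intensities[, M, drop = FALSE]))))
  } else matrix(0, nrow(ds$intensities), 0)
  X <- cbind(1, gcoef)
  XtX <- crossprod(X[blanks, , drop = FALSE])
  XtX <- XtX + 1e-8 * mean(diag(XtX)) * diag(ncol(X))
  beta <- solve(XtX, crossprod(X[blanks, , drop = FALSE], cr[blanks]))
  e <- cr - as.numeric(X %*% beta)
  dfree <- max(length(blanks) - ncol(X), 1)
  attr(e, "blank_mean") <- mean(e[blanks])
  attr(e, "blank_sd") <- sqrt(sum(e[blanks]^2) / dfree)
  e
}

#' Concentration trend of an assigned component
#'
#' Mean component contribution per nominal concentration level and the
#' Spearman rank correlation between the level means and the levels (ties
#' handled through average ranks).
#'
#' @param result an [mcr_result()].
#' @param assignment a [match_components()] result.
#' @param manifest the dataset manifest.
#' @param analyte analyte whose component is analysed.
#' @param intensity optional per-sample intensity vector (e.g. the
#'   blank-corrected [analyte_intensity()]); defaults to the assigned
#'   component's contribution column.
#' @return List with `level_means` (data frame) and `spearman_rho`.
#' @export
concentration_trend <- function(result, assignment, manifest,
                                analyte = "enrofloxacin", intensity = NULL) {
  row <- assignment[assignment$analyte == analyte, ]
  if (!nrow(row) || !row$assigned)
    stop_sersmcr("component for '%s' is not assigned", analyte)
  test <- manifest$concentration_ppm > 0 & manifest$condition != "standard"
  levels <- sort(unique(manifest$concentration_ppm[test]))
  if (length(levels) < 3)
    stop_sersmcr("need >= 3 concentration levels, got %d", length(levels))
  intensity <- intensity %||% result$C[, row$component]
  means <- vapply(levels, function(cc)
    mean(intensity[test & manifest$concentration_ppm == cc]), numeric(1))
  rho <- suppressWarnings(cor(rank(levels), rank(means)))
  list(analyte = analyte, component = row$component,
       level_means = data.frame(concentration_ppm = levels,
                                mean_intensity = means),
       spearman_rho = rho)
}

#' Compare analyte levels across in-vivo conditions
#'
#' Reports the mean analyte-component contribution per condition, checks the
#' expected ordering (day 7 > day 1 > control), and tests the control against
#' a detection cut built from its own spread (mean + `k_sd` SD).  Conditions
#' whose means differ by less than two standard errors are flagged as not
#' separable.
#'
#' @inheritParams concentration_trend
#' @param conditions condition labels, ordered from lowest to highest
#'   expected level (first = negative control).
#' @param k_sd multiple of the control SD defining the detection cut.
#' @return List with per-condition summaries, `ordering_ok`, `separable`,
#'   `control_detected` and the detection `cut`.
#' @export
compare_conditions <- function(result, assignment, manifest,
                               analyte = "enrofloxacin",
                               conditions = c("control", "day1", "day7"),
                               k_sd = 3, intensity = NULL) {
  row <- assignment[assignment$analyte == analyte, ]
  if (!nrow(row) || !row$assigned)
    stop_sersmcr("component for '%s' is not assigned", analyte)
  missing <- setdiff(conditions, manifest$condition)
  if (length(missing))
    stop_sersmcr("conditions absent from manifest: %s",
                 paste(missing, collapse = ", "))
  intensity <- intensity %||% result$C[, row$component]
  stats_by <- lapply(conditions, function(cn) {
    v <- intensity[manifest$condition == cn]
    list(condition = cn, n = length(v), mean = mean(v), sd = sd(v),
         se = sd(v) / sqrt(length(v)))
  })
  means <- vapply(stats_by, `[[`, numeric(1), "mean")
  ses <- vapply(stats_by, `[[`, numeric(1), "se")
  diffs <- diff(means)
  se_diffs <- sqrt(ses[-length(ses)]^2 + ses[-1]^2)
  separable <- all(diffs > 2 * se_diffs)
  ctrl <- intensity[manifest$condition == conditions[1]]
  cut <- mean(ctrl) + k_sd * sd(ctrl)
  test_frac <- vapply(conditions[-1], function(cn)
    mean(intensity[manifest$condition == cn] > cut), numeric(1))
  summary_df <- data.frame(condition = conditions, n = vapply(stats_by, `[[`, numeric(1), "n"),
                           mean_intensity = means, sd = vapply(stats_by, `[[`, numeric(1), "sd"))
  list(analyte = analyte, component = row$component, summary = summary_df,
       ordering_ok = all(diffs > 0),
       separable = separable,
       cut = cut,
       control_detected = mean(ctrl > cut) > 0.5,
       detection_fraction = test_frac)
}

#' Maximum-residue-limit screening calls
#'
#' For each non-blank, non-standard sample: `detected` compares the analyte
#' contribution with the blank-based cut (mean + `k_sd` SD); the contribution
#' is converted to an estimated concentration by inverting the packaged
#' response curve through a calibration slope fitted to the level means; the
#' call is `positive` when the estimate reaches `cut_factor x` MRL,
#' `negative` (a detected but compliant residue level) below the guard band
#' starting at `(1 + cut_factor) / 2 x` MRL, and `indeterminate` in between.
#' The guard band keeps measurement dispersion at the MRL itself from
#' flipping compliant samples to positive.
#'
#' @inheritParams concentration_trend
#' @param mrl maximum residue limit, ppm.
#' @param saturation_conc saturation scale of the response curve used for
#'   inversion (the packaged urine model's value by default).
#' @param cut_factor multiplicative guard band around the MRL.
#' @param k_sd multiple of the blank SD defining the detection cut.
#' @return Object of class `screening_report`: data frame with one row per
#'   sample (`sample_id`, `condition`, `concentration_ppm`, `intensity`,
#'   `detected`, `estimated_ppm`, `call`).
#' @export
screen_samples <- function(result, assignment, manifest,
                           analyte = "enrofloxacin", mrl = 100,
                           saturation_conc = 2000, cut_factor = 1.5,
                           k_sd = 3, intensity = NULL) {
  row <- assignment[assignment$analyte == analyte, ]
  if (!nrow(row) || !row$assigned)
    stop_sersmcr("component for '%s' is not assigned", analyte)
  intensity <- intensity %||% result$C[, row$component]
  blanks <- manifest$concentration_ppm == 0
  cut <- if (any(blanks))
    mean(intensity[blanks]) + k_sd * sd(intensity[blanks]) else 0
  test <- !blanks & manifest$condition != "standard"
  g <- function(cc) response_curve(cc, saturation_conc)
  levels <- sort(unique(manifest$concentration_ppm[test]))
  level_means <- vapply(levels, function(cc)
    mean(intensity[test & manifest$concentration_ppm == cc]), numeric(1))
  slope <- sum(level_means * g(levels)) / sum(g(levels)^2)
  g_inv <- function(y) {
    eff <- pmax(y, 0) / slope
    ifelse(eff >= saturation_conc, Inf, eff / (1 - eff / saturation_conc))
  }
  est <- g_inv(intensity)
  ind_lo <- mrl * (1 + cut_factor) / 2
  call <- ifelse(!(intensity > cut), "negative",
                 ifelse(est >= cut_factor * mrl, "positive",
                        ifelse(est < ind_lo, "negative", "indeterminate")))
  out <- data.frame(sample_id = manifest$sample_id,
                    condition = manifest$condition,
                    concentration_ppm = manifest$concentration_ppm,
                    analyte = analyte,
                    intensity = intensity,
                    detected = intensity > cut,
                    estimated_ppm = est,
                    call = call,
                    stringsAsFactors = FALSE)[test, ]
  attr(out, "mrl") <- mrl
  attr(out, "cut") <- cut
  class(out) <- c("screening_report", class(out))
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %s, MRL %g ppm, %d samples\n",
              x$analyte[1], attr(x, "mrl"), nrow(x)))
  tab <- table(x$concentration_ppm, x$call)
  print(tab)
  invisible(x)
}
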