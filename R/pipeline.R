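#' Resolve a complete run configuration for a scenario
#'
#' Flat key-value configuration for a screening run.  Scenario defaults
#' follow the packaged study designs: six-component unmixing for the water
#' dilution and spiked-urine runs, four components for the in-vivo run.
#' Unknown keys are rejected.
#'
#' @param scenario `"water_dilution"`, `"spiked_urine"` or `"in_vivo"`.
#' @param seed integer master seed.
#' @param ... overrides for any configuration key (see the default list in
#'   the function body: `analyte`, `n_components`, `ref_weight`, `max_iter`,
#'   `tol`, `snr_threshold`, `window_cm1`, `rule`, `assign_threshold`,
#'   `k_sd`, `mrl`, `cut_factor`, `baseline_lambda`, `baseline_p`,
#'   `data_dir`, `out_dir`).
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(scenario = c("water_dilution", "spiked_urine",
                                    "in_vivo"),
                       seed = 1L, ...) {
  scenario <- match.arg(scenario)
  cfg <- list(
    config_version = 1L,
    scenario = scenario,
    seed = as.integer(seed),
    analyte = "enrofloxacin",
    n_components = if (scenario == "in_vivo") 4L else 6L,
    # the deliberately small in-vivo model needs the reference anchor
    ref_weight = if (scenario == "in_vivo") 1 else 0,
    max_iter = 2000L,
    tol = 1e-6,
    snr_threshold = 3,
    window_cm1 = 8,
    rule = 1,
    assign_threshold = 0.7,
    k_sd = 3,
    mrl = 100,
    cut_factor = 1.5,
    # stiff baseline for quiet aqueous runs; flexible for fluorescent urine
    baseline_lambda = if (scenario == "water_dilution") 1e5 else 1e4,
    baseline_p = 0.01,
    data_dir = NA_character_,
    out_dir = NA_character_)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_sersmcr("unknown configuration keys: %s",
                 paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a flat key=value configuration file
#'
#' Plain-text format, one `key = value` pair per line; `#` starts a comment.
#' Unknown keys are rejected by [run_config()].
#'
#' @param path file path.
#' @return A `run_config` (reader) or `path` invisibly (writer).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_sersmcr("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(vapply(kv, length, integer(1)) != 2)
  if (length(bad))
    stop_sersmcr("'%s': cannot parse line %d ('%s')", path, bad[1], lines[bad[1]])
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    v <- x[[2]]
    if (v == "NA") return(NA_character_)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  ints <- intersect(keys, c("seed", "n_components", "max_iter",
                            "config_version"))
  vals[ints] <- lapply(vals[ints], as.integer)
  scenario <- vals$scenario %||% "water_dilution"
  vals$scenario <- NULL
  vals$config_version <- NULL
  do.call(run_config, c(list(scenario = scenario), vals))
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, format(cfg[[k]], scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

log_msg <- function(cfg, fmt, ...) {
  message(sprintf("[sersmcr %s seed=%d] %s", cfg$scenario, cfg$seed,
                  sprintf(fmt, ...)))
}

#' Simulate a scenario dataset and write it to disk
#'
#' @param cfg a [run_config()] with `data_dir` set.
#' @return The manifest path, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.na(cfg$data_dir)) stop_sersmcr("cmd_simulate needs cfg$data_dir")
  design <- scenario_design(cfg$scenario, analyte = cfg$analyte,
                            seed = cfg$seed)
  ds <- generate_dataset(design)
  log_msg(cfg, "simulated %d spectra -> %s", nrow(ds$intensities), cfg$data_dir)
  man <- write_dataset(ds, cfg$data_dir)
  invisible(man)
}

#' Run the full screening pipeline for a scenario
#'
#' Simulates (or loads from `cfg$data_dir`) the scenario dataset, fits the
#' scenario's MCR-ALS model to the pooled raw spectra, assigns the analyte
#' component, computes blank-corrected analyte intensities and produces the
#' scenario reports:
#'
#' * `water_dilution`: univariate and unmixing LODs;
#' * `spiked_urine`: unmixing LOD, concentration trend and MRL screening;
#' * `in_vivo`: condition-ordering report (control / day 1 / day 7).
#'
#' When `cfg$out_dir` is set, component matrices and JSON reports (tagged
#' with the configuration hash) are written there.
#'
#' @param cfg a [run_config()].
#' @param dataset optional pre-built [spectral_dataset()] (overrides
#'   `data_dir` / simulation).
#' @return List of reports (class `run_report`).
#' @export
run_scenario <- function(cfg, dataset = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  refs <- antibiotic_references()
  ds <- dataset %||% (if (!is.na(cfg$data_dir))
    read_dataset(file.path(cfg$data_dir, "manifest.csv"))
    else generate_dataset(scenario_design(cfg$scenario, analyte = cfg$analyte,
                                          seed = cfg$seed)))
  log_msg(cfg, "dataset: %d spectra x %d channels",
          nrow(ds$intensities), ncol(ds$intensities))
  config <- mcr_config(cfg$n_components, max_iter = cfg$max_iter,
                       tol = cfg$tol, ref_weight = cfg$ref_weight,
                       seed = cfg$seed)
  # raw spectra: baseline and fluorescence are low-rank structure that the
  # component model separates itself
  ref_s <- list(build_reference_spectrum(refs[[cfg$analyte]], ds$wavenumber))
  names(ref_s) <- cfg$analyte
  fit <- mcr_fit(ds, refs = ref_s, config = config)
  if (!fit$converged) log_msg(cfg, "WARNING: ALS did not converge (%d iter)",
                              fit$n_iter)
  assignment <- match_components(fit, ref_s,
                                 threshold = cfg$assign_threshold)
  log_msg(cfg, "fit: lof %.3f%%, analyte cosine %.3f",
          fit$lof_percent[length(fit$lof_percent)],
          assignment$similarity[assignment$analyte == cfg$analyte])
  blanks <- ds$manifest$concentration_ppm == 0
  arow <- assignment[assignment$analyte == cfg$analyte, ]
  intensity <- if (arow$assigned && any(blanks))
    analyte_intensity(fit, refs[[cfg$analyte]], ds,
                      component = arow$component, blanks = blanks)
  else NULL
  reports <- list(scenario = cfg$scenario, seed = cfg$seed,
                  config_hash = config_hash(cfg),
                  converged = fit$converged,
                  n_components = nrow(fit$S),
                  assignment = as.data.frame(unclass(assignment)))
  if (cfg$scenario == "water_dilution") {
    reports$lod_univariate <- lod_univariate(
      ds, refs[[cfg$analyte]], rule = cfg$rule,
      snr_threshold = cfg$snr_threshold, window_cm1 = cfg$window_cm1,
      lambda = cfg$baseline_lambda, p = cfg$baseline_p)
    reports$lod_mcr <- lod_mcr(
      ds, refs, analyte = cfg$analyte, config = config, rule = cfg$rule,
      threshold = cfg$assign_threshold, k_sd = cfg$k_sd,
      lambda = cfg$baseline_lambda, p = cfg$baseline_p)
  } else if (cfg$scenario == "spiked_urine") {
    reports$lod_mcr <- lod_mcr(
      ds, refs, analyte = cfg$analyte, config = config, rule = cfg$rule,
      threshold = cfg$assign_threshold, k_sd = cfg$k_sd,
      lambda = cfg$baseline_lambda, p = cfg$baseline_p)
    reports$trend <- concentration_trend(fit, assignment, ds$manifest,
                                         analyte = cfg$analyte,
                                         intensity = intensity)
    reports$screening <- screen_samples(fit, assignment, ds$manifest,
                                        analyte = cfg$analyte, mrl = cfg$mrl,
                                        cut_factor = cfg$cut_factor,
                                        k_sd = cfg$k_sd,
                                        intensity = intensity)
  } else {
    reports$conditions <- compare_conditions(fit, assignment, ds$manifest,
                                             analyte = cfg$analyte,
                                             k_sd = cfg$k_sd,
                                             intensity = intensity)
  }
  if (!is.na(cfg$out_dir)) write_run_report(reports, fit, assignment, cfg)
  class(reports) <- "run_report"
  reports
}

strip_heavy <- function(x) {
  if (inherits(x, "lod_result")) {
    x$details <- x$details[setdiff(names(x$details), c("fit", "assignment"))]
    return(unclass(x))
  }
  x
}

write_run_report <- function(reports, fit, assignment, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mcr_result(fit, cfg$out_dir, assignment = assignment)
  slim <- lapply(reports, strip_heavy)
  slim$screening <- if (!is.null(reports$screening))
    as.data.frame(unclass(reports$screening))
  jsonlite::write_json(slim, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  write_run_config(cfg, file.path(cfg$out_dir, "run_config.txt"))
  log_msg(cfg, "reports written to %s", cfg$out_dir)
  invisible(cfg$out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s (seed %d, %d components, %s)\n",
              x$scenario, x$seed, x$n_components,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$lod_univariate))
    cat(sprintf("  univariate LOD: %s ppm\n", format(x$lod_univariate$lod)))
  if (!is.null(x$lod_mcr))
    cat(sprintf("  unmixing LOD:   %s ppm\n", format(x$lod_mcr$lod)))
  if (!is.null(x$trend))
    cat(sprintf("  trend: Spearman rho = %.3f\n", x$trend$spearman_rho))
  if (!is.null(x$conditions))
    cat(sprintf("  ordering day7 > day1 > control: %s\n",
                x$conditions$ordering_ok))
  invisible(x)
}

#' Run the full pipeline end to end (simulate + analyse)
#'
#' Convenience wrapper equalling [cmd_simulate()] followed by
#' [run_scenario()] on the written dataset.
#'
#' @inheritParams run_scenario
#' @return A `run_report`.
#' @export
cmd_run <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.na(cfg$data_dir) &&
      !file.exists(file.path(cfg$data_dir, "manifest.csv")))
    cmd_simulate(cfg)
  run_scenario(cfg)
}
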