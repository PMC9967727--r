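#' Pure-variable (SIMPLISMA-style) channel selection
#'
#' Selects `n` wavenumber channels that behave as pure variables: high
#' relative standard deviation (purity) weighted, after the first pick, by
#' independence from the channels already chosen (determinant of the
#' correlation-like dispersion submatrix).  Used to initialize unmixing
#' components for which no reference spectrum is supplied.
#'
#' @param D data matrix, samples x channels.
#' @param n number of pure variables to select.
#' @param offset_frac noise offset as a fraction of the maximum channel mean;
#'   damps the purity of low-intensity channels.
#' @return Integer vector of channel indices, in selection order.
#' @export
pure_variables <- function(D, n, offset_frac = 0.05) {
  D <- as.matrix(D)
  m <- ncol(D)
  if (n < 1 || n > m) stop_sersmcr("cannot select %d pure variables from %d channels", n, m)
  mu <- colMeans(D)
  sg <- apply(D, 2, sd)
  delta <- offset_frac * max(mu, .Machine$double.eps)
  purity <- sg / (mu + delta)
  lambda <- sqrt(mu^2 + (sg + delta)^2)
  Z <- sweep(D, 2, pmax(lambda, .Machine$double.eps), "/")
  COO <- crossprod(Z) / nrow(Z)
  sel <- integer(0)
  for (step in seq_len(n)) {
    w <- vapply(seq_len(m), function(j) {
      if (j %in% sel) return(-Inf)
      idx <- c(sel, j)
      det(COO[idx, idx, drop = FALSE])
    }, numeric(1))
    score <- w * purity
    score[sel] <- -Inf
    sel <- c(sel, which.max(score))
  }
  sel
}

#' Configuration for the alternating-least-squares unmixing solver
#'
#' @param n_components number of components k (>= 1).
#' @param max_iter maximum ALS iterations.
#' @param tol convergence tolerance on the relative change of the
#'   lack-of-fit between iterations.
#' @param init `"reference_plus_random"` (seed with any supplied references,
#'   fill the rest by pure-variable selection) or `"random"`.
#' @param nonneg_C,nonneg_S apply non-negativity to the contribution /
#'   spectral half-steps.  When off, the half-step is ordinary least squares.
#' @param ref_weight strength of the soft reference prior: each seeded
#'   spectral row is pulled toward its reference during the S-step by a
#'   ridge term weighted with `ref_weight` times the component's current
#'   contribution norm (0 = references used for initialization only).
#' @param seed RNG seed used by random initialization.
#' @return An object of class `mcr_config`.
#' @export
mcr_config <- function(n_components, max_iter = 500, tol = 1e-6,
                       init = c("reference_plus_random", "random"),
                       nonneg_C = TRUE, nonneg_S = TRUE, ref_weight = 0,
                       seed = 1L) {
  init <- match.arg(init)
  if (n_components < 1) stop_sersmcr("n_components must be >= 1")
  if (max_iter < 1) stop_sersmcr("max_iter must be >= 1")
  if (!is.finite(tol) || tol <= 0) stop_sersmcr("tol must be > 0")
  if (!is.finite(ref_weight) || ref_weight < 0)
    stop_sersmcr("ref_weight must be >= 0")
  structure(list(n_components = as.integer(n_components),
                 max_iter = as.integer(max_iter), tol = tol, init = init,
                 nonneg_C = nonneg_C, nonneg_S = nonneg_S,
                 ref_weight = ref_weight, seed = as.integer(seed)),
            class = "mcr_config")
}

as_ref_rows <- function(refs, grid) {
  if (is.null(refs)) return(NULL)
  if (is.matrix(refs)) return(refs)
  if (inherits(refs, "reference_definition")) refs <- list(refs)
  rows <- lapply(refs, function(r) {
    if (inherits(r, "reference_definition"))
      build_reference_spectrum(r, grid)$intensity
    else if (inherits(r, "raman_spectrum"))
      resample_spectrum(r, grid)$intensity
    else as.numeric(r)
  })
  nm <- names(refs)
  if (is.null(nm))
    nm <- vapply(refs, function(r)
      if (inherits(r, "reference_definition")) r$analyte
      else if (inherits(r, "raman_spectrum")) r$meta$analyte
      else "ref", character(1))
  m <- do.call(rbind, rows)
  rownames(m) <- nm
  m
}

#' Initialize the unmixing factors
#'
#' Reference-seeded rows of `S0` are the supplied reference spectra
#' (unit-max); the remaining rows come from pure-variable selection -- each
#' selected channel contributes the data row that expresses it most strongly
#' -- or, under `init = "random"`, from seeded uniform draws.  When
#' references are seeded, the pure variables are selected on the residual
#' left after deflating the reference contributions, so the free components
#' start out describing background structure rather than duplicating the
#' seeded analyte.  If `bg_rows` names known analyte-free samples (blanks),
#' the free components are drawn from those rows only, which starts the
#' background components uncontaminated.  `C0` is then solved from `S0` by
#' (non-negative) least squares.
#'
#' @param D data matrix, samples x channels (or a [spectral_dataset()]).
#' @param refs references for seeded components: a list of
#'   [reference_definition()] / [spectrum()] objects, a matrix of rows on the
#'   data grid, or `NULL`.
#' @param config an [mcr_config()].
#' @param grid wavenumber grid (taken from the dataset when `D` is one).
#' @param bg_rows optional integer/logical index of known analyte-free rows
#'   (blanks) from which the non-seeded components are initialized.
#' @return List with elements `C0` (n x k) and `S0` (k x m).
#' @export
mcr_initialize <- function(D, refs = NULL, config, grid = NULL,
                           bg_rows = NULL) {
  if (inherits(D, "spectral_dataset")) {
    grid <- D$wavenumber
    D <- D$intensities
  }
  D <- as.matrix(D)
  k <- config$n_components
  if (k > min(dim(D)))
    stop_sersmcr("n_components = %d exceeds min(dim(D)) = %d", k, min(dim(D)))
  Sref <- as_ref_rows(refs, grid %||% seq_len(ncol(D)))
  n_ref <- if (is.null(Sref)) 0L else nrow(Sref)
  if (n_ref > k)
    stop_sersmcr("more references (%d) than components (%d)", n_ref, k)
  S0 <- matrix(0, k, ncol(D))
  if (n_ref > 0) S0[seq_len(n_ref), ] <- Sref
  n_free <- k - n_ref
  if (n_free > 0) {
    if (config$init == "random") {
      S0[(n_ref + 1):k, ] <- with_seed(config$seed,
        matrix(runif(n_free * ncol(D)), n_free))
    } else {
      R <- D
      if (n_ref > 0) {
        Cref <- t(nnls_solve(t(Sref), t(D)))
        R <- pmax(D - Cref %*% Sref, 0)
      }
      if (!is.null(bg_rows)) R <- R[bg_rows, , drop = FALSE]
      pv <- pure_variables(R, min(n_free, nrow(R)))
      for (i in seq_len(n_free)) {
        j <- pv[((i - 1) %% length(pv)) + 1]
        row <- pmax(R[which.max(R[, j]), ], 0)
        if (max(row) > 0) row <- row / max(row)
        S0[n_ref + i, ] <- row
      }
    }
  }
  # normalize rows to unit max where possible
  for (r in seq_len(k)) {
    mx <- max(S0[r, ])
    if (mx > 0) S0[r, ] <- S0[r, ] / mx
  }
  C0 <- if (config$nonneg_C) t(nnls_solve(t(S0), t(D)))
        else t(qr.solve(t(S0), t(D)))
  list(C0 = C0, S0 = S0, Sref = Sref, n_ref = n_ref)
}

lack_of_fit <- function(D, C, S) {
  100 * norm(D - C %*% S, "F") / norm(D, "F")
}

#' Fit a multivariate curve resolution model by alternating least squares
#'
#' Factorizes the non-negative data matrix `D` (samples x channels) as
#' `D ~ C S + E` with `C >= 0` (contributions) and `S >= 0` (component
#' spectra), alternating exact constrained half-steps: `C` given `S`, then
#' `S` given `C`, each solved by [nnls_solve()].  Iteration stops when the
#' relative change of the lack-of-fit `100 * ||D - C S||_F / ||D||_F` drops
#' below `tol`, or at `max_iter` (then `converged = FALSE`).  The scale
#' ambiguity is fixed by normalizing every row of `S` to unit maximum with
#' the compensating factor folded into `C`.  Reference-seeded components are
#' re-estimated during the iterations (soft prior), not frozen.
#'
#' @inheritParams mcr_initialize
#' @return An object of class `mcr_result`: list with `C`, `S`, `lof_percent`
#'   (per-iteration trace, element 1 = after initialization), `n_iter`,
#'   `converged`, `explained_variance`, `config`, `grid`, `regularized`.
#' @examples
#' c_true <- c(1, 2, 4)
#' s_true <- c(0, 1, 4, 1, 0, 0)
#' fit <- mcr_fit(outer(c_true, s_true), config = mcr_config(1))
#' fit$lof_percent[fit$n_iter + 1] < 1e-6
#' @export
mcr_fit <- function(D, refs = NULL, config, grid = NULL, bg_rows = NULL) {
  if (inherits(D, "spectral_dataset")) {
    grid <- D$wavenumber
    D <- D$intensities
  }
  D <- as.matrix(D)
  if (!all(is.finite(D))) stop_sersmcr("D contains non-finite values")
  if (min(D) < -1e-8 && (config$nonneg_C || config$nonneg_S))
    stop_sersmcr("D has negative entries (min %.3g); preprocess with clipping before a non-negative fit",
                 min(D))
  D[D < 0] <- 0
  init <- mcr_initialize(D, refs, config, grid, bg_rows = bg_rows)
  C <- init$C0; S <- init$S0
  n_ref <- init$n_ref
  reg <- FALSE
  lof <- lack_of_fit(D, C, S)
  for (it in seq_len(config$max_iter)) {
    if (config$nonneg_C) {
      Ct <- nnls_solve(t(S), t(D))
      reg <- reg || attr(Ct, "regularized")
      C <- t(Ct)
    } else C <- t(qr.solve(t(S), t(D)))
    A <- C; B <- D
    if (config$ref_weight > 0 && n_ref > 0) {
      # soft prior: ridge rows pulling seeded components toward their
      # reference, weighted by the component's current contribution norm
      W <- matrix(0, n_ref, ncol(C))
      for (r in seq_len(n_ref))
        W[r, r] <- config$ref_weight * sqrt(sum(C[, r]^2))
      A <- rbind(C, W)
      B <- rbind(D, diag(W[, seq_len(n_ref), drop = FALSE]) * init$Sref)
    }
    if (config$nonneg_S) {
      S <- nnls_solve(A, B)
      reg <- reg || attr(S, "regularized")
    } else S <- qr.solve(A, B)
    # resolve scale ambiguity: unit-max spectra, scale folded into C
    for (r in seq_len(nrow(S))) {
      mx <- max(S[r, ])
      if (mx > 0) {
        S[r, ] <- S[r, ] / mx
        C[, r] <- C[, r] * mx
      }
    }
    lof <- c(lof, lack_of_fit(D, C, S))
    i <- length(lof)
    if (abs(lof[i - 1] - lof[i]) <= config$tol * max(lof[i - 1], 1e-12)) break
  }
  res_norm2 <- norm(D - C %*% S, "F")^2
  colnames(S) <- NULL
  structure(list(C = C, S = S, lof_percent = lof, n_iter = length(lof) - 1L,
                 converged = length(lof) - 1L < config$max_iter ||
                   abs(lof[length(lof) - 1] - lof[length(lof)]) <=
                     config$tol * max(lof[length(lof) - 1], 1e-12),
                 explained_variance = 1 - res_norm2 / norm(D, "F")^2,
                 config = config, grid = grid, regularized = reg),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("<mcr_result> %d components, %d x %d data\n",
              nrow(x$S), nrow(x$C), ncol(x$S)))
  cat(sprintf("  lack of fit %.4g%% after %d iterations (%s), R2 = %.5f\n",
              x$lof_percent[length(x$lof_percent)], x$n_iter,
              if (x$converged) "converged" else "NOT converged",
              x$explained_variance))
  invisible(x)
}

#' @export
plot.mcr_result <- function(x, ..., components = seq_len(nrow(x$S))) {
  grid <- x$grid %||% seq_len(ncol(x$S))
  graphics::matplot(grid, t(x$S[components, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "Raman shift (cm-1)",
                    ylab = "Component intensity (a.u.)", ...)
  invisible(x)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Assign unmixed components to analytes by cosine matching
#'
#' Computes the cosine similarity between every component spectrum and every
#' baseline-free reference spectrum (built on the same grid) and assigns each
#' analyte its best-scoring component, provided the score reaches
#' `threshold`; ties go to the lower component index.
#'
#' @param result an [mcr_result()] (or a k x m matrix `S`).
#' @param references named list of [reference_definition()] objects, or of
#'   reference [spectrum()] objects already on the data grid (e.g. from
#'   [effective_reference()]).
#' @param threshold minimum cosine similarity for an assignment.
#' @param grid wavenumber grid of `S` (taken from the result if present).
#' @return Object of class `component_assignment`: data frame with one row
#'   per analyte (`analyte`, `component`, `similarity`, `assigned`) plus the
#'   full similarity matrix in attribute `"similarity_matrix"`.
#' @export
match_components <- function(result, references, threshold = 0.7,
                             grid = NULL) {
  S <- if (inherits(result, "mcr_result")) result$S else as.matrix(result)
  grid <- grid %||% (if (inherits(result, "mcr_result")) result$grid else NULL)
  if (is.null(grid)) stop_sersmcr("a wavenumber grid is required for matching")
  R <- as_ref_rows(references, grid)
  sim <- matrix(0, nrow(S), nrow(R),
                dimnames = list(NULL, rownames(R)))
  for (i in seq_len(nrow(S)))
    for (j in seq_len(nrow(R)))
      sim[i, j] <- cosine_similarity(S[i, ], R[j, ])
  out <- do.call(rbind, lapply(seq_len(ncol(sim)), function(j) {
    best <- which.max(sim[, j])  # which.max takes the lowest index on ties
    data.frame(analyte = colnames(sim)[j], component = as.integer(best),
               similarity = sim[best, j],
               assigned = sim[best, j] >= threshold,
               stringsAsFactors = FALSE)
  }))
  attr(out, "similarity_matrix") <- sim
  class(out) <- c("component_assignment", class(out))
  out
}

#' Serialize an unmixing result
#'
#' Writes `S.csv` (rows = components), `C.csv` (rows = samples) and a JSON
#' sidecar with the configuration, lack-of-fit trace and any assignments.
#'
#' @param result an [mcr_result()].
#' @param dir output directory.
#' @param assignment optional [match_components()] result.
#' @return `dir`, invisibly.
#' @export
write_mcr_result <- function(result, dir, assignment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  S <- as.data.frame(result$S)
  names(S) <- if (!is.null(result$grid)) paste0("w", result$grid)
              else paste0("ch", seq_len(ncol(result$S)))
  write.csv(cbind(component = seq_len(nrow(S)), S),
            file.path(dir, "S.csv"), row.names = FALSE)
  C <- as.data.frame(result$C)
  names(C) <- paste0("component_", seq_len(ncol(C)))
  write.csv(cbind(sample = rownames(result$C) %||% seq_len(nrow(C)), C),
            file.path(dir, "C.csv"), row.names = FALSE)
  side <- list(config = unclass(result$config),
               lof_percent = result$lof_percent,
               n_iter = result$n_iter, converged = result$converged,
               explained_variance = result$explained_variance,
               regularized = result$regularized)
  if (!is.null(assignment))
    side$assignment <- as.data.frame(unclass(assignment))
  jsonlite::write_json(side, file.path(dir, "mcr.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
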