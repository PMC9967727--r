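test_that("exact rank-1 data is factorized to numerical precision", {
  c_true <- c(1, 2, 4, 0.5)
  s_true <- peak_profile(peak_spec(500, fwhm = 16), seq(400, 700, 2))
  D <- outer(c_true, s_true)
  fit <- mcr_fit(D, config = mcr_config(1, tol = 1e-10))
  expect_lt(tail(fit$lof_percent, 1), 1e-6)
  cosine <- sum(fit$S[1, ] * s_true) / sqrt(sum(fit$S[1, ]^2) * sum(s_true^2))
  expect_gte(cosine, 0.9999)
  expect_equal(max(fit$S[1, ]), 1)
})

test_that("noiseless two-component mixtures are recovered across 20 seeded runs", {
  for (seed in 1:20) {
    mix <- make_two_component(seed)
    fit <- mcr_fit(mix$D, config = mcr_config(2, tol = 1e-9, seed = seed),
                   grid = mix$grid)
    # match recovered to true components by best cosine
    cos2 <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    sims <- outer(1:2, 1:2, Vectorize(function(i, j)
      cos2(fit$S[i, ], mix$S[j, ])))
    perm <- if (sims[1, 1] + sims[2, 2] >= sims[1, 2] + sims[2, 1])
      c(1, 2) else c(2, 1)
    for (j in 1:2) {
      expect_gte(sims[perm[j], j], 0.99)
      expect_gte(cor(fit$C[, perm[j]], mix$C[, j]), 0.99)
    }
  }
})

test_that("lack of fit is non-increasing across iterations", {
  mix <- make_two_component(5)
  D <- pmax(mix$D + matrix(rnorm(length(mix$D), sd = 0.01), nrow(mix$D)), 0)
  fit <- mcr_fit(D, config = mcr_config(3, seed = 1))
  expect_true(all(diff(fit$lof_percent) <= 1e-9))
})

test_that("the row-max convention resolves the scale ambiguity", {
  mix <- make_two_component(9)
  D <- pmax(mix$D + matrix(rnorm(length(mix$D), sd = 0.01), nrow(mix$D)), 0)
  fit <- mcr_fit(D, config = mcr_config(2, seed = 1, tol = 1e-10,
                                        max_iter = 2000))
  expect_equal(unname(apply(fit$S, 1, max)), rep(1, 2))
  # refitting from the returned factors barely moves the objective
  lof0 <- tail(fit$lof_percent, 1)
  C2 <- t(nnls_solve(t(fit$S), t(D)))
  S2 <- nnls_solve(C2, D)
  lof1 <- 100 * norm(D - C2 %*% S2, "F") / norm(D, "F")
  expect_lt(lof0 - lof1, 1e-6)
  expect_lte(lof1, lof0 + 1e-10)
})

test_that("the final objective matches multiplicative-update NMF from the same start", {
  for (seed in 1:5) {
    withr::with_seed(seed, D <- matrix(runif(12), 4, 3))
    cfg <- mcr_config(2, tol = 1e-12, max_iter = 5000, seed = seed,
                      init = "random")
    init <- mcr_initialize(D, config = cfg)
    fit <- mcr_fit(D, config = cfg)
    mu <- nmf_mu(D, pmax(init$C0, 1e-6), pmax(init$S0, 1e-6))
    obj_als <- norm(D - fit$C %*% fit$S, "F")
    expect_lt(abs(obj_als - mu$obj), 1e-6 + 1e-3 * mu$obj)
    expect_lte(obj_als, mu$obj + 1e-6)  # ALS at least as good
  }
})

test_that("pure-variable selection separates the true component supports", {
  mix <- make_two_component(3)
  pv <- pure_variables(mix$D, 2)
  # component supports: s1 peaks near 500/560, s2 near 610/450
  which_comp <- function(j) which.max(c(mix$S[1, j], mix$S[2, j]))
  expect_setequal(vapply(pv, which_comp, integer(1)), c(1, 2))
})

test_that("reference seeding puts the reference in row one and is deterministic", {
  refs <- antibiotic_references()
  ds <- generate_dataset(dataset_design(
    data.frame(label = "c5", analyte = "enrofloxacin",
               concentration_ppm = 5, n_replicates = 8),
    water_matrix_model(), seed = 3))
  cfg <- mcr_config(3, seed = 9)
  ref_row <- build_reference_spectrum(refs$enrofloxacin, ds$wavenumber)
  i1 <- mcr_initialize(ds$intensities, refs = list(enrofloxacin = ref_row),
                       config = cfg, grid = ds$wavenumber)
  i2 <- mcr_initialize(ds$intensities, refs = list(enrofloxacin = ref_row),
                       config = cfg, grid = ds$wavenumber)
  expect_equal(i1$S0[1, ], ref_row$intensity)
  expect_identical(i1, i2)
  expect_error(mcr_initialize(ds$intensities, config = mcr_config(20)),
               "n_components")
})

test_that("component matching scores references correctly", {
  refs <- antibiotic_references()
  grid <- default_grid()
  R <- reference_matrix(refs, grid)
  # a component equal to the reference scores 1
  asg <- match_components(R["enrofloxacin", , drop = FALSE],
                          refs["enrofloxacin"], grid = grid)
  expect_equal(asg$similarity, 1, tolerance = 1e-12)
  expect_true(asg$assigned)
  # orthogonal non-overlapping peaks score ~0 and stay unassigned
  far <- peak_profile(peak_spec(450, fwhm = 10), grid)
  asg2 <- match_components(rbind(far), refs["neomycin"], grid = grid)
  expect_lt(asg2$similarity, 0.1)
  expect_false(asg2$assigned)
  # ties break toward the lower component index
  S <- rbind(R["neomycin", ], R["neomycin", ])
  asg3 <- match_components(S, refs["neomycin"], grid = grid)
  expect_equal(asg3$component, 1L)
})

test_that("non-finite and negative inputs are rejected", {
  D <- matrix(1, 3, 5)
  D[2, 2] <- NA
  expect_error(mcr_fit(D, config = mcr_config(1)), "non-finite")
  D[2, 2] <- -3
  expect_error(mcr_fit(D, config = mcr_config(1)), "negative")
})

test_that("results serialize to S/C matrices plus a JSON sidecar", {
  mix <- make_two_component(2)
  fit <- mcr_fit(mix$D, config = mcr_config(2, seed = 1), grid = mix$grid)
  dir <- tempfile()
  write_mcr_result(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("S.csv", "C.csv", "mcr.json")))))
  side <- jsonlite::read_json(file.path(dir, "mcr.json"), simplifyVector = TRUE)
  expect_equal(side$config$n_components, 2)
  expect_length(side$lof_percent, fit$n_iter + 1)
  unlink(dir, recursive = TRUE)
})
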