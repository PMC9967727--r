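# Independent oracles used to cross-check the solvers.

# Exhaustive active-set search: the optimum of min ||Ax - b||, x >= 0 is the
# best non-negative least-squares solution over some passive set.
nnls_brute <- function(A, b) {
  k <- ncol(A)
  best <- list(obj = sum(b^2), x = rep(0, k))
  for (mask in seq_len(2^k) - 1L) {
    P <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    if (!any(P)) next
    sol <- tryCatch(qr.solve(A[, P, drop = FALSE], b), error = function(e) NULL)
    if (is.null(sol) || any(sol < -1e-12)) next
    x <- rep(0, k)
    x[P] <- pmax(sol, 0)
    obj <- sum((A %*% x - b)^2)
    if (obj < best$obj) best <- list(obj = obj, x = x)
  }
  best
}

# Lee-Seung multiplicative updates for min ||D - C S||_F^2, C,S >= 0:
# an algorithm entirely different from alternating NNLS.
nmf_mu <- function(D, C, S, n_iter = 20000, eps = 1e-12) {
  for (i in seq_len(n_iter)) {
    C <- C * (D %*% t(S)) / (C %*% S %*% t(S) + eps)
    S <- S * (t(C) %*% D) / (t(C) %*% C %*% S + eps)
  }
  list(C = C, S = S, obj = norm(D - C %*% S, "F"))
}

# Noiseless two-component mixtures with known factors, on a small grid.
make_two_component <- function(seed, n = 12, m = 120) {
  grid <- seq(400, 400 + 2 * (m - 1), by = 2)
  s1 <- peak_profile(peak_spec(500, fwhm = 16), grid) +
    peak_profile(peak_spec(560, fwhm = 16, rel_amplitude = 0.6), grid)
  s2 <- peak_profile(peak_spec(610, fwhm = 16), grid) +
    peak_profile(peak_spec(450, fwhm = 16, rel_amplitude = 0.5), grid)
  # near-pure samples on both sides keep the factorization identifiable
  withr::with_seed(seed, {
    half <- n %/% 2
    C <- rbind(cbind(runif(half, 1, 2), runif(half, 0, 0.15)),
               cbind(runif(n - half, 0, 0.15), runif(n - half, 1, 2)))
  })
  list(D = C %*% rbind(s1, s2), C = C, S = rbind(s1, s2), grid = grid)
}
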