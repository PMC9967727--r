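#' Non-negative least squares for one or many right-hand sides
#'
#' Solves `min ||A x - b||^2` subject to `x >= 0` independently for every
#' column `b` of `B`, by the Lawson-Hanson active-set method applied to the
#' normal equations.  Two implementation details make the batched call cheap
#' inside the alternating solver: all columns first get the unconstrained
#' solution from a single factorization (columns that come out non-negative
#' are done), and passive-set solves are cached per active-set pattern within
#' the call, since k is small and most columns share patterns.
#'
#' If the passive-set Gram submatrix is numerically singular the solve falls
#' back to a ridge-regularized system and the result is flagged via the
#' `"regularized"` attribute.
#'
#' @param A numeric matrix (m x k).
#' @param B numeric matrix or vector (m x n right-hand sides).
#' @param tol non-negativity / optimality tolerance; default scales with the
#'   Gram matrix.
#' @return A k x n matrix `X >= 0` (a vector input `B` gives a one-column
#'   matrix), with attribute `regularized` (logical scalar).
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2)
#' nnls_solve(A, c(3, -2))  # projection: c(3, 0)
#' @export
nnls_solve <- function(A, B, tol = NULL) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (nrow(A) != nrow(B))
    stop_sersmcr("A (%d rows) and B (%d rows) are not conformable",
                 nrow(A), nrow(B))
  k <- ncol(A); n <- ncol(B)
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  if (is.null(tol)) tol <- 1e-12 * max(1, max(abs(diag(AtA))))
  reg_flag <- FALSE
  cache <- new.env(parent = emptyenv())
  solve_passive <- function(P, rhs) {
    key <- paste(which(P), collapse = ",")
    R <- cache[[key]]
    if (is.null(R)) {
      R <- tryCatch(chol(AtA[P, P, drop = FALSE]), error = function(e) NULL)
      if (is.null(R)) {
        reg_flag <<- TRUE
        ridge <- 1e-10 * max(1, mean(diag(AtA)))
        R <- chol(AtA[P, P, drop = FALSE] + ridge * diag(sum(P)))
      }
      cache[[key]] <- R
    }
    backsolve(R, forwardsolve(t(R), rhs))
  }
  X <- matrix(0, k, n)
  # Fast path: unconstrained solution for all columns at once.
  X0 <- tryCatch(solve_passive(rep(TRUE, k), AtB), error = function(e) NULL)
  todo <- seq_len(n)
  if (!is.null(X0)) {
    ok <- colSums(X0 < -tol) == 0
    if (any(ok)) {
      X[, ok] <- pmax(X0[, ok, drop = FALSE], 0)
      todo <- which(!ok)
    }
  }
  maxit <- 30 * (k + 1)
  for (j in todo) {
    Atb <- AtB[, j]
    x <- numeric(k)
    P <- rep(FALSE, k)
    w <- Atb
    it <- 0
    while (any(!P) && any(w[!P] > tol) && it < maxit) {
      it <- it + 1
      cand <- which(!P)
      P[cand[which.max(w[cand])]] <- TRUE
      repeat {
        s <- numeric(k)
        s[P] <- solve_passive(P, Atb[P])
        if (all(s[P] > tol)) break
        drop_set <- P & s <= tol
        alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
        x <- x + alpha * (s - x)
        P[P & x <= tol] <- FALSE
        if (!any(P)) break
      }
      x <- s
      x[!P] <- 0
      w <- Atb - AtA %*% x
    }
    X[, j] <- pmax(x, 0)
  }
  attr(X, "regularized") <- reg_flag
  X
}
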