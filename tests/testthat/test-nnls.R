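test_that("identity designs reproduce (projected) right-hand sides", {
  A <- diag(3)
  B <- matrix(c(1, 2, 3), 3)
  expect_equal(unname(nnls_solve(A, B)), B, ignore_attr = TRUE)
  b2 <- c(3, -2, 0.5)
  expect_equal(as.numeric(nnls_solve(A, b2)), pmax(b2, 0))
})

test_that("the solution matches the exhaustive active-set oracle on random systems", {
  worst <- 0
  for (i in 1:100) {
    withr::with_seed(2000 + i, {
      A <- matrix(rnorm(6), 3, 2)
      b <- rnorm(3)
    })
    x <- nnls_solve(A, b)
    oracle <- nnls_brute(A, b)
    obj <- sum((A %*% x - b)^2)
    worst <- max(worst, obj - oracle$obj)
    expect_true(all(x >= 0))
  }
  expect_lt(worst, 1e-8)
})

test_that("wider random systems also agree with the oracle", {
  for (i in 1:25) {
    withr::with_seed(3000 + i, {
      A <- matrix(rnorm(20), 5, 4)
      b <- rnorm(5)
    })
    x <- nnls_solve(A, b)
    expect_lt(sum((A %*% x - b)^2) - nnls_brute(A, b)$obj, 1e-8)
  }
})

test_that("the residual never exceeds that of the zero solution", {
  for (i in 1:20) {
    withr::with_seed(4000 + i, {
      A <- matrix(rnorm(12), 4, 3)
      b <- rnorm(4)
    })
    x <- nnls_solve(A, b)
    expect_lte(sum((A %*% x - b)^2), sum(b^2) + 1e-12)
  }
})

test_that("rank-deficient designs fall back to regularization and are flagged", {
  A <- cbind(c(1, 1, 1), c(1, 1, 1))   # perfectly collinear
  x <- nnls_solve(A, c(3, 3, 3))
  expect_true(attr(x, "regularized"))
  expect_equal(as.numeric(A %*% x), c(3, 3, 3), tolerance = 1e-4)
})

test_that("non-conformable inputs are rejected", {
  expect_error(nnls_solve(matrix(1, 3, 2), rep(1, 4)), "conformable")
})
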