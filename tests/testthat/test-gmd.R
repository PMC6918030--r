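test_that("GMD reduces to the SVD under identity kernels", {
  f <- gmd(diag(c(3, 1)), q = 2)
  expect_equal(f$S, c(3, 1))

  for (seed in 1:10) {
    x <- rand_matrix(6, 4, seed)
    f <- gmd(x, q = 4)
    expect_equal(f$S, svd(x)$d, tolerance = 1e-8)
  }
})

test_that("the 2x2 worked example is recovered exactly", {
  f <- gmd(diag(2), H = diag(c(4, 1)), R = NULL, q = 2)
  expect_equal(f$S, c(2, 1), tolerance = 1e-10)
  expect_equal(unname(f$U), rbind(c(0.5, 0), c(0, 1)), tolerance = 1e-8)
  expect_equal(unname(f$V), diag(2), tolerance = 1e-8)
  expect_equal(variance_explained(f), c(0.8, 0.2), tolerance = 1e-10)
  # exact reconstruction at full rank
  expect_lt(max(abs(f$U %*% diag(f$S) %*% t(f$V) - diag(2))), 1e-8)

  g <- gmd_eigen_oracle(diag(2), H = diag(c(4, 1)), q = 2)
  expect_equal(g$S^2, c(4, 1), tolerance = 1e-10)
  expect_equal(unname(g$U), rbind(c(0.5, 0), c(0, 1)), tolerance = 1e-8)
})

test_that("full-rank GMD decomposes X exactly in the H,R-seminorm", {
  set.seed(14)
  for (i in 1:5) {
    x <- rand_matrix(6, 5)
    H <- rand_psd(6)
    R <- rand_psd(5)
    f <- gmd(x, H, R, q = 5)
    resid <- x - f$U %*% (f$S * t(f$V))
    expect_lt(hr_norm_sq(resid, H, R), 1e-8)
  }
})

test_that("power-iteration solver and eigen oracle agree on random problems", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:12, 1); p <- sample(3:12, 1)
    x <- rand_matrix(n, p)
    H <- rand_psd(n)
    R <- rand_psd(p)
    q <- min(n, p, 3)
    f <- gmd(x, H, R, q)
    g <- gmd_eigen_oracle(x, H, R, q)
    expect_lt(max(abs(f$S - g$S)), 1e-8)
    # subspace agreement via principal angles in the H- (R-) metrics
    expect_lt(max_principal_angle(f$U, g$U, H), 1e-6)
    expect_lt(max_principal_angle(f$V, g$V, R), 1e-6)
  }
})

test_that("GMD solutions satisfy the duality and orthonormality identities", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:10, 1); p <- sample(4:9, 1)
    x <- rand_matrix(n, p)
    H <- rand_psd(n)
    R <- rand_psd(p)
    q <- min(n, p, 4)
    f <- gmd(x, H, R, q)
    expect_lt(max(abs(t(f$U) %*% H %*% f$U - diag(f$q))), 1e-8)
    expect_lt(max(abs(t(f$V) %*% R %*% f$V - diag(f$q))), 1e-8)
    # duality: V S = X' H U
    expect_lt(max(abs(f$V %*% diag(f$S, f$q) - crossprod(x, H %*% f$U))),
              1e-8)
    expect_false(is.unsorted(rev(f$S)))
  }
})

test_that("objective equals the HSIC trace form and never increases with q", {
  set.seed(55)
  x <- rand_matrix(7, 6)
  H <- rand_psd(7)
  obj <- function(fit, q) {
    resid <- x - fit$U[, 1:q, drop = FALSE] %*%
      (fit$S[1:q] * t(fit$V[, 1:q, drop = FALSE]))
    hr_norm_sq(resid, H, NULL)
  }
  f <- gmd(x, H, q = 6)
  vals <- vapply(1:6, function(q) obj(f, q), numeric(1))
  expect_true(all(diff(vals) <= 1e-10))
  # R = I: objective is tr(K1 K2) with K1 the residual Gram, K2 = H
  resid <- x - f$U %*% (f$S * t(f$V))
  expect_equal(hr_norm_sq(resid, H, NULL),
               sum(tcrossprod(resid) * H), tolerance = 1e-12)
})

test_that("hr_norm_sq generalizes the Frobenius norm", {
  x <- rand_matrix(5, 4, seed = 77)
  expect_equal(hr_norm_sq(x), sum(x^2))
  expect_equal(hr_norm_sq(diag(2), H = diag(c(4, 1))), 5)
  expect_equal(hr_norm_sq(matrix(0, 3, 2), rand_psd(3, 1), rand_psd(2, 2)), 0)
})

test_that("variance proportions sum to one at full rank", {
  set.seed(19)
  x <- rand_matrix(6, 5)
  H <- rand_psd(6)
  f <- gmd(x, H, q = 5)
  expect_equal(sum(variance_explained(f)), 1, tolerance = 1e-8)
  expect_error(variance_explained(gmd(matrix(0, 3, 3), q = 1)),
               "total variance")
})

test_that("rank-deficient kernels cap the number of components", {
  # H with rank 2 on 4 samples: at most 2 components exist
  set.seed(23)
  B <- qr.Q(qr(rand_matrix(4, 2)))
  H <- B %*% t(B)
  x <- rand_matrix(4, 5)
  f <- gmd(x, H, q = 4)
  expect_lte(f$q, 2L)
  expect_lt(max(abs(t(f$U) %*% H %*% f$U - diag(f$q))), 1e-8)
})

test_that("kernel and dimension mismatches are rejected", {
  x <- rand_matrix(4, 3, seed = 2)
  expect_error(gmd(x, H = diag(5), q = 2), "5x5")
  expect_error(gmd(x, q = 10), "'q' must be")
  expect_error(gmd(x, H = diag(c(1, 1, 1, -1)), q = 2), "negative eigenvalue")
})
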