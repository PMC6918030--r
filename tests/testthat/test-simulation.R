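test_that("synthesize_kernel reproduces a prescribed spectrum", {
  z <- synthesize_kernel(4, c(0, 0, 0), seed = 1)
  expect_equal(unname(z$kernel$values), matrix(0, 4, 4), tolerance = 1e-12)

  spec <- c(3.09, 1.26, 0.77)
  sk <- synthesize_kernel(5, spec, seed = 2)
  ev <- eigen(sk$kernel$values, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, c(spec, 0, 0), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(sk$basis) - diag(3))), 1e-10)

  # spectrum is a seed invariant; the basis is not
  sk2 <- synthesize_kernel(5, spec, seed = 3)
  ev2 <- eigen(sk2$kernel$values, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev2, ev, tolerance = 1e-8)
  expect_gt(max(abs(sk2$kernel$values - sk$kernel$values)), 1e-4)

  expect_error(synthesize_kernel(2, c(1, 2, 3), seed = 1), "at least")
  expect_error(synthesize_kernel(4, c(1, -1), seed = 1), "nonnegative")
})

test_that("the planted design obeys the eigenvalue law d^2 lambda", {
  for (seed in c(1, 7)) {
    fx <- contrast_fixture(seed, n = 20, p = 24, q = 10)
    des <- fx$design
    expect_equal(des$X_S$values,
                 des$B %*% (des$D_S * t(des$V_sim)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    M <- tcrossprod(des$X_S$values) %*% fx$kernel$values
    got <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
    want <- sort(c(des$D_S^2 * des$Lambda,
                   rep(0, nrow(des$B) - length(des$D_S))), decreasing = TRUE)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("reference configuration reproduces the printed top eigenvalues", {
  fx <- contrast_fixture(11)
  M <- tcrossprod(fx$design$X_S$values) %*% fx$kernel$values
  top3 <- sort(Re(eigen(M, only.values = TRUE)$values),
               decreasing = TRUE)[1:3]
  expect_equal(round(top3, 2), c(1.11, 0.81, 0.77))
  # and the GMD solver returns their square roots as its values
  f <- gmd(fx$design$X_S, fx$kernel, q = 3)
  expect_equal(f$S^2, c(1.1124, 0.8064, 0.77), tolerance = 1e-8)
})

test_that("labels follow the sign of the first eigenvector", {
  fx <- contrast_fixture(5, n = 12, p = 15, q = 6)
  des <- fx$design
  expect_equal(des$labels, as.integer(des$B[, 1] > 0))
  # negating the first basis column flips every label
  B2 <- des$B; B2[, 1] <- -B2[, 1]
  des2 <- simulation_design(fx$kernel, B2, des$D_S, p = 15, seed = des$seed)
  expect_equal(des2$labels, 1L - des$labels)
})

test_that("all-zero weights give a zero data matrix", {
  sk <- synthesize_kernel(6, c(2, 1), seed = 3)
  des <- simulation_design(sk$kernel, sk$basis, c(0, 0), p = 8, seed = 4)
  expect_equal(unname(des$X_S$values), matrix(0, 6, 8))
})

test_that("selection contrast: GMD shows (1,2), AMD picks (2,3)", {
  fx <- contrast_fixture(1)
  ctr <- selection_contrast(fx$design, fx$kernel)
  expect_equal(ctr$gmd_dims, c(1L, 2L))
  expect_equal(ctr$amd_dims, c(2L, 3L))
  expect_equal(ctr$gmd_auc, 1.0, tolerance = 1e-6)
  expect_false(is.unsorted(rev(ctr$gmd_scree$proportion)))
  # AMD scree in eigenvector order mirrors the increasing weights
  expect_equal(ctr$amd_scree$value[1:3], c(0.6, 0.8, 1), tolerance = 1e-8)

  # single planted component: one GMD value sqrt(lambda_1), rest zero
  skm <- synthesize_kernel(8, c(2.5, 1, 0.5), seed = 9)
  dm <- simulation_design(skm$kernel, skm$basis, c(1, 0, 0), p = 10, seed = 2)
  fm <- gmd(dm$X_S, skm$kernel, q = 3)
  expect_equal(fm$S[1], sqrt(2.5), tolerance = 1e-8)
  expect_lte(fm$q, 3L)
  if (fm$q > 1) expect_lt(max(fm$S[-1]), 1e-8)
})

test_that("nonincreasing weights make both methods agree on (1,2)", {
  sk <- synthesize_kernel(10, c(3, 2, 1, 0.5), seed = 13)
  des <- simulation_design(sk$kernel, sk$basis, c(1, 0.8, 0.5, 0.2),
                           p = 12, seed = 14)
  ctr <- selection_contrast(des, sk$kernel, q = 4)
  expect_equal(ctr$amd_dims, c(1L, 2L))
  expect_equal(ctr$gmd_dims, c(1L, 2L))
})
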