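test_that("form biplot places samples at x_i'v and arrows at rows of V", {
  f <- gmd(diag(2), H = diag(c(4, 1)), R = NULL, q = 2)
  lay <- form_biplot(diag(2), f, dims = c(1, 2))
  expect_equal(unname(lay$sample_points), diag(2), tolerance = 1e-8)
  expect_equal(unname(lay$arrows), diag(2), tolerance = 1e-8)
  expect_equal(lay$prop_variance, c(0.8, 0.2), tolerance = 1e-10)

  # with R = I, sample points equal U diag(S) at the displayed dims
  set.seed(41)
  x <- rand_matrix(8, 6)
  H <- rand_psd(8)
  f2 <- gmd(x, H, q = 3)
  lay2 <- form_biplot(x, f2, dims = c(1, 2))
  expect_equal(lay2$sample_points,
               f2$U[, 1:2] %*% diag(f2$S[1:2]),
               tolerance = 1e-8, ignore_attr = TRUE)

  # a zero sample row sits at the origin
  x0 <- x; x0[3, ] <- 0
  lay3 <- form_biplot(x0, f2, dims = c(1, 2))
  expect_equal(unname(lay3$sample_points[3, ]), c(0, 0))

  expect_error(form_biplot(x, f2, dims = c(1, 9)), "dims")
})

test_that("identity-kernel form biplot reproduces the classical SVD-biplot", {
  x <- scale(rand_matrix(7, 5, seed = 61), scale = FALSE)
  f <- gmd(x, q = 4)
  lay <- form_biplot(x, f)
  sv <- svd(x)
  pts <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  # compare up to per-axis sign
  for (j in 1:2) {
    expect_equal(abs(lay$sample_points[, j]), abs(pts[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("project_sample reproduces training points and maps zero to origin", {
  set.seed(43)
  x <- rand_matrix(6, 5)
  H <- rand_psd(6)
  f <- gmd(x, H, q = 3)
  lay <- form_biplot(x, f, dims = c(1, 2))
  for (i in seq_len(nrow(x))) {
    expect_equal(project_sample(x[i, ], f, dims = c(1, 2)),
                 lay$sample_points[i, ], ignore_attr = TRUE)
  }
  expect_equal(unname(project_sample(numeric(5), f)), c(0, 0))
  expect_error(project_sample(numeric(3), f), "length")
})

test_that("covariance arrows partition the total variance", {
  # V = I2, S = (2, 1): lengths are the values themselves
  f <- gmd(diag(c(2, 1)), q = 2)
  ca <- covariance_arrows(f)
  expect_equal(unname(ca$arrow_lengths), c(2, 1))
  expect_equal(unname(ca$prop_by_variable), c(0.8, 0.2))

  set.seed(47)
  x <- rand_matrix(7, 5)
  H <- rand_psd(7)
  f2 <- gmd(x, H, q = 5)
  ca2 <- covariance_arrows(f2)
  expect_equal(sum(ca2$prop_by_variable), 1, tolerance = 1e-8)
  # sum_j sum_m v_jm^2 s_m^2 = sum_m s_m^2 since V'V = I
  expect_equal(sum(ca2$arrow_lengths^2), sum(f2$S^2), tolerance = 1e-10)

  fR <- gmd(x, H, R = rand_psd(5), q = 3)
  expect_error(covariance_arrows(fR), "R = identity")
})

test_that("scree tables expose GMD monotonicity and AMD non-monotonicity", {
  f <- gmd(diag(c(2, 1)), q = 2)
  sg <- scree(f, top = 10)
  expect_equal(sg$proportion, c(0.8, 0.2))
  expect_false(is.unsorted(rev(sg$proportion)))

  set.seed(53)
  x <- rand_matrix(9, 7)
  H <- rand_psd(9)
  sg2 <- scree(gmd(x, H, q = 6), top = 6)
  expect_false(is.unsorted(rev(sg2$proportion)))

  a <- amd(rbind(c(1, 0), c(0, 2)), H = diag(c(2, 1)))
  sa <- scree(a, top = 2)
  expect_equal(sa$proportion, c(0.2, 0.8))
  expect_true(is.unsorted(rev(sa$value)))
})

test_that("top_arrows ranks by length with lexicographic tie-breaks", {
  f <- gmd(diag(c(2, 1)), q = 2)
  lay <- form_biplot(diag(c(2, 1)), f)
  expect_equal(top_arrows(lay, 1), rownames(f$V)[1])
  expect_equal(length(top_arrows(lay, 2)), 2L)

  # equal lengths: IDs come back in lexicographic order
  arrows <- diag(2); rownames(arrows) <- c("zeta", "alpha")
  lay2 <- lay
  lay2$arrows <- arrows
  lay2$arrow_lengths <- sqrt(rowSums(arrows^2))
  expect_equal(top_arrows(lay2, 2), c("alpha", "zeta"))
  expect_error(top_arrows(lay, 5), "'m' must be")
})

test_that("layouts are equivariant to simultaneous permutation of samples", {
  set.seed(59)
  x <- rand_matrix(6, 4)
  rownames(x) <- sprintf("s%d", 1:6); colnames(x) <- sprintf("v%d", 1:4)
  H <- rand_psd(6); dimnames(H) <- list(rownames(x), rownames(x))
  f <- gmd(x, H, q = 2)
  lay <- form_biplot(x, f, dims = c(1, 2))

  perm <- sample(6)
  xp <- x[perm, ]
  Hp <- H[perm, perm]
  fp <- gmd(xp, Hp, q = 2)
  layp <- form_biplot(xp, fp, dims = c(1, 2))
  expect_equal(layp$sample_points[rownames(x), ], lay$sample_points,
               tolerance = 1e-7)
})
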