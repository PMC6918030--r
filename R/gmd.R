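# Generalized matrix decomposition.
#
# Solves argmin_{U,S,V} ||X - U S V'||^2_{H,R} subject to U'HU = I_q,
# V'RV = I_q, diag(S) >= 0, where ||X||^2_{H,R} = tr(X R X' H) and H, R are
# PSD similarity kernels on samples and variables. With H = I and R = I this
# is the SVD. Components are extracted one at a time by alternating
# power-iteration updates followed by rank-one deflation, which yields
# nonincreasing GMD values.

# Multiply by a kernel that may be NULL (identity): K %*% m
.kmul <- function(K, m) if (is.null(K)) m else K %*% m

.as_kernel_matrix <- function(K, n, ids, what) {
  if (is.null(K)) return(NULL)
  kv <- if (inherits(K, "similarity_kernel")) K$values else as.matrix(K)
  if (nrow(kv) != n || ncol(kv) != n) {
    stop(what, " kernel is ", nrow(kv), "x", ncol(kv),
         " but the data axis has length ", n)
  }
  if (!is.null(ids) && !is.null(rownames(kv))) {
    if (!identical(rownames(kv), ids)) {
      if (!setequal(rownames(kv), ids)) {
        stop(what, " kernel IDs do not match the data IDs")
      }
      kv <- kv[ids, ids, drop = FALSE]
    }
  }
  kv
}

.check_psd <- function(kv, what, tol = 1e-8) {
  if (is.null(kv)) return(invisible(NULL))
  e <- eigen(kv, symmetric = TRUE, only.values = TRUE)$values
  lam_max <- max(e, 0)
  if (min(e) < -tol * max(lam_max, 1)) {
    stop(what, " kernel has a negative eigenvalue (", format(min(e)),
         "); apply psd_project() first")
  }
  invisible(NULL)
}

# Flip the sign of a (u, v) pair so the largest-magnitude entry of v is
# positive; makes output reproducible across algorithmic routes.
.sign_fix <- function(u, v) {
  j <- which.max(abs(v))
  if (v[j] < 0) list(u = -u, v = -v) else list(u = u, v = v)
}

#' Generalized matrix decomposition by power iteration with deflation
#'
#' Finds the best rank-`q` approximation `U S V'` to `X` in the H,R-norm,
#' with `U' H U = I_q` and `V' R V = I_q`. Each component is obtained by
#' alternating the dual updates `u <- X R v` (normalized in the H-norm) and
#' `v <- X' H u` (normalized in the R-norm) until the component value
#' `s = u' H X R v` stabilizes, then deflating `X <- X - s u v'`. The
#' returned values `S` are nonincreasing, so a biplot can always display
#' components 1 and 2.
#'
#' `v` is initialized at the leading right singular vector of the current
#' deflated matrix, so no random seed is involved. If a candidate component
#' falls outside the range of `H` (or `R`), extraction stops early and
#' fewer than `q` components are returned.
#'
#' @param X a [data_matrix()] or numeric matrix (samples x variables).
#' @param H sample kernel: [similarity_kernel()], matrix, or `NULL` for the
#'   identity.
#' @param R variable kernel, same conventions; `NULL` (identity) gives the
#'   decomposition used by the covariance biplot.
#' @param q number of components, `1 <= q <= min(n, p)`.
#' @param tol convergence tolerance: iteration stops when both the
#'   relative change in the component value and the change in the right
#'   vector `v` fall below `tol` (default `1e-10`). The vector criterion
#'   is what guarantees `U'HU` and `V'RV` are identity to ~`tol`.
#' @param max_iter iteration cap per component (default 10000); hitting it
#'   flags `converged = FALSE` for that component but is not fatal.
#' @return An object of class `gmd` with elements `U` (n x k), `S`
#'   (length-k nonincreasing), `V` (p x k), `q` (components returned),
#'   `q_requested`, `total_variance = tr(X R X' H)`, `converged`,
#'   `iterations`, `identity_R`, and the sample/variable IDs.
#' @seealso [gmd_eigen_oracle()] for the eigendecomposition route,
#'   [form_biplot()] for display.
#' @export
gmd <- function(X, H = NULL, R = NULL, q = 2L, tol = 1e-10,
                max_iter = 10000L) {
  x <- .values(X)
  n <- nrow(x); p <- ncol(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(n))
  if (is.null(colnames(x))) colnames(x) <- paste0("var", seq_len(p))
  if (q < 1 || q > min(n, p)) {
    stop("'q' must be between 1 and min(n, p) = ", min(n, p))
  }
  Hm <- .as_kernel_matrix(H, n, rownames(x), "sample")
  Rm <- .as_kernel_matrix(R, p, colnames(x), "variable")
  .check_psd(Hm, "sample")
  .check_psd(Rm, "variable")

  total_variance <- hr_norm_sq(x, Hm, Rm)
  xd <- x
  U <- matrix(0, n, q); V <- matrix(0, p, q)
  S <- numeric(q); iters <- integer(q); conv <- logical(q)
  k <- 0L
  # absolute floor below which a component (or its H/R-norm) counts as zero
  floor_tol <- 1e-12 * max(sqrt(total_variance), 1)
  for (comp in seq_len(q)) {
    v <- tryCatch(svd(xd, nu = 0, nv = 1)$v[, 1],
                  error = function(e) NULL)
    if (is.null(v)) {  # LAPACK failure fallback: largest-norm column
      j <- which.max(colSums(xd^2))
      v <- numeric(p); v[j] <- 1
    }
    s_old <- -Inf; s <- 0; it <- 0L; ok <- FALSE; dead <- FALSE
    v_old <- rep(Inf, p); dv_old <- Inf
    repeat {
      it <- it + 1L
      u <- xd %*% .kmul(Rm, v)
      un <- sqrt(max(0, sum(u * .kmul(Hm, u))))
      if (un < floor_tol) { dead <- TRUE; break }
      u <- u / un
      v <- crossprod(xd, .kmul(Hm, u))
      vn <- sqrt(max(0, sum(v * .kmul(Rm, v))))
      if (vn < floor_tol) { dead <- TRUE; break }
      v <- v / vn
      dv <- min(max(abs(v - v_old)), max(abs(v + v_old)))  # sign-agnostic
      s <- sum(.kmul(Hm, u) * (xd %*% .kmul(Rm, v)))
      # Power iteration converges linearly at rate r (the eigenvalue
      # ratio); the per-step change dv understates the remaining error by
      # a factor r/(1 - r), so correct it Aitken-style before testing.
      r <- if (is.finite(dv_old) && dv_old > 0) dv / dv_old else 1
      err <- if (r < 1) dv * r / (1 - r) else dv
      if (is.finite(s_old) &&
          abs(s - s_old) <= tol * max(abs(s_old), 1e-300) &&
          max(dv, err) <= tol) {
        ok <- TRUE
        break
      }
      if (it >= max_iter) break
      s_old <- s
      v_old <- v
      dv_old <- dv
    }
    if (dead || s < floor_tol) break  # exhausted the H,R-seminorm of X
    sf <- .sign_fix(u, v)
    k <- comp
    U[, k] <- sf$u; V[, k] <- sf$v; S[k] <- s
    iters[k] <- it; conv[k] <- ok
    xd <- xd - S[k] * tcrossprod(U[, k], V[, k])
  }
  if (k == 0L) {
    # X has no mass in the H,R-seminorm; return a single zero component
    k <- 1L
  }
  # Deflation extracts exact components in whatever order the iteration
  # converges to them; reorder so the GMD values are nonincreasing.
  ord <- order(-S[seq_len(k)])
  U <- U[, ord, drop = FALSE]
  V <- V[, ord, drop = FALSE]
  S[seq_len(k)] <- S[ord]
  iters[seq_len(k)] <- iters[ord]
  conv[seq_len(k)] <- conv[ord]
  rownames(U) <- rownames(x); rownames(V) <- colnames(x)
  structure(
    list(U = U, S = S[seq_len(k)], V = V, q = k, q_requested = as.integer(q),
         total_variance = total_variance,
         converged = conv[seq_len(k)], iterations = iters[seq_len(k)],
         identity_R = is.null(Rm),
         sample_ids = rownames(x), variable_ids = colnames(x)),
    class = "gmd"
  )
}

#' Eigendecomposition route to the GMD (reference implementation)
#'
#' Computes the same decomposition as [gmd()] through the symmetric
#' reformulation: with `H = E L E'` and `R = F M F'`, the SVD
#' `P D Q' = H^{1/2} X R^{1/2}` gives `S = D`, `U = H^{+1/2} P`,
#' `V = R^{+1/2} Q`, where `+1/2` denotes the pseudo-inverse square root.
#' Equivalently, `S^2` holds the leading eigenvalues of `X R X' H`. This
#' route is independent of the power-iteration solver and serves as its
#' cross-check in the test suite.
#'
#' @inheritParams gmd
#' @param tol relative eigenvalue cutoff for the kernel square roots.
#' @return An object of class `gmd` (same contract as [gmd()];
#'   `iterations` is 0 and `converged` is `TRUE`).
#' @export
gmd_eigen_oracle <- function(X, H = NULL, R = NULL, q = 2L, tol = 1e-10) {
  x <- .values(X)
  n <- nrow(x); p <- ncol(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(n))
  if (is.null(colnames(x))) colnames(x) <- paste0("var", seq_len(p))
  if (q < 1 || q > min(n, p)) {
    stop("'q' must be between 1 and min(n, p) = ", min(n, p))
  }
  Hm <- .as_kernel_matrix(H, n, rownames(x), "sample")
  Rm <- .as_kernel_matrix(R, p, colnames(x), "variable")
  .check_psd(Hm, "sample")
  .check_psd(Rm, "variable")
  sqrtk <- function(K, n) {
    if (is.null(K)) {
      return(list(half = NULL, pinv_half = NULL))
    }
    e <- eigen(K, symmetric = TRUE)
    keep <- e$values > tol * max(e$values, 0)
    vk <- e$vectors[, keep, drop = FALSE]
    lk <- e$values[keep]
    list(half = vk %*% (sqrt(lk) * t(vk)),
         pinv_half = vk %*% (1 / sqrt(lk) * t(vk)))
  }
  Hs <- sqrtk(Hm, n); Rs <- sqrtk(Rm, p)
  y <- .kmul(Hs$half, x)
  y <- if (is.null(Rs$half)) y else y %*% Rs$half
  sv <- svd(y)
  pos <- sv$d > tol * max(sv$d, 0)
  k <- min(q, sum(pos))
  if (k == 0L) k <- 1L
  idx <- seq_len(k)
  U <- .kmul(Hs$pinv_half, sv$u[, idx, drop = FALSE])
  V <- sv$v[, idx, drop = FALSE]
  V <- if (is.null(Rs$pinv_half)) V else Rs$pinv_half %*% V
  S <- sv$d[idx]
  for (j in idx) {
    sf <- .sign_fix(U[, j], V[, j])
    U[, j] <- sf$u; V[, j] <- sf$v
  }
  rownames(U) <- rownames(x); rownames(V) <- colnames(x)
  structure(
    list(U = U, S = S, V = V, q = k, q_requested = as.integer(q),
         total_variance = hr_norm_sq(x, Hm, Rm),
         converged = rep(TRUE, k), iterations = rep(0L, k),
         identity_R = is.null(Rm),
         sample_ids = rownames(x), variable_ids = colnames(x)),
    class = "gmd"
  )
}

#' Squared H,R-norm of a matrix
#'
#' Computes `tr(X R X' H)`, the squared seminorm that the GMD objective
#' minimizes over rank-`q` residuals. With `H = R = I` this is the squared
#' Frobenius norm.
#'
#' @inheritParams gmd
#' @return A nonnegative scalar.
#' @export
hr_norm_sq <- function(X, H = NULL, R = NULL) {
  x <- .values(X)
  Hm <- if (is.null(H)) NULL else
    .as_kernel_matrix(H, nrow(x), rownames(x), "sample")
  Rm <- if (is.null(R)) NULL else
    .as_kernel_matrix(R, ncol(x), colnames(x), "variable")
  xr <- if (is.null(Rm)) x else x %*% Rm
  g <- tcrossprod(xr, x)            # X R X'
  if (is.null(Hm)) sum(diag(g)) else sum(g * Hm)
}

#' Proportion of total variance explained by each GMD component
#'
#' Component `k` explains `S_k^2 / tr(X R X' H)` of the total variance.
#' The proportions sum to one when the decomposition is exact (full rank).
#'
#' @param result a `gmd` object.
#' @return Numeric vector of proportions in `[0, 1]`.
#' @export
variance_explained <- function(result) {
  stopifnot(inherits(result, "gmd"))
  if (!(result$total_variance > 0)) {
    stop("total variance is zero; proportions are undefined")
  }
  result$S^2 / result$total_variance
}

#' @export
print.gmd <- function(x, ...) {
  cat("Generalized matrix decomposition:", length(x$sample_ids), "samples x",
      length(x$variable_ids), "variables,", x$q, "component(s)\n")
  cat("GMD values:", format(x$S, digits = 5), "\n")
  if (x$total_variance > 0) {
    cat("variance explained:",
        format(variance_explained(x), digits = 4), "\n")
  }
  invisible(x)
}
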