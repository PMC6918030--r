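# Approximate matrix duality (AMD) — the comparison decomposition.
#
# AMD fixes U as the eigenvectors of the sample kernel H (so the sample
# configuration depends only on H, not on X) and solves
# argmin_{V,D} ||X - U_H D V'||_F^2 per column via the duality
# d_k = ||X' u_k||, v_k = X' u_k / d_k. Unlike the GMD, the resulting
# "singular values" D need not be nonincreasing, which is why the display
# components must be chosen by the size of D rather than by position.

#' Approximate matrix duality decomposition
#'
#' @param X a [data_matrix()] or matrix (samples x variables); for the
#'   standard workflow, relative abundances that have been double-centered.
#' @param H sample [similarity_kernel()] or symmetric PSD matrix with rank
#'   at least 2.
#' @param tol relative eigenvalue cutoff defining "positive" eigenvalues of
#'   `H`; the default matches [psd_project()] so AMD and GMD see the same
#'   repaired kernel.
#' @return An object of class `amd` with elements `U_H` (eigenvectors of H
#'   for its positive eigenvalues, nonincreasing order), `H_eigenvalues`,
#'   `D` (per-column duality values, not necessarily monotone), `V` (unit
#'   columns; only approximately mutually orthogonal —
#'   `orthogonality_defect` reports max |v_i'v_j| off the diagonal),
#'   `selected` (indices of the two largest D), and `zero_components`
#'   flagging columns with `d_k = 0`, whose `v_k` is an arbitrary unit
#'   vector.
#' @export
amd <- function(X, H, tol = 1e-10) {
  x <- .values(X)
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(n))
  if (is.null(colnames(x))) colnames(x) <- paste0("var", seq_len(ncol(x)))
  Hm <- .as_kernel_matrix(H, n, rownames(x), "sample")
  e <- eigen(Hm, symmetric = TRUE)
  lam_max <- max(e$values, 0)
  if (min(e$values) < -1e-8 * max(lam_max, 1)) {
    stop("sample kernel has a negative eigenvalue; apply psd_project() first")
  }
  keep <- e$values > tol * lam_max
  r <- sum(keep)
  if (r < 2) stop("sample kernel must have rank at least 2 (rank = ", r, ")")
  U_H <- e$vectors[, keep, drop = FALSE]
  # deterministic eigenvector signs: largest-magnitude entry positive
  for (j in seq_len(r)) {
    i <- which.max(abs(U_H[, j]))
    if (U_H[i, j] < 0) U_H[, j] <- -U_H[, j]
  }
  XtU <- crossprod(x, U_H)           # columns X' u_k
  D <- sqrt(colSums(XtU^2))
  V <- XtU
  zero <- D <= 1e-12 * max(D, 1)
  for (j in seq_len(r)) {
    if (zero[j]) {
      V[, j] <- 0; V[1, j] <- 1      # arbitrary unit vector, flagged
    } else {
      V[, j] <- V[, j] / D[j]
    }
  }
  gram <- crossprod(V)
  defect <- max(abs(gram - diag(r)))
  rownames(U_H) <- rownames(x); rownames(V) <- colnames(x)
  res <- structure(
    list(U_H = U_H, H_eigenvalues = e$values[keep], D = D, V = V,
         rank = r, zero_components = zero, orthogonality_defect = defect,
         sample_ids = rownames(x), variable_ids = colnames(x)),
    class = "amd"
  )
  res$selected <- select_display_components(res)
  res
}

#' Display components of an AMD fit
#'
#' Because AMD values are not necessarily nonincreasing, the two components
#' shown in an AMD-biplot are those with the two largest `D` entries (not
#' components 1 and 2). Ties are broken toward the smaller index.
#'
#' @param result an `amd` object.
#' @return Integer pair of component indices in ascending order.
#' @export
select_display_components <- function(result) {
  stopifnot(inherits(result, "amd"))
  ord <- order(-result$D, seq_along(result$D))
  sort(ord[1:2])
}

#' @export
print.amd <- function(x, ...) {
  cat("AMD decomposition:", length(x$sample_ids), "samples x",
      length(x$variable_ids), "variables, rank", x$rank, "\n")
  cat("AMD values (eigenvector order):",
      format(x$D[seq_len(min(6, x$rank))], digits = 5),
      if (x$rank > 6) "...\n" else "\n")
  cat("display components:", x$selected[1], "and", x$selected[2], "\n")
  invisible(x)
}
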