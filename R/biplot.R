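# Biplot layouts: samples as points, variables as arrows, on the
# coordinate system of the decomposition's right vectors.

.new_layout <- function(points, arrows, component_indices, prop_variance,
                        style, source) {
  structure(
    list(sample_points = points, arrows = arrows,
         arrow_lengths = sqrt(rowSums(arrows^2)),
         component_indices = as.integer(component_indices),
         prop_variance = prop_variance, style = style, source = source),
    class = "biplot_layout"
  )
}

#' Form biplot layout from a GMD or AMD fit
#'
#' For a GMD fit, sample `i` is placed at `(x_i' v_a, x_i' v_b)` and the
#' arrow for variable `j` at `(V_ja, V_jb)` — the coordinates of the
#' standard basis vector `e_j` in the same system. For an AMD fit, sample
#' points are the selected columns of `U_H D` and arrows the matching
#' columns of `V`; the default `dims` then come from
#' [select_display_components()] rather than being `(1, 2)` — the central
#' difference between the two displays.
#'
#' @param X the [data_matrix()] (or matrix) that was decomposed; required
#'   for GMD fits, ignored for AMD fits.
#' @param result a `gmd` or `amd` object.
#' @param dims pair of component indices to display.
#' @return A `biplot_layout` with `sample_points` (n x 2), `arrows`
#'   (p x 2), `arrow_lengths`, `component_indices`, `prop_variance` and
#'   `source`.
#' @export
form_biplot <- function(X, result, dims = NULL) {
  UseMethod("form_biplot", result)
}

#' @export
form_biplot.gmd <- function(X, result, dims = NULL) {
  if (is.null(dims)) dims <- c(1L, 2L)
  .check_dims(dims, result$q)
  x <- .values(X)
  if (ncol(x) != nrow(result$V)) {
    stop("'X' has ", ncol(x), " variables but the fit has ", nrow(result$V))
  }
  v2 <- result$V[, dims, drop = FALSE]
  points <- x %*% v2
  colnames(points) <- colnames(v2) <- paste0("dim", dims)
  prop <- if (result$total_variance > 0) {
    variance_explained(result)[dims]
  } else {
    c(NA_real_, NA_real_)
  }
  .new_layout(points, v2, dims, prop, "form", "gmd")
}

#' @export
form_biplot.amd <- function(X, result, dims = NULL) {
  if (is.null(dims)) dims <- result$selected
  .check_dims(dims, result$rank)
  points <- result$U_H[, dims, drop = FALSE] %*% diag(result$D[dims])
  arrows <- result$V[, dims, drop = FALSE]
  colnames(points) <- colnames(arrows) <- paste0("dim", dims)
  rownames(points) <- result$sample_ids
  tot <- sum(result$D^2)
  prop <- if (tot > 0) result$D[dims]^2 / tot else c(NA_real_, NA_real_)
  .new_layout(points, arrows, dims, prop, "form", "amd")
}

.check_dims <- function(dims, q) {
  if (length(dims) != 2 || any(dims < 1) || any(dims > q) ||
      dims[1] == dims[2]) {
    stop("'dims' must be two distinct component indices in 1..", q)
  }
  invisible(TRUE)
}

#' Project a new sample onto an existing biplot coordinate system
#'
#' A future sample `x*` (preprocessed exactly like the training rows: same
#' transform, same column centers) is displayed at `(x*' v_a, x*' v_b)`.
#'
#' @param x_new numeric vector of length p.
#' @param result a `gmd` object.
#' @param dims pair of component indices (default `c(1, 2)`).
#' @return Length-2 numeric point.
#' @export
project_sample <- function(x_new, result, dims = c(1L, 2L)) {
  stopifnot(inherits(result, "gmd"))
  .check_dims(dims, result$q)
  x_new <- as.numeric(x_new)
  if (length(x_new) != nrow(result$V)) {
    stop("'x_new' has length ", length(x_new), " but the fit has ",
         nrow(result$V), " variables")
  }
  drop(crossprod(x_new, result$V[, dims, drop = FALSE]))
}

#' Covariance-biplot arrow lengths and per-variable variance shares
#'
#' In the covariance biplot (GMD of X with respect to H only, i.e.
#' `R = I` so `V'V = I`), the arrow for variable `j` has length
#' `sqrt(sum_m v_jm^2 s_m^2)` and the squared lengths partition the total
#' variance: `sum_j sum_m v_jm^2 s_m^2 = sum_m s_m^2`.
#'
#' @param result a `gmd` object fitted with `R = NULL` (identity).
#' @return List with `arrow_lengths` (length p) and `prop_by_variable`
#'   (each variable's share of `tr(X X' H)`; sums to 1 at full rank).
#' @export
covariance_arrows <- function(result) {
  stopifnot(inherits(result, "gmd"))
  if (!isTRUE(result$identity_R)) {
    stop("covariance arrows require a fit with R = identity (V'V = I)")
  }
  mass <- drop(result$V^2 %*% result$S^2)   # sum_m v_jm^2 s_m^2
  names(mass) <- result$variable_ids
  list(arrow_lengths = sqrt(mass),
       prop_by_variable = mass / result$total_variance)
}

#' Scree table of component contributions
#'
#' For a GMD fit, component `k` contributes `S_k^2 / tr(X R X' H)` and the
#' proportions are nonincreasing. For an AMD fit, contributions
#' `d_k^2 / sum(d^2)` are listed in eigenvector order of H and may be
#' non-monotone — the signature AMD pathology.
#'
#' @param result a `gmd` or `amd` object.
#' @param top number of leading components to tabulate (default 10).
#' @return `data.frame` with columns `component`, `value`, `proportion`.
#' @export
scree <- function(result, top = 10L) UseMethod("scree")

#' @export
scree.gmd <- function(result, top = 10L) {
  stopifnot(top >= 1)
  k <- min(top, result$q)
  data.frame(component = seq_len(k), value = result$S[seq_len(k)],
             proportion = result$S[seq_len(k)]^2 / result$total_variance)
}

#' @export
scree.amd <- function(result, top = 10L) {
  stopifnot(top >= 1)
  k <- min(top, result$rank)
  tot <- sum(result$D^2)
  data.frame(component = seq_len(k), value = result$D[seq_len(k)],
             proportion = result$D[seq_len(k)]^2 / tot)
}

#' Variables with the longest arrows
#'
#' @param layout a `biplot_layout`.
#' @param m number of variables to return, `1 <= m <= p`.
#' @return Character vector of `m` variable IDs sorted by decreasing arrow
#'   length, ties broken by lexicographic ID order.
#' @export
top_arrows <- function(layout, m) {
  stopifnot(inherits(layout, "biplot_layout"))
  ids <- rownames(layout$arrows)
  p <- length(ids)
  if (m < 1 || m > p) stop("'m' must be in 1..", p)
  ord <- order(-layout$arrow_lengths, ids)
  ids[ord][seq_len(m)]
}

#' Plot a biplot layout
#'
#' Base-graphics rendering: sample points, arrows for the `n_arrows`
#' longest variables, axis labels carrying the proportion of variance.
#' Arrows can be magnified for display (`arrow_scale`) without touching
#' the stored coordinates.
#'
#' @param x a `biplot_layout`.
#' @param n_arrows number of longest arrows to draw (default all, capped
#'   at 10).
#' @param arrow_scale display magnification applied to arrows only.
#' @param col point colors; `...` passed to [graphics::plot()].
#' @importFrom graphics arrows text
#' @export
plot.biplot_layout <- function(x, n_arrows = min(10L, nrow(x$arrows)),
                               arrow_scale = 1, col = 1, ...) {
  lab <- sprintf("component %d (%s)", x$component_indices,
                 ifelse(is.na(x$prop_variance), "NA",
                        sprintf("%.1f%%", 100 * x$prop_variance)))
  a <- x$arrows * arrow_scale
  rng <- function(i) range(c(x$sample_points[, i], a[, i], 0))
  plot(x$sample_points, xlab = lab[1], ylab = lab[2], col = col,
       xlim = rng(1), ylim = rng(2), ...)
  keep <- rownames(x$arrows) %in% top_arrows(x, n_arrows)
  if (any(keep)) {
    arrows(0, 0, a[keep, 1], a[keep, 2], length = 0.08, col = "grey40")
    text(a[keep, 1], a[keep, 2], rownames(a)[keep], cex = 0.7, pos = 3)
  }
  invisible(x)
}

#' @export
print.biplot_layout <- function(x, ...) {
  cat(x$source, x$style, "biplot: components", x$component_indices[1], "and",
      x$component_indices[2], "\n")
  cat(nrow(x$sample_points), "samples,", nrow(x$arrows), "arrows;",
      "variance explained:",
      paste(sprintf("%.3f", x$prop_variance), collapse = ", "), "\n")
  invisible(x)
}
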