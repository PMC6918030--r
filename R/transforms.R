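#' Centered log-ratio transform of a count table
#'
#' Maps each sample's composition to log(x_ij / g(x_i)), where g is the
#' geometric mean of the (pseudocount-shifted) row. The CLR places
#' compositions in an unconstrained space where Euclidean geometry is
#' meaningful; every output row sums to zero.
#'
#' The pseudocount is added to every cell (not only zeros) so that the
#' shift is scale-consistent across samples. Natural logarithms are used;
#' any other base rescales all entries uniformly and changes no downstream
#' ordination.
#'
#' @param counts a [count_table()].
#' @param pseudocount nonnegative value added to every cell before taking
#'   logs; must be positive when any count is zero. Default 0.5.
#' @return A [data_matrix()] with `transform = "clr"`, `centering = "none"`.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  stopifnot(inherits(counts, "count_table"))
  if (length(pseudocount) != 1 || !is.finite(pseudocount) || pseudocount < 0) {
    stop("'pseudocount' must be a single nonnegative number")
  }
  x <- counts$values
  if (pseudocount == 0 && any(x == 0)) {
    bad <- which(x == 0, arr.ind = TRUE)[1, ]
    stop("zero count at sample '", counts$sample_ids[bad[1]],
         "', variable '", counts$variable_ids[bad[2]],
         "' requires a positive pseudocount")
  }
  x <- x + pseudocount
  logx <- log(x)
  clr <- logx - rowMeans(logx)  # subtracting log g(x_i) row-wise
  data_matrix(clr, counts$sample_ids, counts$variable_ids,
              transform = "clr", centering = "none")
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each row by its total so rows sum to one (the empirical
#' frequencies of each taxon within a sample).
#'
#' @param counts a [count_table()]; every row must have a positive total.
#' @return A [data_matrix()] with `transform = "relative_abundance"`.
#' @export
relative_abundance <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  totals <- rowSums(counts$values)
  if (any(totals <= 0)) {
    stop("sample '", counts$sample_ids[which(totals <= 0)[1]],
         "' has zero total count; relative abundances are undefined")
  }
  data_matrix(counts$values / totals, counts$sample_ids,
              counts$variable_ids, transform = "relative_abundance",
              centering = "none")
}

#' Center a data matrix by columns or doubly
#'
#' Column centering subtracts each column mean (the preprocessing required
#' before a Euclidean Gram kernel or an SVD/GMD fit). Double centering
#' subtracts row means and column means and adds back the grand mean, so
#' every row and column mean is zero; it is idempotent.
#'
#' @param data a [data_matrix()], [count_table()] or bare matrix.
#' @param mode `"columns"` or `"double"`.
#' @return A [data_matrix()] with `centering` updated.
#' @export
center_data <- function(data, mode = c("columns", "double")) {
  mode <- match.arg(mode)
  x <- .values(data)
  transform <- if (inherits(data, "data_matrix")) data$transform else "raw"
  if (mode == "columns") {
    out <- sweep(x, 2, colMeans(x))
  } else {
    out <- x - rowMeans(x)
    out <- sweep(out, 2, colMeans(out))
  }
  data_matrix(out, rownames(x), colnames(x),
              transform = transform, centering = mode)
}
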