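#' Construct a squared-dissimilarity matrix
#'
#' Validated container for a square symmetric matrix of (squared)
#' dissimilarities between samples or between variables. Distances that are
#' not yet squared are squared on construction, since the Gower-centering
#' map consumes squared dissimilarities.
#'
#' @param values square numeric matrix with zero diagonal and nonnegative
#'   entries. Asymmetry up to `1e-8` (relative to the largest entry) is
#'   symmetrized by averaging with the transpose; beyond that, an error.
#' @param ids identifiers for rows/columns (default: dimnames).
#' @param squared logical; `TRUE` if `values` already holds squared
#'   dissimilarities. If `FALSE` (default) entries are squared internally.
#' @return An object of class `distance_matrix` whose `values` are always
#'   squared dissimilarities (`squared = TRUE`).
#' @export
distance_matrix <- function(values, ids = rownames(values), squared = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) {
    stop("dissimilarity matrix must be square")
  }
  if (any(!is.finite(values))) stop("non-finite dissimilarity entries")
  if (any(values < 0)) stop("negative dissimilarity entries")
  scale <- max(abs(values), 1e-300)
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8 * scale) {
    stop("dissimilarity matrix is asymmetric (max |d_ij - d_ji| = ",
         format(asym), ")")
  }
  values <- (values + t(values)) / 2
  if (any(abs(diag(values)) > 1e-10 * scale)) {
    stop("dissimilarity matrix has a nonzero diagonal")
  }
  diag(values) <- 0
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(values)))
  ids <- as.character(ids)
  .check_unique(ids, "ID")
  if (!squared) values <- values^2
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, squared = TRUE),
            class = "distance_matrix")
}

#' Construct a similarity kernel
#'
#' @param values symmetric matrix.
#' @param ids identifiers (default dimnames).
#' @param rank integer rank if known, else `NA`.
#' @param removed_negative_mass total absolute negative eigenvalue mass
#'   clipped by [psd_project()], 0 for kernels PSD by construction, `NA` if
#'   not yet assessed.
#' @return Object of class `similarity_kernel`.
#' @export
similarity_kernel <- function(values, ids = rownames(values),
                              rank = NA_integer_,
                              removed_negative_mass = NA_real_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) stop("kernel must be square")
  if (any(!is.finite(values))) stop("non-finite kernel entries")
  if (max(abs(values - t(values))) > 1e-8 * max(abs(values), 1e-300)) {
    stop("kernel is not symmetric")
  }
  values <- (values + t(values)) / 2
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(values)))
  ids <- as.character(ids)
  .check_unique(ids, "ID")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, rank = rank,
                 removed_negative_mass = removed_negative_mass),
            class = "similarity_kernel")
}

#' Gower-center squared dissimilarities into a similarity kernel
#'
#' Applies the map H = -(1/2) J D J with J = I - (1/n) 11', turning a
#' matrix D of squared dissimilarities into a centered inner-product-like
#' kernel. When D holds squared Euclidean distances of a column-centered X,
#' the result equals X X' exactly. For non-Euclidean dissimilarities the
#' output may have negative eigenvalues; follow with [psd_project()].
#'
#' @param dist a [distance_matrix()] (squared internally on construction).
#' @return A [similarity_kernel()] with row and column sums zero. `rank`
#'   and `removed_negative_mass` are left `NA` until [psd_project()].
#' @export
gower_kernel <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  d <- dist$values
  n <- nrow(d)
  # -1/2 J D J without forming J: double-center D, then halve and negate
  dc <- d - rowMeans(d)
  dc <- sweep(dc, 2, colMeans(dc))
  similarity_kernel(-dc / 2, dist$ids)
}

#' Project a symmetric kernel onto the positive semidefinite cone
#'
#' Eigendecomposes the kernel and reconstructs it from eigenpairs whose
#' eigenvalues exceed `tol` times the largest eigenvalue; negative
#' eigenvalues are dropped outright (not shifted). Gower kernels of
#' non-Euclidean dissimilarities such as UniFrac typically need this
#' repair before they can serve as the H of a GMD.
#'
#' @param kernel a [similarity_kernel()] or symmetric matrix.
#' @param tol relative eigenvalue cutoff (default `1e-10`).
#' @return A PSD [similarity_kernel()] with `rank` set to the number of
#'   retained eigenpairs and `removed_negative_mass` the summed absolute
#'   value of all clipped negative eigenvalues.
#' @export
psd_project <- function(kernel, tol = 1e-10) {
  k <- if (inherits(kernel, "similarity_kernel")) kernel else
    similarity_kernel(kernel)
  e <- eigen(k$values, symmetric = TRUE)
  lam_max <- max(e$values, 0)
  keep <- e$values > tol * lam_max
  removed <- sum(abs(e$values[e$values < 0]))
  vals <- if (any(keep)) {
    vk <- e$vectors[, keep, drop = FALSE]
    vk %*% (e$values[keep] * t(vk))
  } else {
    matrix(0, nrow(k$values), ncol(k$values))
  }
  similarity_kernel(vals, k$ids, rank = sum(keep),
                    removed_negative_mass = removed)
}

#' Euclidean Gram kernel X X'
#'
#' The similarity kernel of the classical SVD-biplot. Requires
#' column-centered data so that the kernel corresponds to Gower-centered
#' squared Euclidean distances.
#'
#' @param data a column-centered [data_matrix()] or matrix.
#' @return A PSD [similarity_kernel()] with `rank = rank(X)` and zero
#'   removed mass.
#' @export
euclidean_gram <- function(data) {
  x <- .values(data)
  cm <- colMeans(x)
  if (max(abs(cm)) > 1e-8 * max(abs(x), 1e-300)) {
    stop("data must be column-centered before forming X X'")
  }
  similarity_kernel(tcrossprod(x), rownames(x),
                    rank = qr(x)$rank, removed_negative_mass = 0)
}

#' Squared patristic distances between the tips of a phylogenetic tree
#'
#' The patristic distance between two tips is the sum of branch lengths on
#' the unique path connecting them; its square feeds the Gower map to
#' build a variable (taxon) kernel R.
#'
#' @param tree an `ape::phylo` object, a Newick string, or a path to a
#'   Newick file. Branch lengths are required; tip labels must be unique.
#' @param ids optional character vector giving the desired tip order of the
#'   output (e.g. a count table's variable order); must be a permutation of
#'   the tip labels. Default: tree traversal order.
#' @return A [distance_matrix()] of squared patristic distances.
#' @export
patristic_squared_distances <- function(tree, ids = NULL) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1 && file.exists(tree)) {
      ape::read.tree(tree)
    } else {
      ape::read.tree(text = tree)
    }
  }
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or Newick")
  if (is.null(tree$edge.length) || any(is.na(tree$edge.length))) {
    stop("tree is missing branch lengths")
  }
  .check_unique(tree$tip.label, "tip label")
  if (length(tree$tip.label) == 1) {
    d <- matrix(0, 1, 1)
    return(distance_matrix(d, ids = tree$tip.label, squared = TRUE))
  }
  pd <- ape::cophenetic.phylo(tree)
  if (!is.null(ids)) {
    if (!setequal(ids, tree$tip.label) || length(ids) != nrow(pd)) {
      stop("'ids' must be a permutation of the tree's tip labels")
    }
    pd <- pd[ids, ids, drop = FALSE]
  }
  distance_matrix(pd^2, ids = rownames(pd), squared = TRUE)
}

#' @export
print.similarity_kernel <- function(x, ...) {
  cat("similarity_kernel:", nrow(x$values), "x", ncol(x$values))
  if (!is.na(x$rank)) cat(", rank", x$rank)
  if (!is.na(x$removed_negative_mass)) {
    cat(", removed negative eigenvalue mass",
        format(x$removed_negative_mass, digits = 4))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (squared):", nrow(x$values), "x", ncol(x$values), "\n")
  invisible(x)
}
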