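# End-to-end pipeline: transform -> kernel(s) -> decomposition -> layout
# -> scree -> optional evaluation, with all outputs written as TSV and a
# run log recording the configuration and kernel diagnostics.

#' Pipeline run configuration
#'
#' @param method decomposition: `"gmd"`, `"amd"` or `"svd"`. `"svd"` is
#'   the GMD with identity kernels and needs no distance file.
#' @param transform preprocessing of the counts: `"clr"` (then column
#'   centering; the GMD/SVD default), `"relative_abundance"` (then double
#'   centering; the AMD convention), or `"none"` (column centering only).
#' @param pseudocount for the CLR (default 0.5).
#' @param distance_is_squared `TRUE` if the distance file already holds
#'   squared dissimilarities.
#' @param use_variable_kernel build a taxon kernel R from a phylogenetic
#'   tree (GMD only).
#' @param q number of components to extract (default 5).
#' @param dims components to display; `NULL` means `(1, 2)` for GMD/SVD
#'   and the two largest AMD values for AMD.
#' @param seed integer seed echoed into the log (the pipeline itself is
#'   deterministic).
#' @param psd_tol relative eigenvalue cutoff for the PSD repair.
#' @return Object of class `run_config`.
#' @export
run_config <- function(method = c("gmd", "amd", "svd"),
                       transform = c("clr", "relative_abundance", "none"),
                       pseudocount = 0.5, distance_is_squared = FALSE,
                       use_variable_kernel = FALSE, q = 5L, dims = NULL,
                       seed = 1L, psd_tol = 1e-10) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (pseudocount < 0) stop("'pseudocount' must be nonnegative")
  if (!is.null(dims)) {
    if (length(dims) != 2 || any(dims < 1)) stop("'dims' must be two indices")
    if (method != "amd" && any(dims > q)) {
      stop("'dims' must lie within 1..q")
    }
  }
  structure(list(method = method, transform = transform,
                 pseudocount = pseudocount,
                 distance_is_squared = distance_is_squared,
                 use_variable_kernel = use_variable_kernel,
                 q = as.integer(q), dims = dims, seed = as.integer(seed),
                 psd_tol = psd_tol),
            class = "run_config")
}

.preprocess <- function(counts, config) {
  switch(config$transform,
    clr = center_data(clr_transform(counts, config$pseudocount), "columns"),
    relative_abundance = center_data(relative_abundance(counts), "double"),
    none = center_data(counts, "columns")
  )
}

#' Run the full ordination pipeline
#'
#' Reads a count table (and, for GMD/AMD, a sample distance matrix;
#' optionally a Newick tree for a variable kernel), preprocesses, fits the
#' requested decomposition, and writes `samples.tsv`, `arrows.tsv`,
#' `scree.tsv` and `run_log.txt` under `out_dir`. If labels are supplied,
#' the leave-one-out logistic AUC of the displayed layout is computed and
#' logged.
#'
#' @param config a [run_config()].
#' @param counts path to the count table, or a [count_table()].
#' @param distance path to the sample distance matrix, or a
#'   [distance_matrix()]; required for methods `"gmd"` and `"amd"`.
#' @param tree optional Newick path/string/`phylo` for the variable
#'   kernel.
#' @param labels optional path to a label file, or [binary_labels()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the fit, layout, scree table, kernel
#'   diagnostics, optional `auc`, and the paths written.
#' @export
run_pipeline <- function(config, counts, distance = NULL, tree = NULL,
                         labels = NULL, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts <- if (inherits(counts, "count_table")) counts else
    read_count_table(counts)
  X <- .preprocess(counts, config)

  H <- NULL
  diagnostics <- list()
  if (config$method %in% c("gmd", "amd")) {
    if (is.null(distance)) {
      stop("configuration error: method '", config$method,
           "' requires a sample distance matrix ('distance')")
    }
    dist <- if (inherits(distance, "distance_matrix")) distance else
      read_distance_matrix(distance, squared = config$distance_is_squared)
    if (!setequal(dist$ids, counts$sample_ids)) {
      stop("distance matrix IDs do not match the count table's sample IDs")
    }
    H0 <- gower_kernel(dist)
    H <- psd_project(H0, tol = config$psd_tol)
    diagnostics$H_rank <- H$rank
    diagnostics$H_removed_negative_mass <- H$removed_negative_mass
  }

  R <- NULL
  if (config$use_variable_kernel) {
    if (config$method != "gmd") {
      stop("configuration error: a variable kernel requires method 'gmd'")
    }
    if (is.null(tree)) {
      stop("configuration error: 'use_variable_kernel' requires a tree")
    }
    dR <- patristic_squared_distances(tree, ids = counts$variable_ids)
    R <- psd_project(gower_kernel(dR), tol = config$psd_tol)
    diagnostics$R_rank <- R$rank
    diagnostics$R_removed_negative_mass <- R$removed_negative_mass
  }

  if (config$method == "amd") {
    fit <- amd(X, H, tol = config$psd_tol)
    layout <- form_biplot(X, fit, dims = config$dims)
    scree_df <- scree(fit, top = min(10L, fit$rank))
  } else {
    fit <- gmd(X, H, R, q = min(config$q, nrow(X$values), ncol(X$values)))
    dims <- if (is.null(config$dims)) c(1L, 2L) else as.integer(config$dims)
    layout <- form_biplot(X, fit, dims = dims)
    scree_df <- scree(fit, top = min(10L, fit$q))
  }

  paths <- write_layout(layout, file.path(out_dir, ""))
  scree_path <- file.path(out_dir, "scree.tsv")
  write_scree(scree_df, scree_path)

  auc <- NULL
  if (!is.null(labels)) {
    lab <- if (inherits(labels, "binary_labels")) labels else
      read_labels(labels)
    ord <- match(counts$sample_ids, lab$ids)
    if (any(is.na(ord))) stop("label file is missing some sample IDs")
    lab <- binary_labels(lab$values[ord], counts$sample_ids)
    auc <- loo_logistic_auc(layout$sample_points, lab)
  }

  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    "gmdbiplot pipeline run",
    sprintf("method=%s transform=%s pseudocount=%g q=%d seed=%d",
            config$method, config$transform, config$pseudocount,
            config$q, config$seed),
    sprintf("dims=%d,%d", layout$component_indices[1],
            layout$component_indices[2]),
    sprintf("samples=%d variables=%d", nrow(X$values), ncol(X$values)),
    if (length(diagnostics)) {
      paste0(names(diagnostics), "=",
             vapply(diagnostics, format, character(1)))
    },
    sprintf("prop_variance=%.6f,%.6f", layout$prop_variance[1],
            layout$prop_variance[2]),
    if (!is.null(auc)) sprintf("loo_logistic_auc=%.6f", auc)
  )
  writeLines(log_lines, log_path)

  invisible(list(fit = fit, layout = layout, scree = scree_df,
                 diagnostics = diagnostics, auc = auc,
                 paths = c(paths, scree_path, log_path)))
}
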