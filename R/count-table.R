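#' Construct a sample-by-taxon count table
#'
#' Thin validated container for a nonnegative abundance matrix with sample
#' rows and variable (taxon) columns. All downstream transforms and
#' decompositions consume either this class or [data_matrix()].
#'
#' @param values numeric matrix, samples in rows, variables in columns; all
#'   entries must be finite and nonnegative.
#' @param sample_ids,variable_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return An object of class `count_table` with elements `values`,
#'   `sample_ids`, `variable_ids`. `values` carries the IDs as dimnames.
#' @export
count_table <- function(values,
                        sample_ids = rownames(values),
                        variable_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(nrow(values)))
  }
  if (is.null(variable_ids)) {
    variable_ids <- paste0("var", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  variable_ids <- as.character(variable_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length of 'sample_ids' (", length(sample_ids),
         ") does not match number of rows (", nrow(values), ")")
  }
  if (length(variable_ids) != ncol(values)) {
    stop("length of 'variable_ids' (", length(variable_ids),
         ") does not match number of columns (", ncol(values), ")")
  }
  .check_unique(sample_ids, "sample ID")
  .check_unique(variable_ids, "variable ID")
  if (any(!is.finite(values))) {
    stop("count table contains non-finite values")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative count at sample '", sample_ids[bad[1]],
         "', variable '", variable_ids[bad[2]], "'")
  }
  dimnames(values) <- list(sample_ids, variable_ids)
  structure(
    list(values = values, sample_ids = sample_ids,
         variable_ids = variable_ids),
    class = "count_table"
  )
}

#' Construct a (possibly transformed) data matrix
#'
#' Container for the real-valued matrix consumed by the decompositions,
#' tagged with the transform and centering that produced it.
#'
#' @param values numeric matrix (samples x variables), all entries finite.
#' @param sample_ids,variable_ids unique identifiers (default: dimnames).
#' @param transform one of `"raw"`, `"clr"`, `"relative_abundance"`.
#' @param centering one of `"none"`, `"columns"`, `"double"`.
#' @return An object of class `data_matrix`.
#' @export
data_matrix <- function(values,
                        sample_ids = rownames(values),
                        variable_ids = colnames(values),
                        transform = c("raw", "clr", "relative_abundance"),
                        centering = c("none", "columns", "double")) {
  transform <- match.arg(transform)
  centering <- match.arg(centering)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(nrow(values)))
  }
  if (is.null(variable_ids)) {
    variable_ids <- paste0("var", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  variable_ids <- as.character(variable_ids)
  .check_unique(sample_ids, "sample ID")
  .check_unique(variable_ids, "variable ID")
  if (length(sample_ids) != nrow(values) ||
      length(variable_ids) != ncol(values)) {
    stop("ID lengths do not match matrix dimensions")
  }
  if (any(!is.finite(values))) {
    stop("data matrix contains non-finite values")
  }
  dimnames(values) <- list(sample_ids, variable_ids)
  structure(
    list(values = values, sample_ids = sample_ids,
         variable_ids = variable_ids, transform = transform,
         centering = centering),
    class = "data_matrix"
  )
}

.check_unique <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate ", what, ": '", dup[1], "'")
  }
  invisible(TRUE)
}

# Accept a data_matrix, count_table or bare matrix and return the numeric
# matrix; used at every module boundary.
.values <- function(x) {
  if (inherits(x, c("data_matrix", "count_table"))) x$values else as.matrix(x)
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$values), "samples x", ncol(x$values),
      "variables\n")
  invisible(x)
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("data_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "variables (transform = ", x$transform,
      ", centering = ", x$centering, ")\n", sep = "")
  invisible(x)
}
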