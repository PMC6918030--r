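# Readers and writers for the plain-text interchange formats: count
# tables (TSV/CSV, first column sample IDs), square distance matrices,
# two-column label files, and the layout/scree output tables.

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a count table from TSV/CSV
#'
#' Expected layout: header row of variable IDs, first column of sample
#' IDs, nonnegative numeric counts.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("count table needs an ID column and >= 1 variable")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count table")
  count_table(m, sample_ids = ids, variable_ids = colnames(df)[-1])
}

#' Write a count table
#'
#' @param counts a [count_table()].
#' @param path output path (separator chosen from the extension).
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  df <- data.frame(sample_id = counts$sample_ids, counts$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a square dissimilarity matrix
#'
#' Expected layout: square numeric matrix with a header of IDs and a
#' first column repeating the same IDs in the same order.
#'
#' @param path file path.
#' @param squared `TRUE` if the file already holds squared
#'   dissimilarities; if `FALSE` (default) entries are squared on read.
#' @return A [distance_matrix()].
#' @export
read_distance_matrix <- function(path, squared = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(ids, colnames(m))) {
    stop("row IDs and column IDs of the distance matrix do not match")
  }
  distance_matrix(m, ids = ids, squared = squared)
}

#' Write a distance matrix
#' @param dist a [distance_matrix()] (values written as stored: squared).
#' @param path output path.
#' @export
write_distance_matrix <- function(dist, path) {
  stopifnot(inherits(dist, "distance_matrix"))
  df <- data.frame(id = dist$ids, dist$values, check.names = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read binary sample labels
#'
#' Two-column TSV/CSV: sample ID, label in {0, 1}. A header row is
#' optional and detected from the second field.
#'
#' @param path file path.
#' @return A [binary_labels()].
#' @export
read_labels <- function(path) {
  first <- utils::read.table(path, header = FALSE, sep = .sep_for(path),
                             nrows = 1, stringsAsFactors = FALSE)
  header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  df <- utils::read.table(path, header = header, sep = .sep_for(path),
                          stringsAsFactors = FALSE)
  binary_labels(df[[2]], ids = as.character(df[[1]]))
}

#' Write biplot layout tables
#'
#' Serializes a layout as two TSVs: `<prefix>samples.tsv` (sample_id,
#' dim_a, dim_b) and `<prefix>arrows.tsv` (variable_id, dim_a, dim_b,
#' length), so any plot built from them is reproducible.
#'
#' @param layout a `biplot_layout`.
#' @param prefix path prefix for the two output files.
#' @return Character vector of the paths written.
#' @export
write_layout <- function(layout, prefix) {
  stopifnot(inherits(layout, "biplot_layout"))
  dims <- layout$component_indices
  samples <- data.frame(sample_id = rownames(layout$sample_points),
                        a = layout$sample_points[, 1],
                        b = layout$sample_points[, 2])
  arrows <- data.frame(variable_id = rownames(layout$arrows),
                       a = layout$arrows[, 1], b = layout$arrows[, 2],
                       length = layout$arrow_lengths)
  names(samples)[2:3] <- names(arrows)[2:3] <- paste0("dim", dims)
  paths <- paste0(prefix, c("samples.tsv", "arrows.tsv"))
  utils::write.table(samples, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(arrows, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write a scree table
#' @param scree_df output of [scree()].
#' @param path output path.
#' @export
write_scree <- function(scree_df, path) {
  utils::write.table(scree_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
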