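#' Write / read a count table as TSV
#'
#' Rows are samples, columns are features; the first column holds the
#' sample identifier.
#'
#' @param table samples x features count matrix.
#' @param path output file.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @return `read_count_table()` returns an integer matrix with sample row
#'   names and feature column names.
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read sample metadata as TSV
#' @param metadata data.frame with columns `sample_id`, `soil`,
#'   `treatment`, `day`, `replicate`.
#' @param path file path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write / read a labelled square distance matrix as TSV
#' @param D symmetric matrix with sample names.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write an embedding as TSV
#'
#' One row per sample: `sample_id` followed by `Axis1..Axisd`; the method
#' and dimensionality are recorded in a comment-free header via column
#' naming and returned invisibly.
#'
#' @param E an `"embedding"`.
#' @param path file path.
#' @export
write_embedding <- function(E, path) {
  stopifnot(inherits(E, "embedding"))
  pts <- E$points
  colnames(pts) <- paste0(E$method, "_Axis", seq_len(ncol(pts)))
  df <- data.frame(sample_id = rownames(pts), pts, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return an `ape` `"phylo"` object.
#' @export
read_tree_newick <- function(path) ape::read.tree(path)

#' Write a tree as Newick
#' @param tree a `"phylo"` object.
#' @param path file path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
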