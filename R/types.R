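#' Gene expression table
#'
#' Container for a genes x samples expression matrix, the working format for
#' scRNA-seq data throughout the package. Values must be finite and
#' nonnegative; gene identifiers must be unique.
#'
#' @param values numeric matrix, genes in rows, samples (cells) in columns.
#' @param gene_ids character vector of gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of sample identifiers (defaults to
#'   `colnames(values)`).
#'
#' @return An object of class `gene_expression_table`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`.
#' @export
gene_expression_table <- function(values,
                                  gene_ids = rownames(values),
                                  sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0 || ncol(values) == 0) {
    stop("expression table is empty")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers; collapse duplicates before construction")
  }
  if (any(!is.finite(values))) {
    stop("expression values must be finite")
  }
  if (any(values < 0)) {
    stop("expression values must be nonnegative")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "gene_expression_table")
}

#' @export
print.gene_expression_table <- function(x, ...) {
  cat("gene_expression_table:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' @export
dim.gene_expression_table <- function(x) dim(x$values)

#' Spatial reference atlas
#'
#' Container for a spatial reference atlas: expression of G genes at P
#' positions with known 2-D or 3-D coordinates. Expression values must lie in
#' [0,1]; a binary atlas additionally has values in {0,1}.
#'
#' @param expression numeric matrix, positions in rows, genes in columns,
#'   values in [0,1].
#' @param coordinates numeric matrix of position coordinates, P rows and 2 or
#'   3 columns.
#' @param gene_ids character vector of gene identifiers.
#' @param position_ids character vector of position identifiers.
#' @param is_binary logical; if `NULL` (default) detected from the values.
#'
#' @return An object of class `spatial_atlas`.
#' @export
spatial_atlas <- function(expression, coordinates,
                          gene_ids = colnames(expression),
                          position_ids = rownames(expression),
                          is_binary = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (nrow(expression) < 2) {
    stop("a spatial atlas needs at least 2 positions")
  }
  if (is.null(gene_ids)) {
    gene_ids <- paste0("gene_", seq_len(ncol(expression)))
  }
  if (is.null(position_ids)) {
    position_ids <- paste0("pos_", seq_len(nrow(expression)))
  }
  gene_ids <- as.character(gene_ids)
  position_ids <- as.character(position_ids)
  if (length(gene_ids) != ncol(expression)) {
    stop("gene identifier count does not match expression columns")
  }
  if (length(position_ids) != nrow(expression)) {
    stop("position identifier count does not match expression rows")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers in atlas")
  }
  if (any(!is.finite(expression))) {
    stop("atlas expression must be finite")
  }
  if (any(expression < 0) || any(expression > 1)) {
    stop("atlas expression values must lie in [0,1]; ",
         "rescale explicitly (e.g. with normalize_cells) before construction")
  }
  if (nrow(coordinates) != nrow(expression)) {
    stop("coordinate rows do not match atlas positions")
  }
  if (!ncol(coordinates) %in% c(2L, 3L)) {
    stop("coordinates must be 2-D or 3-D")
  }
  if (any(!is.finite(coordinates))) {
    stop("coordinates must be finite")
  }
  if (is.null(is_binary)) {
    is_binary <- all(expression %in% c(0, 1))
  }
  if (is_binary && !all(expression %in% c(0, 1))) {
    stop("atlas flagged binary but contains non-binary values")
  }
  dimnames(expression) <- list(position_ids, gene_ids)
  rownames(coordinates) <- position_ids
  colnames(coordinates) <- c("x", "y", "z")[seq_len(ncol(coordinates))]
  structure(list(expression = expression, coordinates = coordinates,
                 gene_ids = gene_ids, position_ids = position_ids,
                 is_binary = is_binary),
            class = "spatial_atlas")
}

#' @export
print.spatial_atlas <- function(x, ...) {
  cat("spatial_atlas:", nrow(x$expression), "positions x",
      ncol(x$expression), "genes (",
      if (x$is_binary) "binary" else "continuous", ",",
      ncol(x$coordinates), "D coordinates )\n")
  invisible(x)
}

#' @export
dim.spatial_atlas <- function(x) dim(x$expression)
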