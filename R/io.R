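# Readers and writers for the delimited-text interchange formats.
#
# Dense tables are TSV with genes as rows: first column gene identifiers,
# header row of sample identifiers. Sparse input is a matrix-market triplet
# file plus two one-column identifier files. Coordinate tables are TSV with a
# position identifier column followed by x, y (and optionally z). Lines
# starting with '#' are treated as comments in all formats.

#' Read a gene expression table
#'
#' Reads a genes x samples expression matrix from either a dense delimited
#' file or a matrix-market triplet file with separate identifier lists.
#' Duplicate gene rows are collapsed by summing, with a warning.
#'
#' @param path path to the expression file.
#' @param format `"dense"` (delimited text, genes as rows) or `"mtx"`
#'   (matrix-market triplets).
#' @param gene_path,sample_path for `format = "mtx"`: one-column text files
#'   listing gene and sample identifiers in matrix order.
#' @param sep field separator for dense files (default tab).
#'
#' @return A [gene_expression_table].
#' @export
read_expression_table <- function(path, format = c("dense", "mtx"),
                                  gene_path = NULL, sample_path = NULL,
                                  sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "dense") {
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("cannot parse '", path, "' as a dense table: ",
                               conditionMessage(e)))
    if (nrow(df) == 0 || ncol(df) < 2) {
      stop("expression table in '", path, "' is empty")
    }
    gene_ids <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    sample_ids <- colnames(df)[-1]
  } else {
    if (is.null(gene_path) || is.null(sample_path)) {
      stop("matrix-market input needs gene_path and sample_path")
    }
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("cannot parse '", path,
                                           "' as matrix-market: ",
                                           conditionMessage(e)))
    values <- as.matrix(m)
    gene_ids <- readLines(gene_path)
    gene_ids <- gene_ids[nzchar(gene_ids)]
    sample_ids <- readLines(sample_path)
    sample_ids <- sample_ids[nzchar(sample_ids)]
    if (length(gene_ids) != nrow(values) ||
        length(sample_ids) != ncol(values)) {
      stop("identifier files do not match matrix dimensions")
    }
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    warning("collapsing ", length(dup),
            " duplicated gene identifier(s) by summation: ",
            paste(utils::head(dup, 5), collapse = ", "))
    collapsed <- rowsum(values, group = gene_ids, reorder = FALSE)
    gene_ids <- rownames(collapsed)
    values <- collapsed
  }
  gene_expression_table(values, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write a gene expression table as dense delimited text
#'
#' @param table a [gene_expression_table].
#' @param path output path.
#' @param sep field separator (default tab).
#' @param header_comment optional character vector of comment lines (written
#'   with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path, sep = "\t",
                                   header_comment = NULL) {
  stopifnot(inherits(table, "gene_expression_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  df <- data.frame(gene_id = table$gene_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", table$sample_ids)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spatial reference atlas
#'
#' Reads atlas expression (dense delimited, genes as rows, positions as
#' columns) and a coordinate table (position identifier, x, y, optionally z).
#' Position identifiers must agree between the two files; expression values
#' must already lie in [0,1] (normalization is explicit, never silent).
#'
#' @param expr_path path to the expression file.
#' @param coords_path path to the coordinate file.
#' @param sep field separator (default tab).
#'
#' @return A [spatial_atlas].
#' @export
read_atlas <- function(expr_path, coords_path, sep = "\t") {
  tab <- read_expression_table(expr_path, format = "dense", sep = sep)
  coords <- utils::read.table(coords_path, header = TRUE, sep = sep,
                              comment.char = "#", check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (ncol(coords) < 3) {
    stop("coordinate file must have a position id column plus x,y(,z)")
  }
  pos_ids <- as.character(coords[[1]])
  if (!setequal(pos_ids, tab$sample_ids) ||
      length(pos_ids) != length(tab$sample_ids)) {
    stop("position identifiers in '", coords_path,
         "' do not match the expression columns")
  }
  coords <- coords[match(tab$sample_ids, pos_ids), -1, drop = FALSE]
  expression <- t(tab$values)
  if (any(expression < 0) || any(expression > 1)) {
    stop("atlas expression values outside [0,1]; rescale explicitly ",
         "(e.g. with normalize_cells) before loading as an atlas")
  }
  spatial_atlas(expression, as.matrix(coords),
                gene_ids = tab$gene_ids, position_ids = tab$sample_ids)
}

#' Write a spatial atlas to delimited text
#'
#' @param atlas a [spatial_atlas].
#' @param expr_path,coords_path output paths for the expression (genes as
#'   rows) and coordinate tables.
#' @param sep field separator.
#' @param header_comment optional comment line(s) for both files.
#' @return invisible list of the two paths.
#' @export
write_atlas <- function(atlas, expr_path, coords_path, sep = "\t",
                        header_comment = NULL) {
  stopifnot(inherits(atlas, "spatial_atlas"))
  tab <- gene_expression_table(t(atlas$expression),
                               gene_ids = atlas$gene_ids,
                               sample_ids = atlas$position_ids)
  write_expression_table(tab, expr_path, sep = sep,
                         header_comment = header_comment)
  con <- file(coords_path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  df <- data.frame(position_id = atlas$position_ids, atlas$coordinates,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(list(expression = expr_path, coordinates = coords_path))
}
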