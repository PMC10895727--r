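# Readers and writers for the containers the tool exchanges:
# - Matrix Market triplet (.mtx) + gene/barcode TSVs (genes x cells on disk,
#   the 10x convention; transposed to cells x genes in memory),
# - delimited text matrix (CSV/TSV, cells x genes, header row of gene ids,
#   first column cell ids),
# - labels as a single-column (or named-column) TSV,
# - priorities as `gene_id<TAB>score`, complexes as one complex per line,
# - panel TSV and JSON reports.

#' Read an expression matrix
#'
#' Dispatches on the file extension: \code{.mtx} (Matrix Market, genes x
#' cells on disk, with companion gene/barcode tables) or \code{.csv} /
#' \code{.tsv} / \code{.txt} (cells x genes, header of gene ids, first
#' column cell ids).
#'
#' @param path Matrix file.
#' @param genes,barcodes For \code{.mtx}: paths to the gene and barcode
#'   tables (defaults: \code{genes.tsv} / \code{barcodes.tsv} next to the
#'   matrix).
#' @return Dense numeric matrix, cells x genes, with dimnames.
#' @export
read_expression <- function(path, genes = NULL, barcodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    if (is.null(genes)) genes <- file.path(dir, "genes.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    g <- utils::read.delim(genes, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    b <- utils::read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(g) || ncol(m) != length(b))
      stop("matrix dimensions do not match gene/barcode tables")
    out <- t(as.matrix(m))
    dimnames(out) <- list(b, g)
    out
  } else if (ext %in% c("csv", "tsv", "txt")) {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    as.matrix(df)
  } else stop("unsupported matrix format: .", ext)
}

#' Write an expression matrix
#'
#' \code{.mtx} output is genes x cells with companion \code{genes.tsv} and
#' \code{barcodes.tsv}; delimited output is cells x genes.
#'
#' @param mat Cells x genes matrix with dimnames.
#' @param path Output file (\code{.mtx}, \code{.csv} or \code{.tsv}).
#' @export
write_expression <- function(mat, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(mat), sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(colnames(mat), file.path(dir, "genes.tsv"))
    writeLines(rownames(mat), file.path(dir, "barcodes.tsv"))
  } else if (ext %in% c("csv", "tsv")) {
    sep <- if (ext == "csv") "," else "\t"
    utils::write.table(mat, path, sep = sep, quote = FALSE, col.names = NA)
  } else stop("unsupported matrix format: .", ext)
  invisible(path)
}

#' Read per-cell labels
#'
#' @param path TSV/CSV file with a header.
#' @param column Column name holding the labels; default: the last column.
#' @return Character vector of labels.
#' @export
read_labels <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(column)) column <- names(df)[ncol(df)]
  if (!column %in% names(df)) stop("no column '", column, "' in ", path)
  as.character(df[[column]])
}

#' Write per-cell labels
#' @param labels Character vector.
#' @param path Output TSV.
#' @param cell_ids Optional cell identifiers (first column).
#' @export
write_labels <- function(labels, path, cell_ids = NULL) {
  df <- if (is.null(cell_ids)) data.frame(label = labels)
        else data.frame(cell_id = cell_ids, label = labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene priorities (`gene_id<TAB>score`)
#' @param path Two-column TSV, no header required.
#' @return Named numeric vector.
#' @export
read_priorities <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("priorities file needs two columns: gene_id, score")
  setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Read complexes (one complex per line, tab-separated gene ids)
#' @param path Text file.
#' @return List of character vectors.
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(strsplit(lines, "\t", fixed = TRUE), trimws)
}

#' Write a gene panel to TSV
#' @param panel A \code{gene_panel}.
#' @param path Output TSV with columns rank, gene_id, weight, prioritized,
#'   complex_id.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel TSV
#' @param path Panel file written by \code{\link{write_panel}}.
#' @return A \code{gene_panel} data frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("gene_panel", "data.frame"))
}
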