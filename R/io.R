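#' Read a dense expression matrix from TSV/CSV
#'
#' Reads a delimited text matrix with a header row of column ids and a first
#' column of gene ids, and returns it in the package's internal genes x
#' columns orientation. Numbers are parsed locale-independently (dot
#' decimal). The delimiter is inferred from the file extension (.csv =>
#' comma, otherwise tab) unless given.
#'
#' @param path file path.
#' @param orientation \code{"genes_by_columns"} (rows are genes, default) or
#'   \code{"columns_by_genes"} (rows are samples/cells; transposed on read).
#' @param unitTag unit tag to attach (default "counts").
#' @param sep field separator; inferred from the extension when NULL.
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
readDenseMatrix <- function(path, orientation = c("genes_by_columns", "columns_by_genes"),
                            unitTag = "counts", sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stopf("duplicate row ids in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn))
    stopf("duplicate column ids in %s: %s", path,
          paste(unique(cn[duplicated(cn)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stopf("non-numeric value '%s' at row '%s', column '%s' in %s",
          raw[bad[1], bad[2]], ids[bad[1]], cn[bad[2]], path)
  }
  dimnames(num) <- list(ids, cn)
  if (orientation == "columns_by_genes") num <- t(num)
  ExpressionMatrix(num, unitTag = unitTag)
}

#' Write an ExpressionMatrix as dense TSV
#'
#' Full double precision; round-trips through \code{\link{readDenseMatrix}}
#' to within 1e-12.
#'
#' @param mat an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @param idColumn name of the first (gene id) column.
#' @return invisibly, \code{path}.
#' @export
writeDenseMatrix <- function(mat, path, idColumn = "gene_id") {
  v <- asDense(mat@values)
  df <- data.frame(rownames(v), format(v, digits = 17, scientific = TRUE,
                                       trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 10x-style MatrixMarket triplet
#'
#' Reads a MatrixMarket coordinate file plus plain-text features and barcodes
#' files into a sparse genes x cells \linkS4class{ExpressionMatrix}. The
#' 1-based MTX coordinates are those of the format; internally all indexing
#' is 0-based half-open via R's own conventions.
#'
#' @param matrixPath path to the .mtx file.
#' @param featuresPath one feature (gene) id per line; if tab-delimited, the
#'   first field is used.
#' @param barcodesPath one cell barcode per line.
#' @param unitTag unit tag (default "counts").
#' @return an \linkS4class{ExpressionMatrix} backed by a sparse Matrix.
#' @export
readMtxTriplet <- function(matrixPath, featuresPath, barcodesPath,
                           unitTag = "counts") {
  m <- Matrix::readMM(matrixPath)
  feats <- read.delim(featuresPath, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  bcs <- read.delim(barcodesPath, header = FALSE,
                    stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(feats))
    stopf("MTX header says %d genes but features file has %d lines",
          nrow(m), length(feats))
  if (ncol(m) != length(bcs))
    stopf("MTX header says %d cells but barcodes file has %d lines",
          ncol(m), length(bcs))
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(feats, bcs)
  ExpressionMatrix(m, unitTag = unitTag)
}

#' Write an MTX triplet
#'
#' @param mat an \linkS4class{ExpressionMatrix}.
#' @param dir output directory (created if missing); writes matrix.mtx,
#'   features.tsv, barcodes.tsv.
#' @return invisibly, \code{dir}.
#' @export
writeMtxTriplet <- function(mat, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(mat@values, "sparseMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat@values), file.path(dir, "features.tsv"))
  writeLines(colnames(mat@values), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a CompositionMatrix as TSV
#'
#' Sample rows, cell-type columns, full double precision; round-trips
#' through \code{\link{readComposition}} to within 1e-12.
#'
#' @param comp a \linkS4class{CompositionMatrix}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeComposition <- function(comp, path) {
  v <- comp@values
  header <- c("sample_id", colnames(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(v) > 0) {
    body <- apply(format(v, digits = 17, scientific = TRUE, trim = TRUE), 1,
                  paste, collapse = "\t")
    writeLines(paste(rownames(v), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a CompositionMatrix from TSV
#'
#' @param path file written by \code{\link{writeComposition}} (or any TSV
#'   with a sample_id first column and cell-type columns).
#' @param kind \code{"estimate"} or \code{"gold_standard"}.
#' @return a \linkS4class{CompositionMatrix}.
#' @export
readComposition <- function(path, kind = "estimate") {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df[[1]]
  if (nrow(v) == 0) {
    cn <- colnames(df)[-1]
    v <- matrix(numeric(0), 0, length(cn), dimnames = list(NULL, cn))
  }
  CompositionMatrix(v, kind = kind)
}

#' Write a CellLabelTable as TSV
#'
#' @param labels a \linkS4class{CellLabelTable}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeCellLabels <- function(labels, path) {
  write.table(as.data.frame(labels), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a CellLabelTable from TSV
#'
#' Expects columns cell_id, sample_id, cluster_id and optionally
#' mito_fraction, ribo_fraction.
#'
#' @param path file path.
#' @return a \linkS4class{CellLabelTable}.
#' @export
readCellLabels <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id", "cluster_id")
  if (!all(need %in% colnames(df)))
    stopf("label table %s must have columns %s", path, paste(need, collapse = ", "))
  CellLabelTable(df$cell_id, df$sample_id, df$cluster_id,
    mitoFraction = if ("mito_fraction" %in% colnames(df)) df$mito_fraction else rep(NA_real_, nrow(df)),
    riboFraction = if ("ribo_fraction" %in% colnames(df)) df$ribo_fraction else rep(NA_real_, nrow(df)))
}
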