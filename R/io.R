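#' Read a GMT gene-set file
#'
#' GMT is tab-separated: set name, description, then one gene id per field.
#' @param path file path.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": need name, description, >=1 gene")
    nm <- f[1]
    if (nm %in% names(sets))
      stop("GMT parse error at line ", i, ": duplicate set name '", nm, "'")
    sets[[nm]] <- unique(f[-(1:2)])
    desc[nm] <- f[2]
  }
  GeneSetCollection(sets, desc)
}

#' Write a GeneSetCollection as GMT
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @export
writeGMT <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  lines <- vapply(names(gsc@sets), function(nm) {
    paste(c(nm, gsc@description[[nm]], gsc@sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression TSV (genes in rows, first column gene id)
#'
#' @param path file path.
#' @param unit unit tag for the resulting [ExpressionMatrix-class].
#' @return An [ExpressionMatrix-class]; gene and column order preserved.
#' @export
readExpressionTSV <- function(path, unit = "log2TPM") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate gene id at line ", dup[1] + 1L, ": ", ids[dup[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stop("non-numeric expression column: ", names(df)[-1][bad])
  }
  rownames(m) <- ids
  ExpressionMatrix(m, unit)
}

#' Write an ExpressionMatrix as TSV (first column `gene_id`)
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @export
writeExpressionTSV <- function(x, path) {
  v <- exprValues(x)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket single-cell UMI matrix with features and barcodes
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` in `dir` (the 10x
#' plain-text layout). Cells with no nonzero entries are retained as zero
#' columns.
#'
#' @param dir directory with the three files.
#' @return A [Matrix::sparseMatrix] genes x cells with dimnames.
#' @export
readMTX <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  ok <- file.exists(paths)
  if (!all(ok)) stop("missing file(s): ", paste(paths[!ok], collapse = ", "))
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  feats <- readLines(paths[2])
  bcs <- readLines(paths[3])
  if (nrow(m) != length(feats))
    stop("feature count (", length(feats), ") does not match matrix rows (",
         nrow(m), ")")
  if (ncol(m) != length(bcs))
    stop("barcode count does not match matrix columns")
  feats <- vapply(strsplit(feats, "\t"), `[`, "", 1L)
  dimnames(m) <- list(feats, bcs)
  m
}

#' Write a sparse UMI matrix in MatrixMarket layout
#' @param m genes x cells matrix (dense or sparse) with dimnames.
#' @param dir output directory (created if needed).
#' @export
writeMTX <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

.clinical_required <- c("sample_id", "os_time", "os_event",
                        "vimentin_proportion", "vimentin_intensity",
                        paste0("cd8_f", 1:5))

#' Read a clinical table (CSV)
#'
#' Required columns: `sample_id`, `os_time`, `os_event`,
#' `vimentin_proportion`, `vimentin_intensity`, `cd8_f1`..`cd8_f5`.
#' Extra columns (e.g. `subtype`) are preserved.
#' @param path CSV path.
#' @return A data.frame.
#' @export
readClinicalCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.clinical_required, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  num <- setdiff(.clinical_required, "sample_id")
  for (cn in num)
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in clinical column ", cn)
  df
}

#' Write a clinical table (CSV)
#' @param df clinical data.frame.
#' @param path output path.
#' @export
writeClinicalCSV <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column ortholog map (TSV: human id, mouse id)
#' @param path TSV path, no header.
#' @return data.frame with columns `human`, `mouse`.
#' @export
readOrthologMap <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ortholog map needs two columns")
  stats::setNames(df[, 1:2], c("human", "mouse"))
}
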