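#' Construct a PeakCellMatrix
#'
#' @param counts non-negative numeric matrix, peaks as rows, cells as
#'   columns. A `Matrix` sparse matrix is densified.
#' @param peakNames,cellNames identifiers; taken from dimnames when missing.
#' @param cellTypes optional per-cell labels stored in `colData$cell_type`.
#' @return a [PeakCellMatrix].
#' @examples
#' m <- matrix(c(0, 2, 5, 0), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("c1", "c2")))
#' pcm <- PeakCellMatrix(m)
#' assay(binarize(pcm))
#' @export
PeakCellMatrix <- function(counts, peakNames = rownames(counts),
                           cellNames = colnames(counts), cellTypes = NULL) {
  counts <- as.matrix(counts)
  .assert(!is.null(peakNames) && !is.null(cellNames),
          "peak and cell identifiers are required")
  .assert(length(peakNames) == nrow(counts),
          "peak identifiers do not match the number of rows")
  .assert(length(cellNames) == ncol(counts),
          "cell identifiers do not match the number of columns")
  dimnames(counts) <- list(peakNames, cellNames)
  cd <- S4Vectors::DataFrame(row.names = cellNames)
  if (!is.null(cellTypes)) {
    .assert(length(cellTypes) == ncol(counts),
            "one cell type per cell required")
    cd$cell_type <- as.character(cellTypes)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("PeakCellMatrix", se)
}

#' @describeIn PeakCellMatrix cell-type labels (NULL when absent).
#' @param x a `PeakCellMatrix`.
#' @export
cellTypes <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("cell_type" %in% colnames(cd)) cd$cell_type else NULL
}

#' @rdname binarize
setMethod("binarize", "matrix", function(x, threshold = 0) {
  .assert(all(x >= 0), "negative entries cannot be binarized")
  out <- (x > threshold) * 1
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname binarize
setMethod("binarize", "PeakCellMatrix", function(x, threshold = 0) {
  b <- binarize(SummarizedExperiment::assay(x, "counts"), threshold)
  PeakCellMatrix(b, cellTypes = cellTypes(x))
})

#' Read a peak-by-cell matrix with identifier sidecars
#'
#' Loads a MatrixMarket (`.mtx`) matrix stored peaks x cells together with
#' `peaks.tsv` and `barcodes.tsv` sidecar files in the same directory. A
#' second column in `barcodes.tsv`, when present, is attached as the
#' `cell_type` label.
#'
#' @param path path to the `.mtx` file or to the directory holding
#'   `matrix.mtx`, `peaks.tsv` and `barcodes.tsv`.
#' @param format only `"mtx"` is supported; `"h5ad"` input must be converted
#'   to MTX + sidecars first (e.g. with anndata/scanpy).
#' @return a [PeakCellMatrix], peaks as rows, cells as columns.
#' @export
readPeakCellMatrix <- function(path, format = c("mtx", "h5ad")) {
  format <- match.arg(format)
  if (format == "h5ad")
    stop("format 'h5ad' is not supported; export the AnnData object to ",
         "MTX with peaks.tsv/barcodes.tsv sidecars and use format = 'mtx'",
         call. = FALSE)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    dirn <- path
  } else {
    mtx <- path
    dirn <- dirname(path)
  }
  .assert(file.exists(mtx), "matrix file not found: ", mtx)
  m <- as.matrix(Matrix::readMM(mtx))
  peaks <- read.table(file.path(dirn, "peaks.tsv"), sep = "\t",
                      header = FALSE, stringsAsFactors = FALSE)
  cells <- read.table(file.path(dirn, "barcodes.tsv"), sep = "\t",
                      header = FALSE, stringsAsFactors = FALSE)
  .assert(nrow(peaks) == nrow(m),
          "peak sidecar has ", nrow(peaks), " identifiers for ", nrow(m),
          " matrix rows")
  .assert(nrow(cells) == ncol(m),
          "barcode sidecar has ", nrow(cells), " identifiers for ", ncol(m),
          " matrix columns")
  types <- if (ncol(cells) >= 2) cells[[2]] else NULL
  PeakCellMatrix(m, peakNames = peaks[[1]], cellNames = cells[[1]],
                 cellTypes = types)
}

#' Write a peak-by-cell matrix as MTX with identifier sidecars
#'
#' Values are written at full double precision so a load/save/load round trip
#' preserves entries bit-exactly.
#'
#' @param x a [PeakCellMatrix].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `peaks.tsv` and `barcodes.tsv`.
#' @return invisibly, the paths written.
#' @export
writePeakCellMatrix <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(x, "counts")
  sp <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  mtx <- file.path(dir, "matrix.mtx")
  con <- file(mtx, "w")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               paste(nrow(m), ncol(m), length(sp@x))), con)
  ord <- order(sp@j, sp@i)
  writeLines(sprintf("%d %d %.17g", sp@i[ord] + 1L, sp@j[ord] + 1L,
                     sp@x[ord]), con)
  close(con)
  pk <- file.path(dir, "peaks.tsv")
  writeLines(rownames(x), pk)
  bc <- file.path(dir, "barcodes.tsv")
  ct <- cellTypes(x)
  if (is.null(ct)) writeLines(colnames(x), bc)
  else write.table(data.frame(colnames(x), ct), bc, sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(mtx, pk, bc))
}
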