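#' Write a simulated dataset as an MTX fixture
#'
#' Writes `matrix.mtx` (Matrix Market, 1-based on disk), `genes.tsv`,
#' `barcodes.tsv` and the ground-truth tables `truth_cells.csv` /
#' `truth_genes.csv` under `path`. Round-trips losslessly through
#' [read_counts()].
#'
#' @param counts sparse cells x genes count matrix.
#' @param truth truth list from [simulate_tissue()] (optional).
#' @param path output directory, created if missing.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(counts, truth = NULL, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts, file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(gene = colnames(counts)),
                     file.path(path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(barcode = rownames(counts)),
                     file.path(path, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(truth$cells, file.path(path, "truth_cells.csv"),
                     row.names = FALSE)
    gg <- truth$genes
    gg$param <- vapply(gg$param, function(p)
      if (is.null(p)) "" else paste(deparse(p, width.cutoff = 500),
                                    collapse = ""), character(1))
    utils::write.csv(gg, file.path(path, "truth_genes.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a count matrix from an MTX triplet or dense CSV
#'
#' @param path directory holding `matrix.mtx` + `genes.tsv` +
#'   `barcodes.tsv`, or a single dense CSV file (cells in rows, genes in
#'   columns, first column = cell ids).
#' @param raw if `TRUE`, non-integer values are rejected.
#' @return sparse cells x genes `dgCMatrix` with dimnames attached.
#' @export
read_counts <- function(path, raw = TRUE) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)[, 1]
    cells <- utils::read.table(file.path(path, "barcodes.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)[, 1]
    if (nrow(m) != length(cells))
      stopf("barcodes.tsv has %d rows but matrix has %d rows",
            length(cells), nrow(m))
    if (ncol(m) != length(genes))
      stopf("genes.tsv has %d rows but matrix has %d columns",
            length(genes), ncol(m))
    if (anyDuplicated(genes)) stopf("duplicate gene ids in genes.tsv")
    dimnames(m) <- list(cells, genes)
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- Matrix::Matrix(as.matrix(df), sparse = TRUE)
  }
  if (raw && any(m@x != round(m@x)))
    stopf("non-integer values in raw count matrix")
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}
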