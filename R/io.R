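#' @include AllClasses.R AllGenerics.R
NULL

## Expression I/O -----------------------------------------------------------

#' Load a time-stamped expression dataset
#'
#' Reads per-cell expression plus a timepoint stamp per cell and partitions
#' cells into per-timepoint blocks ordered by stamp. Three on-disk layouts
#' are supported:
#' \describe{
#'   \item{csv}{one row per cell: a `cell_id` column, the stamp column named
#'     by `timepointKey`, and one numeric column per gene.}
#'   \item{mtx}{a directory holding `matrix.mtx` (cells x genes,
#'     MatrixMarket), `genes.tsv` (one gene per line) and `cells.tsv`
#'     (TSV with header, columns `cell_id` and `timepointKey`).}
#'   \item{h5}{an HDF5 file with datasets `<layer>` (cells x genes),
#'     `gene_names`, `cell_ids` and `<timepointKey>`; requires the rhdf5
#'     package.}
#' }
#'
#' @param path file (csv, h5) or directory (mtx) path.
#' @param format one of `"csv"`, `"mtx"`, `"h5"`.
#' @param timepointKey name of the per-cell stamp column/dataset.
#' @param h5Layer dataset name of the expression layer for `format = "h5"`.
#' @return A \linkS4class{TimeStampedExpression}.
#' @seealso [writeExpression()] for the inverse operation.
#' @export
loadExpression <- function(path, format = c("csv", "mtx", "h5"),
                           timepointKey = "timepoint", h5Layer = "X") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parts <- switch(format,
    csv = .readExpressionCSV(path, timepointKey),
    mtx = .readExpressionMTX(path, timepointKey),
    h5  = .readExpressionH5(path, timepointKey, h5Layer))
  .partitionByStamp(parts$mat, parts$stamps)
}

.readExpressionCSV <- function(path, timepointKey) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df)) stop("csv needs a 'cell_id' column")
  if (!timepointKey %in% names(df))
    stop("csv has no timepoint column '", timepointKey, "'")
  stamps <- df[[timepointKey]]
  genes <- setdiff(names(df), c("cell_id", timepointKey))
  mat <- as.matrix(df[, genes, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- as.character(df$cell_id)
  list(mat = mat, stamps = stamps)
}

.readExpressionMTX <- function(path, timepointKey) {
  if (!dir.exists(path)) stop("mtx format expects a directory: ", path)
  m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
  genes <- readLines(file.path(path, "genes.tsv"))
  cells <- utils::read.delim(file.path(path, "cells.tsv"),
                             stringsAsFactors = FALSE)
  if (!timepointKey %in% names(cells))
    stop("cells.tsv has no timepoint column '", timepointKey, "'")
  if (nrow(m) != nrow(cells) || ncol(m) != length(genes))
    stop("matrix.mtx dimensions do not match genes.tsv/cells.tsv")
  dimnames(m) <- list(as.character(cells$cell_id), genes)
  list(mat = m, stamps = cells[[timepointKey]])
}

.readExpressionH5 <- function(path, timepointKey, layer) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading HDF5 containers requires the 'rhdf5' package")
  mat <- rhdf5::h5read(path, layer)
  genes <- as.character(rhdf5::h5read(path, "gene_names"))
  cells <- as.character(rhdf5::h5read(path, "cell_ids"))
  stamps <- as.vector(rhdf5::h5read(path, timepointKey))
  if (nrow(mat) != length(cells)) mat <- t(mat)
  dimnames(mat) <- list(cells, genes)
  list(mat = mat, stamps = stamps)
}

.partitionByStamp <- function(mat, stamps) {
  missing <- which(is.na(stamps) | (is.character(stamps) & !nzchar(stamps)))
  if (length(missing))
    stop("cells without a timepoint stamp: ",
         paste(rownames(mat)[missing], collapse = ", "))
  stamps <- as.numeric(stamps)
  lev <- sort(unique(stamps))
  if (length(lev) < 2L) stop("need at least 2 distinct timepoints")
  blocks <- lapply(lev, function(s) mat[stamps == s, , drop = FALSE])
  TimeStampedExpression(blocks, lev)
}

#' Write a time-stamped expression dataset
#'
#' Inverse of [loadExpression()] for the `csv` and `mtx` layouts (and `h5`
#' when rhdf5 is available); a written dataset loads back with identical
#' matrices and ordering.
#'
#' @param dataset a \linkS4class{TimeStampedExpression}.
#' @param path output file (csv, h5) or directory (mtx).
#' @param format one of `"csv"`, `"mtx"`, `"h5"`.
#' @param timepointKey stamp column/dataset name to write.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(dataset, path, format = c("csv", "mtx", "h5"),
                            timepointKey = "timepoint") {
  format <- match.arg(format)
  mat <- do.call(rbind, blocks(dataset))
  stamps <- rep(timepoints(dataset), nCells(dataset))
  if (format == "csv") {
    df <- data.frame(cell_id = rownames(mat), stamp = stamps,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[2L] <- timepointKey
    df <- cbind(df, as.data.frame(mat, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(mat), file.path(path, "genes.tsv"))
    cells <- data.frame(cell_id = rownames(mat), stamp = stamps)
    names(cells)[2L] <- timepointKey
    utils::write.table(cells, file.path(path, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("writing HDF5 containers requires the 'rhdf5' package")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(mat, path, "X")
    rhdf5::h5write(colnames(mat), path, "gene_names")
    rhdf5::h5write(rownames(mat), path, "cell_ids")
    rhdf5::h5write(stamps, path, timepointKey)
    rhdf5::h5closeAll()
  }
  invisible(path)
}

## Normalization ------------------------------------------------------------

#' Total-count normalize and log1p-transform raw counts
#'
#' Scales every cell's counts to a common target sum, then applies
#' log(1 + x), the standard single-cell normalization. Cells with zero
#' total are left all-zero (with a warning).
#'
#' @param raw a \linkS4class{TimeStampedExpression} of raw counts (>= 0).
#' @param targetSum positive number, or `"median"` (default) for the median
#'   of nonzero per-cell totals.
#' @return A \linkS4class{TimeStampedExpression} of log-normalized values.
#' @export
normalizeCounts <- function(raw, targetSum = "median") {
  if (any(vapply(blocks(raw), function(b) any(b < 0), logical(1L))))
    stop("raw counts must be nonnegative")
  totals <- unlist(lapply(blocks(raw), rowSums), use.names = FALSE)
  if (identical(targetSum, "median")) {
    nz <- totals[totals > 0]
    if (!length(nz)) stop("all cells have zero total counts")
    targetSum <- stats::median(nz)
  }
  if (!is.numeric(targetSum) || targetSum <= 0)
    stop("targetSum must be positive or 'median'")
  if (any(totals == 0))
    warning(sum(totals == 0), " cell(s) with zero total counts left as zero")
  out <- lapply(blocks(raw), function(b) {
    tot <- rowSums(b)
    scale <- ifelse(tot > 0, targetSum / tot, 0)
    log1p(b * scale)
  })
  TimeStampedExpression(out, timepoints(raw))
}

## Pseudotime binning -------------------------------------------------------

#' Bin continuous pseudotimes into discrete timepoints
#'
#' Maps per-cell pseudotimes to integer bins 1..nBins so a coupling-based
#' analysis can treat the bins as discrete snapshots with unit spacing.
#' The map is monotone: a larger pseudotime never gets an earlier bin.
#'
#' @param pseudotimes finite numeric vector, one value per cell.
#' @param nBins integer >= 2.
#' @param strategy `"quantile"` (default; near-equal occupancy) or
#'   `"uniform"` (equal-width intervals over the pseudotime range).
#' @return Integer bin assignments in `1..nBins`.
#' @export
binPseudotime <- function(pseudotimes, nBins,
                          strategy = c("quantile", "uniform")) {
  strategy <- match.arg(strategy)
  if (!all(is.finite(pseudotimes))) stop("pseudotimes must be finite")
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  breaks <- if (strategy == "quantile") {
    stats::quantile(pseudotimes, probs = seq(0, 1, length.out = nBins + 1L),
                    names = FALSE)
  } else {
    seq(min(pseudotimes), max(pseudotimes), length.out = nBins + 1L)
  }
  if (anyDuplicated(breaks))
    stop("a pseudotime bin would be empty; use fewer bins")
  bins <- as.integer(cut(pseudotimes, breaks = breaks, include.lowest = TRUE,
                         right = TRUE))
  occ <- tabulate(bins, nbins = nBins)
  if (any(occ == 0L))
    stop("pseudotime bin(s) ", paste(which(occ == 0L), collapse = ", "),
         " would be empty; use fewer bins")
  bins
}

## Cell-type loading --------------------------------------------------------

#' Load per-cell cell-type labels or proportions
#'
#' Hard labels are expanded to one-hot simplex rows so that downstream
#' cell type-weighted statistics treat both label kinds uniformly. Soft
#' rows must sum to 1 within 1e-6 and are renormalized exactly.
#'
#' @param path TSV with header: `cell_id, label` (hard mode) or
#'   `cell_id` plus one numeric column per cell type (soft mode).
#' @param dataset the matching \linkS4class{TimeStampedExpression}.
#' @param mode `"hard"` or `"soft"`.
#' @return A \linkS4class{CellTypeProportions} aligned to `dataset`.
#' @export
loadCellTypes <- function(path, dataset, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df)) stop("cell-type file needs 'cell_id' column")
  allIds <- unlist(cellIds(dataset), use.names = FALSE)
  missing <- setdiff(allIds, df$cell_id)
  if (length(missing))
    stop("no cell-type entry for cell(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  df <- df[match(allIds, df$cell_id), , drop = FALSE]
  if (mode == "hard") {
    if (!"label" %in% names(df)) stop("hard mode needs a 'label' column")
    CellTypeProportions(df$label, dataset)
  } else {
    typeCols <- setdiff(names(df), "cell_id")
    P <- as.matrix(df[, typeCols, drop = FALSE])
    mode(P) <- "numeric"
    rs <- rowSums(P)
    bad <- which(abs(rs - 1) > 1e-6)
    if (length(bad))
      stop("proportion row(s) not summing to 1 (tolerance 1e-6) for cell(s): ",
           paste(utils::head(df$cell_id[bad], 10L), collapse = ", "))
    P <- P / rs
    CellTypeProportions(P, dataset, labels = typeCols)
  }
}

## GRN I/O ------------------------------------------------------------------

#' Write a GRN as a ranked edge-list TSV
#'
#' Emits columns `regulator, target, score, rank`, ranked by descending
#' absolute score with lexicographic tie-breaks; self-edges are excluded.
#' Output is deterministic: identical networks yield byte-identical files.
#'
#' @param grn a \linkS4class{GRNMatrix}.
#' @param path output TSV path.
#' @param topK optional cutoff; `NULL` writes all off-diagonal edges.
#' @return `path`, invisibly.
#' @export
writeGRN <- function(grn, path, topK = NULL) {
  g <- nrow(scores(grn))
  if (is.null(topK)) topK <- g * (g - 1L)
  ranking <- rankEdges(grn, topK)
  e <- edges(ranking)
  e$score <- sprintf("%.10g", e$score)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth GRN edge list
#'
#' @param path two-column TSV of (regulator, target) pairs; a header line
#'   `regulator<TAB>target` is skipped if present.
#' @param name identifier for the truth set (defaults to the file name).
#' @param cellType optional cell-type tag.
#' @return A \linkS4class{GroundTruthGRN}.
#' @export
readGroundTruth <- function(path, name = basename(path),
                            cellType = NA_character_) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && identical(tolower(as.character(df[1L, 1:2])),
                            c("regulator", "target")))
    df <- df[-1L, , drop = FALSE]
  GroundTruthGRN(df[, 1:2], name = name, cellType = cellType)
}
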