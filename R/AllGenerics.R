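#' @include AllClasses.R
NULL

#' Accessors for veloGRN containers
#'
#' `timepoints` returns the ordered stamps of a
#' \linkS4class{TimeStampedExpression}; `blocks` its per-timepoint
#' expression matrices; `geneNames` the shared gene axis; `cellIds` the
#' per-block cell identifiers; `nCells` the per-block cell counts.
#' `coupling` extracts the matrix of a \linkS4class{TransitionMatrix},
#' `scores` the matrix of a \linkS4class{GRNMatrix}, `edges` the table of an
#' \linkS4class{EdgeRanking} or \linkS4class{GroundTruthGRN}, and
#' `cellTypeLabels` the type names of a \linkS4class{CellTypeProportions}.
#'
#' @param x a veloGRN object.
#' @return The slot contents described above.
#' @name accessors
#' @aliases timepoints blocks geneNames cellIds nCells coupling scores edges
#'   cellTypeLabels velocityBlocks velocitySchemes
NULL

#' @rdname accessors
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))
#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))
#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("coupling", function(x) standardGeneric("coupling"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("cellTypeLabels", function(x) standardGeneric("cellTypeLabels"))
#' @rdname accessors
#' @export
setGeneric("velocityBlocks", function(x) standardGeneric("velocityBlocks"))
#' @rdname accessors
#' @export
setGeneric("velocitySchemes", function(x) standardGeneric("velocitySchemes"))

setMethod("timepoints", "TimeStampedExpression", function(x) x@timepoints)
setMethod("blocks", "TimeStampedExpression", function(x) x@blocks)
setMethod("geneNames", "TimeStampedExpression",
          function(x) colnames(x@blocks[[1L]]))
setMethod("cellIds", "TimeStampedExpression",
          function(x) lapply(x@blocks, rownames))
setMethod("nCells", "TimeStampedExpression",
          function(x) vapply(x@blocks, nrow, 0L))
setMethod("coupling", "TransitionMatrix", function(x) x@coupling)
setMethod("scores", "GRNMatrix", function(x) x@scores)
setMethod("geneNames", "GRNMatrix", function(x) rownames(x@scores))
setMethod("geneNames", "EdgeRanking", function(x) x@geneNames)
setMethod("edges", "EdgeRanking", function(x) x@edges)
setMethod("edges", "GroundTruthGRN", function(x) x@edges)
setMethod("cellTypeLabels", "CellTypeProportions", function(x) x@labels)
setMethod("blocks", "CellTypeProportions", function(x) x@perBlock)
setMethod("velocityBlocks", "VelocityField", function(x) x@perBlock)
setMethod("velocitySchemes", "VelocityField", function(x) x@schemes)

setMethod("show", "TimeStampedExpression", function(object) {
  cat("TimeStampedExpression:", length(object@timepoints), "timepoints,",
      ncol(object@blocks[[1L]]), "genes\n")
  cat("  stamps:", paste(signif(object@timepoints, 4), collapse = ", "), "\n")
  cat("  cells per timepoint:",
      paste(vapply(object@blocks, nrow, 0L), collapse = ", "), "\n")
})

setMethod("show", "CellTypeProportions", function(object) {
  cat("CellTypeProportions:", length(object@labels), "cell types over",
      sum(vapply(object@perBlock, nrow, 0L)), "cells\n")
  cat("  labels:", paste(object@labels, collapse = ", "), "\n")
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix %d x %d for pair (%g, %g)\n",
              nrow(object@coupling), ncol(object@coupling),
              object@pair[1L], object@pair[2L]))
  cat(sprintf("  final objective %.6g after %d iterations (%s)\n",
              utils::tail(object@objective, 1L), length(object@objective),
              if (object@converged) "converged" else "max iterations"))
})

setMethod("show", "VelocityField", function(object) {
  cat("VelocityField:", length(object@perBlock), "blocks; schemes:",
      paste(object@schemes, collapse = ", "), "\n")
  cat("  standardized:", object@standardized)
  if (length(object@degenerateGenes))
    cat(";", length(object@degenerateGenes), "degenerate gene(s)")
  cat("\n")
})

setMethod("show", "GRNMatrix", function(object) {
  kind <- if (is.na(object@cellType)) "global"
          else paste0("cell type '", object@cellType, "'")
  cat(sprintf("GRNMatrix (%s): %d x %d genes; |score| range [%.4g, %.4g]\n",
              kind, nrow(object@scores), ncol(object@scores),
              min(abs(object@scores)), max(abs(object@scores))))
})

setMethod("show", "EdgeRanking", function(object) {
  cat("EdgeRanking: top", nrow(object@edges), "edges (k =", object@k, ")\n")
  print(utils::head(object@edges, 5L))
})

setMethod("show", "GroundTruthGRN", function(object) {
  cat("GroundTruthGRN '", object@name, "': ", nrow(object@edges),
      " directed edges", sep = "")
  if (!is.na(object@cellType)) cat(" [", object@cellType, "]", sep = "")
  cat("\n")
})
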