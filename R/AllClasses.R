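#' @import methods
#' @importFrom stats rnorm runif quantile sd phyper p.adjust
NULL

## ---------------------------------------------------------------------------
## TimeStampedExpression
## ---------------------------------------------------------------------------

#' Time-stamped single-cell expression container
#'
#' Holds per-timepoint expression blocks sharing one gene axis. Block k is a
#' numeric matrix of c_k cells (rows, named by cell id) by g genes (columns,
#' named by gene). Timepoints are strictly increasing real stamps; cells are
#' measured destructively, so no cell id may occur in two blocks.
#'
#' @slot timepoints numeric, strictly increasing stamps, length N >= 2.
#' @slot blocks list of N cells-by-genes numeric matrices with identical
#'   column names and unique row names across blocks.
#'
#' @aliases TimeStampedExpression-class
#' @export
setClass("TimeStampedExpression",
  representation(timepoints = "numeric", blocks = "list"))

setValidity("TimeStampedExpression", function(object) {
  msg <- character()
  N <- length(object@timepoints)
  if (N < 2L) msg <- c(msg, "need at least 2 timepoints")
  if (length(object@blocks) != N)
    msg <- c(msg, "number of blocks must equal number of timepoints")
  if (N >= 2L && any(diff(object@timepoints) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (!all(vapply(object@blocks, is.matrix, logical(1L))))
    msg <- c(msg, "all blocks must be matrices")
  if (length(msg) == 0L) {
    gn <- colnames(object@blocks[[1L]])
    if (is.null(gn)) msg <- c(msg, "blocks must have gene (column) names")
    for (b in object@blocks) {
      if (!identical(colnames(b), gn)) {
        msg <- c(msg, "all blocks must share an identical gene axis")
        break
      }
    }
    ids <- unlist(lapply(object@blocks, rownames), use.names = FALSE)
    if (is.null(ids) || length(ids) != sum(vapply(object@blocks, nrow, 0L)))
      msg <- c(msg, "every block must have cell (row) names")
    else if (anyDuplicated(ids))
      msg <- c(msg, "cell ids must be unique across blocks (destructive sampling)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TimeStampedExpression
#'
#' @param blocks list of cells-by-genes matrices (row names: cell ids,
#'   column names: genes), one per timepoint, in time order.
#' @param timepoints numeric stamps, strictly increasing, one per block.
#' @return A \linkS4class{TimeStampedExpression}.
#' @examples
#' b1 <- matrix(1:6, 2, 3, dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
#' b2 <- matrix(7:12, 2, 3, dimnames = list(c("c3", "c4"), c("g1", "g2", "g3")))
#' TimeStampedExpression(list(b1, b2), c(0, 1))
#' @export
TimeStampedExpression <- function(blocks, timepoints) {
  ord <- order(timepoints)
  new("TimeStampedExpression",
      timepoints = as.numeric(timepoints)[ord], blocks = blocks[ord])
}

## ---------------------------------------------------------------------------
## CellTypeProportions
## ---------------------------------------------------------------------------

#' Per-cell cell-type proportion container
#'
#' One simplex vector over H cell types per cell, stored blockwise in the
#' order of a \linkS4class{TimeStampedExpression}. Hard labels are the
#' degenerate (one-hot) case.
#'
#' @slot labels character, the H cell-type names.
#' @slot perBlock list of cells-by-H numeric matrices; each row sums to 1.
#'
#' @aliases CellTypeProportions-class
#' @export
setClass("CellTypeProportions",
  representation(labels = "character", perBlock = "list"))

setValidity("CellTypeProportions", function(object) {
  H <- length(object@labels)
  if (H < 1L) return("need at least one cell type")
  for (m in object@perBlock) {
    if (!is.matrix(m) || ncol(m) != H)
      return("each block must be a matrix with one column per cell type")
    if (any(m < -1e-12) || any(m > 1 + 1e-8))
      return("proportions must lie in [0, 1]")
    if (nrow(m) > 0L && any(abs(rowSums(m) - 1) > 1e-8))
      return("each cell's proportions must sum to 1 (tolerance 1e-8)")
  }
  TRUE
})

#' Construct CellTypeProportions from labels or a proportion matrix
#'
#' @param x either a character/factor vector of hard labels (one per cell,
#'   in block order) or a numeric cells-by-H matrix of proportions with
#'   column names naming the types.
#' @param dataset the matching \linkS4class{TimeStampedExpression}; defines
#'   the block structure and cell order.
#' @param labels optional explicit type names (defaults to the levels found).
#' @return A \linkS4class{CellTypeProportions}.
#' @export
CellTypeProportions <- function(x, dataset, labels = NULL) {
  sizes <- vapply(blocks(dataset), nrow, 0L)
  total <- sum(sizes)
  if (is.matrix(x)) {
    if (nrow(x) != total)
      stop("proportion matrix must have one row per cell (", total, ")")
    if (is.null(labels)) labels <- colnames(x)
    if (is.null(labels)) stop("proportion matrix needs column names or 'labels'")
    P <- x
  } else {
    x <- as.character(x)
    if (length(x) != total)
      stop("need one label per cell (", total, " cells)")
    if (is.null(labels)) labels <- sort(unique(x))
    unknown <- setdiff(x, labels)
    if (length(unknown))
      stop("unknown cell type label(s): ", paste(unknown, collapse = ", "))
    P <- matrix(0, total, length(labels), dimnames = list(NULL, labels))
    P[cbind(seq_len(total), match(x, labels))] <- 1
  }
  colnames(P) <- labels
  off <- c(0L, cumsum(sizes))
  per <- lapply(seq_along(sizes), function(k) {
    m <- P[(off[k] + 1L):(off[k] + sizes[k]), , drop = FALSE]
    rownames(m) <- rownames(blocks(dataset)[[k]])
    m
  })
  new("CellTypeProportions", labels = labels, perBlock = per)
}

## ---------------------------------------------------------------------------
## TransportConfig
## ---------------------------------------------------------------------------

#' Configuration for the entropic fused Gromov-Wasserstein solver
#'
#' @slot alpha numeric in [0, 1]; weight of the Gromov-Wasserstein
#'   (structure-matching) term against the Wasserstein (cross-cost) term.
#' @slot epsilon numeric; entropic regularization strength. `NA` means
#'   auto-scaling to 0.05 times the mean cross cost of each pair.
#' @slot maxIter integer; outer iteration cap.
#' @slot tol numeric; convergence tolerance on the coupling update.
#' @slot costMetric `"sq-euclidean"` or `"euclidean"`.
#' @slot reduceDim integer or NA; optional PCA rank applied to expression
#'   before distance computation.
#'
#' @aliases TransportConfig-class
#' @export
setClass("TransportConfig",
  representation(alpha = "numeric", epsilon = "numeric", maxIter = "integer",
                 tol = "numeric", costMetric = "character",
                 reduceDim = "integer"))

setValidity("TransportConfig", function(object) {
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0, 1]")
  if (!is.na(object@epsilon) && object@epsilon <= 0)
    return("epsilon must be positive")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@tol <= 0) return("tol must be positive")
  if (!object@costMetric %in% c("sq-euclidean", "euclidean"))
    return("costMetric must be 'sq-euclidean' or 'euclidean'")
  TRUE
})

#' Create a TransportConfig
#'
#' @param alpha Wasserstein/Gromov-Wasserstein trade-off in [0, 1].
#' @param epsilon entropic regularization; `NA` (default) auto-scales to
#'   0.05 x mean cross-cost per timepoint pair.
#' @param maxIter outer iteration cap.
#' @param tol convergence tolerance on the L1 change of the coupling.
#' @param costMetric `"sq-euclidean"` (default) or `"euclidean"`.
#' @param reduceDim optional PCA rank for expression before distances;
#'   `NA` (default) uses full expression.
#' @return A \linkS4class{TransportConfig}.
#' @export
transportConfig <- function(alpha = 0.5, epsilon = NA_real_, maxIter = 1000L,
                            tol = 1e-6, costMetric = "sq-euclidean",
                            reduceDim = NA_integer_) {
  new("TransportConfig", alpha = as.numeric(alpha),
      epsilon = as.numeric(epsilon), maxIter = as.integer(maxIter),
      tol = as.numeric(tol), costMetric = costMetric,
      reduceDim = as.integer(reduceDim))
}

## ---------------------------------------------------------------------------
## TransitionMatrix
## ---------------------------------------------------------------------------

#' Optimal-transport coupling between two consecutive timepoints
#'
#' @slot coupling numeric c_t-by-c_t~ matrix; nonnegative, total mass ~ 1.
#' @slot p numeric source marginal (row sums of `coupling`).
#' @slot q numeric target marginal (column sums of `coupling`).
#' @slot pair numeric length-2, the (t, t~) stamps coupled.
#' @slot objective numeric trace of the solver objective per outer iteration.
#' @slot converged logical; FALSE if maxIter was exhausted.
#'
#' @aliases TransitionMatrix-class
#' @export
setClass("TransitionMatrix",
  representation(coupling = "matrix", p = "numeric", q = "numeric",
                 pair = "numeric", objective = "numeric",
                 converged = "logical"))

setValidity("TransitionMatrix", function(object) {
  T <- object@coupling
  if (any(T < -1e-12)) return("coupling entries must be nonnegative")
  if (length(object@p) != nrow(T) || length(object@q) != ncol(T))
    return("marginal lengths must match coupling dimensions")
  if (abs(sum(T) - 1) > 1e-4) return("total coupling mass must be ~1")
  if (length(object@pair) != 2L) return("pair must be two timepoint stamps")
  TRUE
})

## ---------------------------------------------------------------------------
## VelocityField
## ---------------------------------------------------------------------------

#' Per-cell, per-gene velocity field
#'
#' Finite-difference rates of change of expression aligned to the blocks of
#' a \linkS4class{TimeStampedExpression}. The first block uses the forward
#' scheme, the last the backward scheme, and interior blocks the centred
#' convex combination.
#'
#' @slot perBlock list of cells-by-genes velocity matrices.
#' @slot schemes character, one of "forward"/"center"/"backward" per block.
#' @slot standardized logical; TRUE after per-gene pooled-sd normalization.
#' @slot degenerateGenes character; genes zeroed for near-zero pooled sd.
#'
#' @aliases VelocityField-class
#' @export
setClass("VelocityField",
  representation(perBlock = "list", schemes = "character",
                 standardized = "logical", degenerateGenes = "character"))

setValidity("VelocityField", function(object) {
  if (length(object@perBlock) != length(object@schemes))
    return("one scheme per block required")
  if (!all(object@schemes %in% c("forward", "center", "backward")))
    return("schemes must be forward/center/backward")
  TRUE
})

## ---------------------------------------------------------------------------
## GRNMatrix
## ---------------------------------------------------------------------------

#' Inferred gene regulatory network score matrix
#'
#' Entry (i, j) is the time-lagged correlation of regulator i's velocity at
#' t_k with target j's velocity at t_{k+1}, accumulated over consecutive
#' timepoint pairs and weighted by the transport coupling (and, for cell
#' type-specific networks, by cell-type proportions). The sign carries the
#' activating/repressive direction; the diagonal is reported but never
#' ranked.
#'
#' @slot scores numeric g-by-g matrix with gene dimnames.
#' @slot cellType character; `NA` for the global network.
#'
#' @aliases GRNMatrix-class
#' @export
setClass("GRNMatrix",
  representation(scores = "matrix", cellType = "character"))

setValidity("GRNMatrix", function(object) {
  s <- object@scores
  if (nrow(s) != ncol(s)) return("score matrix must be square")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    return("score matrix needs identical row/column gene names")
  if (any(!is.finite(s))) return("scores must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## EdgeRanking
## ---------------------------------------------------------------------------

#' Ranked top-k edge list of a GRN
#'
#' @slot edges data.frame with columns regulator, target, score, rank;
#'   ordered by descending ranking statistic, ties broken lexicographically
#'   by (regulator, target); no self-edges.
#' @slot k integer, the requested cutoff.
#' @slot geneNames character, the gene universe of the source network.
#'
#' @aliases EdgeRanking-class
#' @export
setClass("EdgeRanking",
  representation(edges = "data.frame", k = "integer", geneNames = "character"))

setValidity("EdgeRanking", function(object) {
  e <- object@edges
  need <- c("regulator", "target", "score", "rank")
  if (!all(need %in% names(e)))
    return("edges needs columns regulator, target, score, rank")
  if (any(e$regulator == e$target)) return("self-edges are not allowed")
  TRUE
})

## ---------------------------------------------------------------------------
## GroundTruthGRN
## ---------------------------------------------------------------------------

#' Ground-truth regulator-target edge set
#'
#' @slot edges data.frame with character columns regulator, target;
#'   directed, duplicates collapsed.
#' @slot name character identifier of the truth source.
#' @slot cellType character; `NA` if not cell type-specific.
#'
#' @aliases GroundTruthGRN-class
#' @export
setClass("GroundTruthGRN",
  representation(edges = "data.frame", name = "character",
                 cellType = "character"))

setValidity("GroundTruthGRN", function(object) {
  e <- object@edges
  if (!all(c("regulator", "target") %in% names(e)))
    return("edges needs columns regulator, target")
  if (nrow(e) && (any(!nzchar(e$regulator)) || any(!nzchar(e$target))))
    return("gene names must be non-empty strings")
  TRUE
})

#' Construct a GroundTruthGRN from an edge table
#'
#' @param edges data.frame (or two-column object) of regulator, target pairs.
#' @param name identifier for the truth set.
#' @param cellType optional cell-type tag.
#' @return A \linkS4class{GroundTruthGRN}; duplicate pairs are collapsed.
#' @export
GroundTruthGRN <- function(edges, name = "truth", cellType = NA_character_) {
  edges <- data.frame(regulator = as.character(edges[[1L]]),
                      target = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  rownames(edges) <- NULL
  new("GroundTruthGRN", edges = edges, name = name,
      cellType = as.character(cellType))
}

## ---------------------------------------------------------------------------
## SimulationConfig / SyntheticTruth
## ---------------------------------------------------------------------------

#' Configuration of the synthetic snapshot generator
#'
#' Latent lineages evolve under cell type-specific linear dynamics
#' x(t + dt) = max(0, x + dt (A_shared + A_type) x + noise); each timepoint
#' emits an independent set of cells (destructive sampling).
#'
#' @slot nTimepoints integer >= 2.
#' @slot cellsPerTimepoint integer; also the number of latent lineages.
#' @slot nGenes integer.
#' @slot nCellTypes integer >= 1.
#' @slot edgesPerType integer; planted type-specific edges per cell type.
#' @slot sharedEdges integer; planted edges common to all types.
#' @slot effectSize numeric >= 0; magnitude of regulatory coefficients.
#' @slot noiseSd numeric >= 0; sd of the per-step Gaussian perturbation.
#' @slot dt numeric > 0; integration/sampling step.
#' @slot seed integer RNG seed.
#'
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig",
  representation(nTimepoints = "integer", cellsPerTimepoint = "integer",
                 nGenes = "integer", nCellTypes = "integer",
                 edgesPerType = "integer", sharedEdges = "integer",
                 effectSize = "numeric", noiseSd = "numeric",
                 dt = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nTimepoints < 2L) return("need at least 2 timepoints")
  if (object@cellsPerTimepoint < 1L) return("need at least 1 cell per timepoint")
  if (object@nGenes < 2L) return("need at least 2 genes")
  if (object@nCellTypes < 1L) return("need at least 1 cell type")
  if (object@effectSize < 0) return("effectSize must be nonnegative")
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  if (object@dt <= 0) return("dt must be positive")
  npairs <- object@nGenes * (object@nGenes - 1L)
  if (object@sharedEdges + object@nCellTypes * object@edgesPerType > npairs)
    return("too many planted edges for the number of genes")
  TRUE
})

#' Create a SimulationConfig
#'
#' Defaults define the package's reference synthetic study: 4 timepoints of
#' 200 cells over 30 genes with 2 cell types, 10 planted edges per type plus
#' 5 shared, effect size 0.5, noise sd 0.1, unit time step.
#'
#' @param nTimepoints,cellsPerTimepoint,nGenes,nCellTypes dimensions.
#' @param edgesPerType,sharedEdges planted edge counts.
#' @param effectSize,noiseSd,dt dynamics parameters.
#' @param seed RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nTimepoints = 4L, cellsPerTimepoint = 200L,
                             nGenes = 30L, nCellTypes = 2L,
                             edgesPerType = 10L, sharedEdges = 5L,
                             effectSize = 0.5, noiseSd = 0.1, dt = 1,
                             seed = 0L) {
  new("SimulationConfig", nTimepoints = as.integer(nTimepoints),
      cellsPerTimepoint = as.integer(cellsPerTimepoint),
      nGenes = as.integer(nGenes), nCellTypes = as.integer(nCellTypes),
      edgesPerType = as.integer(edgesPerType),
      sharedEdges = as.integer(sharedEdges),
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      dt = as.numeric(dt), seed = as.integer(seed))
}

#' Ground truth of a synthetic simulation
#'
#' @slot typeEdges named list (one per cell type) of data.frames with
#'   columns regulator, target, sign: the type-specific planted edges.
#' @slot sharedEdges data.frame of planted edges common to all types.
#' @slot trajectories numeric array lineages x genes x timepoints of latent
#'   states (debugging aid).
#' @slot lineageTypes character; cell type of each latent lineage.
#' @slot cellIds list of per-timepoint emitted cell id vectors.
#' @slot stamps numeric timepoint stamps of the emitted snapshots.
#' @slot geneNames character.
#'
#' @aliases SyntheticTruth-class
#' @export
setClass("SyntheticTruth",
  representation(typeEdges = "list", sharedEdges = "data.frame",
                 trajectories = "array", lineageTypes = "character",
                 cellIds = "list", stamps = "numeric",
                 geneNames = "character"))
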