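#' @include AllClasses.R AllGenerics.R
NULL

.samplePlantedEdges <- function(config) {
  g <- config@nGenes
  M <- matrix(0, g, g)
  pairs <- which(row(M) != col(M))
  need <- config@sharedEdges + config@nCellTypes * config@edgesPerType
  pick <- sample(pairs, need)
  mkdf <- function(ix) data.frame(
    regulator = paste0("g", col(M)[ix], recycle0 = TRUE),
    target = paste0("g", row(M)[ix], recycle0 = TRUE),
    sign = sample(c(-1, 1), length(ix), replace = TRUE),
    stringsAsFactors = FALSE)
  shared <- mkdf(pick[seq_len(config@sharedEdges)])
  rest <- pick[config@sharedEdges + seq_len(length(pick) - config@sharedEdges)]
  typeEdges <- lapply(seq_len(config@nCellTypes), function(h)
    mkdf(rest[((h - 1L) * config@edgesPerType + 1L):(h * config@edgesPerType)]))
  names(typeEdges) <- paste0("type", seq_len(config@nCellTypes))
  list(shared = shared, typeEdges = typeEdges)
}

.edgeMatrix <- function(df, g, effect) {
  A <- matrix(0, g, g)
  if (nrow(df)) {
    i <- as.integer(sub("^g", "", df$target))
    j <- as.integer(sub("^g", "", df$regulator))
    A[cbind(i, j)] <- df$sign * effect
  }
  A
}

#' Simulate destructively sampled snapshots under known dynamics
#'
#' Evolves one latent lineage per emitted cell under cell type-specific
#' linear regulatory dynamics
#' \deqn{x_{t+dt} = \max\{0,\; x_t + dt\,(A_{shared} + A_{type})\,x_t +
#'   \mathcal N(0, \sigma^2)\}}
#' where the A matrices carry the planted signed edges (entry (target,
#' regulator) = sign x effectSize). At every timepoint each lineage emits
#' one freshly labelled cell, so cell ids are disjoint across timepoints —
#' the destructive-sampling regime of single-cell assays. Lineages are
#' assigned to cell types round-robin (near-equal proportions) with
#' one-hot labels. Fully deterministic given `config@seed`.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return List with `dataset` (\linkS4class{TimeStampedExpression}),
#'   `proportions` (\linkS4class{CellTypeProportions}) and `truth`
#'   (\linkS4class{SyntheticTruth}).
#' @export
simulateRegulatoryDynamics <- function(config) {
  validObject(config)
  set.seed(config@seed)
  g <- config@nGenes
  nL <- config@cellsPerTimepoint
  N <- config@nTimepoints
  H <- config@nCellTypes
  geneNames <- paste0("g", seq_len(g))
  planted <- .samplePlantedEdges(config)
  Ashared <- .edgeMatrix(planted$shared, g, config@effectSize)
  Atype <- lapply(planted$typeEdges, .edgeMatrix, g = g,
                  effect = config@effectSize)
  lineageTypes <- paste0("type", rep_len(seq_len(H), nL))
  X <- matrix(runif(nL * g, 1, 2), nL, g)  # initial lineage states
  traj <- array(NA_real_, dim = c(nL, g, N))
  for (k in seq_len(N)) {
    traj[, , k] <- X
    if (k < N) {
      drift <- X %*% t(Ashared)
      for (h in seq_len(H)) {
        sel <- lineageTypes == paste0("type", h)
        if (any(sel))
          drift[sel, ] <- drift[sel, ] +
            X[sel, , drop = FALSE] %*% t(Atype[[h]])
      }
      X <- pmax(X + config@dt * drift +
                  matrix(rnorm(nL * g, sd = config@noiseSd), nL, g), 0)
    }
  }
  tp <- seq_len(N) * config@dt
  cellIds <- lapply(seq_len(N), function(k)
    sprintf("t%d_c%03d", k, seq_len(nL)))
  blocksList <- lapply(seq_len(N), function(k) {
    m <- matrix(traj[, , k], nL, g)
    dimnames(m) <- list(cellIds[[k]], geneNames)
    m
  })
  dataset <- TimeStampedExpression(blocksList, tp)
  proportions <- CellTypeProportions(rep(lineageTypes, N), dataset,
                                     labels = paste0("type", seq_len(H)))
  truth <- new("SyntheticTruth",
               typeEdges = planted$typeEdges, sharedEdges = planted$shared,
               trajectories = traj, lineageTypes = lineageTypes,
               cellIds = cellIds, stamps = tp, geneNames = geneNames)
  list(dataset = dataset, proportions = proportions, truth = truth)
}

#' Planted edges of a synthetic truth
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param cellType a type name for that type's truth (its specific edges
#'   plus the shared ones), or `NULL` (default) for the union over all
#'   types — the global truth.
#' @return data.frame with columns regulator, target, sign.
#' @export
plantedEdges <- function(truth, cellType = NULL) {
  if (is.null(cellType)) {
    out <- rbind(truth@sharedEdges,
                 do.call(rbind, unname(truth@typeEdges)))
  } else {
    if (!cellType %in% names(truth@typeEdges))
      stop("unknown cell type '", cellType, "'")
    out <- rbind(truth@sharedEdges, truth@typeEdges[[cellType]])
  }
  rownames(out) <- NULL
  out
}

#' True lineage-based coupling between two timepoints
#'
#' Each emitted cell at the earlier timepoint descends from exactly one
#' cell at the later timepoint (its own lineage), so the true coupling
#' places uniform mass 1/n on each ancestor-descendant pair — an identity
#' permutation over lineages. Using it instead of an inferred coupling
#' isolates the lagged-correlation statistic from transport error.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param pair integer length-2: indices (k, k+1) of consecutive
#'   timepoints.
#' @return A \linkS4class{TransitionMatrix}.
#' @export
oracleCoupling <- function(truth, pair) {
  k <- as.integer(pair)
  N <- length(truth@cellIds)
  if (length(k) != 2L || k[2L] != k[1L] + 1L || k[1L] < 1L || k[2L] > N)
    stop("pair must index two consecutive timepoints")
  n <- length(truth@cellIds[[k[1L]]])
  T <- diag(n) / n
  dimnames(T) <- list(truth@cellIds[[k[1L]]], truth@cellIds[[k[2L]]])
  new("TransitionMatrix", coupling = T, p = rep(1 / n, n), q = rep(1 / n, n),
      pair = truth@stamps[k], objective = numeric(0), converged = TRUE)
}

#' All consecutive oracle couplings of a synthetic truth
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return List of N-1 \linkS4class{TransitionMatrix} objects.
#' @export
oracleCouplings <- function(truth) {
  N <- length(truth@cellIds)
  lapply(seq_len(N - 1L), function(k) oracleCoupling(truth, c(k, k + 1L)))
}
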