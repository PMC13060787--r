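#' @include AllClasses.R AllGenerics.R transport.R velocity.R
NULL

.laggedContraction <- function(field, transitions, srcW = NULL, tgtW = NULL) {
  V <- field@perBlock
  N <- length(V)
  g <- ncol(V[[1L]])
  C <- matrix(0, g, g)
  for (k in seq_len(N - 1L)) {
    Vk <- V[[k]]; Vk1 <- V[[k + 1L]]
    if (!is.null(srcW)) Vk <- Vk * srcW[[k]]
    if (!is.null(tgtW)) Vk1 <- Vk1 * tgtW[[k + 1L]]
    T <- coupling(transitions[[k]])
    if (nrow(T) != nrow(Vk) || ncol(T) != nrow(Vk1))
      stop("coupling/velocity shape mismatch at pair ", k)
    C <- C + crossprod(Vk, T %*% Vk1)
  }
  C <- C / (N - 1L)
  gn <- colnames(V[[1L]])
  if (is.null(gn)) gn <- paste0("g", seq_len(g))
  dimnames(C) <- list(gn, gn)
  C
}

#' Global time-lagged correlation GRN
#'
#' Scores each directed gene pair (g1, g2) by the coupling-weighted sum of
#' products of g1's velocity in source cells at t_k with g2's velocity in
#' target cells at t_{k+1}, averaged over the N-1 consecutive pairs:
#' \deqn{C_{g_1,g_2} = \frac{1}{N-1}\sum_k \sum_{c,\bar c}
#'   v_{g_1}(x_{t_k,c})\, v_{g_2}(x_{t_{k+1},\bar c})\,
#'   T^{t_k,t_{k+1}}_{c,\bar c}}
#' computed as the accumulated matrix product V_k^T T V_{k+1}. A positive
#' entry suggests activation of g2 by g1 one step earlier; a negative entry
#' repression.
#'
#' @param field a standardized \linkS4class{VelocityField}.
#' @param transitions list of N-1 \linkS4class{TransitionMatrix} objects.
#' @return A global \linkS4class{GRNMatrix}.
#' @export
timeLaggedCorrelation <- function(field, transitions) {
  if (!field@standardized)
    stop("velocity field must be standardized first (standardizeVelocities)")
  new("GRNMatrix", scores = .laggedContraction(field, transitions),
      cellType = NA_character_)
}

#' Cell type-specific time-lagged correlation GRN
#'
#' Same contraction as [timeLaggedCorrelation()] with every source and
#' target cell additionally weighted by its proportion of the chosen cell
#' type, L(c, type) * L(c~, type), focusing the statistic on transitions
#' occurring within that type. With a single type of proportion 1
#' everywhere it reduces exactly to the global statistic.
#'
#' @param field a standardized \linkS4class{VelocityField}.
#' @param transitions list of N-1 \linkS4class{TransitionMatrix} objects.
#' @param proportions a \linkS4class{CellTypeProportions}.
#' @param cellType one of `cellTypeLabels(proportions)`.
#' @return A cell type-tagged \linkS4class{GRNMatrix}.
#' @export
celltypeTimeLaggedCorrelation <- function(field, transitions, proportions,
                                          cellType) {
  if (!field@standardized)
    stop("velocity field must be standardized first (standardizeVelocities)")
  if (!cellType %in% proportions@labels)
    stop("unknown cell type '", cellType, "'")
  L <- lapply(proportions@perBlock, function(m) m[, cellType])
  new("GRNMatrix",
      scores = .laggedContraction(field, transitions, srcW = L, tgtW = L),
      cellType = cellType)
}

#' Infer global and per-cell-type GRNs in one pass
#'
#' Full pipeline: couple consecutive timepoints with entropic fused
#' Gromov-Wasserstein transport, derive per-cell velocities with the
#' forward/center/backward boundary rule, standardize them per gene, then
#' evaluate the global and every cell type-specific time-lagged
#' correlation. One set of couplings is computed and reused for all
#' outputs, so the run is deterministic.
#'
#' @param dataset a \linkS4class{TimeStampedExpression} of log-normalized
#'   expression.
#' @param proportions a \linkS4class{CellTypeProportions} (or NULL for the
#'   global network only).
#' @param config a \linkS4class{TransportConfig}.
#' @param center passed to [standardizeVelocities()].
#' @return List with elements `global` (a \linkS4class{GRNMatrix}),
#'   `cellType` (named list of \linkS4class{GRNMatrix}), `transitions`,
#'   and `velocities`.
#' @export
inferGRNs <- function(dataset, proportions = NULL,
                      config = transportConfig(), center = FALSE) {
  transitions <- computeAllTransitions(dataset, config)
  field <- standardizeVelocities(assembleVelocities(dataset, transitions),
                                 center = center)
  global <- timeLaggedCorrelation(field, transitions)
  ct <- list()
  if (!is.null(proportions)) {
    ct <- lapply(proportions@labels, function(h)
      celltypeTimeLaggedCorrelation(field, transitions, proportions, h))
    names(ct) <- proportions@labels
  }
  list(global = global, cellType = ct, transitions = transitions,
       velocities = field)
}

#' Rank the top-k edges of a GRN
#'
#' Off-diagonal entries ranked by descending absolute score (so repressive
#' edges compete with activating ones) or by signed score, with ties broken
#' lexicographically by (regulator, target). Self-edges never appear; `k`
#' is clamped to the number of available edges.
#'
#' @param grn a \linkS4class{GRNMatrix}.
#' @param k positive integer cutoff.
#' @param by `"magnitude"` (default) or `"signed"`.
#' @return An \linkS4class{EdgeRanking}.
#' @export
rankEdges <- function(grn, k, by = c("magnitude", "signed")) {
  by <- match.arg(by)
  if (k < 1L) stop("k must be >= 1")
  S <- scores(grn)
  gn <- rownames(S)
  idx <- which(row(S) != col(S))
  df <- data.frame(regulator = gn[row(S)[idx]], target = gn[col(S)[idx]],
                   score = S[idx], stringsAsFactors = FALSE)
  stat <- if (by == "magnitude") abs(df$score) else df$score
  ord <- order(-stat, df$regulator, df$target)
  df <- df[ord, , drop = FALSE]
  kEff <- min(as.integer(k), nrow(df))
  df <- df[seq_len(kEff), , drop = FALSE]
  df$rank <- seq_len(kEff)
  rownames(df) <- NULL
  new("EdgeRanking", edges = df, k = as.integer(k), geneNames = gn)
}

.edgeKeys <- function(df) paste(df$regulator, df$target, sep = "\r")

#' Differential edges between a cell-type GRN and the global GRN
#'
#' Pairwise set difference of two equal-k top edge lists: `gained` holds
#' edges present in the global ranking but absent from the cell-type one,
#' `lost` holds edges present in the cell-type ranking but absent from the
#' global one. When a ground truth is supplied, both sets are intersected
#' with its edges, restricting the comparison to validated regulation.
#'
#' @param celltypeRanking,globalRanking \linkS4class{EdgeRanking} objects
#'   computed with the same `k`.
#' @param truth optional \linkS4class{GroundTruthGRN}.
#' @return List of data.frames `gained` and `lost`.
#' @export
differentialEdges <- function(celltypeRanking, globalRanking, truth = NULL) {
  if (celltypeRanking@k != globalRanking@k)
    stop("rankings must use the same k (got ", celltypeRanking@k, " and ",
         globalRanking@k, ")")
  ctE <- edges(celltypeRanking)[, c("regulator", "target")]
  glE <- edges(globalRanking)[, c("regulator", "target")]
  gained <- glE[!(.edgeKeys(glE) %in% .edgeKeys(ctE)), , drop = FALSE]
  lost <- ctE[!(.edgeKeys(ctE) %in% .edgeKeys(glE)), , drop = FALSE]
  if (!is.null(truth)) {
    tk <- .edgeKeys(edges(truth))
    gained <- gained[.edgeKeys(gained) %in% tk, , drop = FALSE]
    lost <- lost[.edgeKeys(lost) %in% tk, , drop = FALSE]
  }
  rownames(gained) <- rownames(lost) <- NULL
  list(gained = gained, lost = lost)
}
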