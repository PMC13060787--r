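#' @include AllClasses.R AllGenerics.R grn.R
NULL

.restrictTruth <- function(truth, geneUniverse, restrict = TRUE) {
  e <- edges(truth)
  e <- e[e$regulator != e$target, , drop = FALSE]
  if (restrict)
    e <- e[e$regulator %in% geneUniverse & e$target %in% geneUniverse, ,
           drop = FALSE]
  e
}

#' Early F1 of a top-k edge ranking against a ground truth
#'
#' Precision is the fraction of returned edges found in the truth; recall
#' is the fraction of truth edges recovered, with the truth restricted (by
#' default) to gene pairs over the genes of the prediction's universe so a
#' method is not penalized for genes it never saw.
#'
#' @param predicted an \linkS4class{EdgeRanking}.
#' @param truth a \linkS4class{GroundTruthGRN}.
#' @param restrictUniverse restrict the truth to predicted-universe genes
#'   (default TRUE).
#' @return F1 in [0, 1]; 0 when precision and recall are both 0.
#' @export
earlyF1 <- function(predicted, truth, restrictUniverse = TRUE) {
  pe <- edges(predicted)
  if (!nrow(pe)) stop("prediction is empty")
  te <- .restrictTruth(truth, geneNames(predicted), restrictUniverse)
  if (!nrow(te))
    stop("no ground-truth edges remain within the prediction's gene universe")
  overlap <- sum(.edgeKeys(pe) %in% .edgeKeys(te))
  precision <- overlap / nrow(pe)
  recall <- overlap / nrow(te)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Upper-tail hypergeometric overlap p-value
#'
#' P(X >= overlap) for X hypergeometric: drawing `tfPredTargets` genes from
#' a universe of `universe` genes containing `tfTruthTargets` true targets.
#'
#' @param overlap observed number of shared targets.
#' @param tfTruthTargets number of true targets of the TF in the universe.
#' @param tfPredTargets number of predicted targets of the TF.
#' @param universe size of the gene universe.
#' @return The upper-tail p-value.
#' @export
hypergeometricPValue <- function(overlap, tfTruthTargets, tfPredTargets,
                                 universe) {
  if (overlap > min(tfTruthTargets, tfPredTargets) ||
      tfTruthTargets > universe || tfPredTargets > universe || overlap < 0)
    stop("inconsistent hypergeometric counts")
  stats::phyper(overlap - 1, m = tfTruthTargets, n = universe - tfTruthTargets,
                k = tfPredTargets, lower.tail = FALSE)
}

#' Count predictable transcription factors in a top-k ranking
#'
#' A regulator in the top-k predicted subgraph is predictable when its
#' predicted target set overlaps its ground-truth target set more than
#' expected by chance (upper-tail hypergeometric test over the prediction's
#' gene universe), after Benjamini-Hochberg correction across all tested
#' regulators, at the given FDR. Regulators with no truth targets in the
#' universe are untestable and excluded (reported in the table).
#'
#' @param predicted an \linkS4class{EdgeRanking}.
#' @param truth a \linkS4class{GroundTruthGRN}.
#' @param fdr FDR cutoff in (0, 1); default 0.05.
#' @return List with `count` (integer) and `table` (per-TF data.frame with
#'   overlap counts, p-values, BH-adjusted p-values and the predictable
#'   flag).
#' @export
predictableTFs <- function(predicted, truth, fdr = 0.05) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  universe <- geneNames(predicted)
  pe <- edges(predicted)
  te <- .restrictTruth(truth, universe)
  predTargets <- split(pe$target, pe$regulator)
  truthTargets <- split(te$target, te$regulator)
  tfs <- sort(names(predTargets))
  tab <- data.frame(
    tf = tfs,
    nPred = vapply(predTargets[tfs], function(x) length(unique(x)), 0L),
    nTruth = vapply(tfs, function(tf)
      length(unique(truthTargets[[tf]])), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  tab$overlap <- vapply(tfs, function(tf)
    length(intersect(unique(predTargets[[tf]]),
                     unique(truthTargets[[tf]]))), 0L)
  tab$testable <- tab$nTruth > 0L
  tab$pvalue <- NA_real_
  tested <- which(tab$testable)
  if (length(tested))
    tab$pvalue[tested] <- mapply(hypergeometricPValue,
                                 tab$overlap[tested], tab$nTruth[tested],
                                 tab$nPred[tested],
                                 MoreArgs = list(universe = length(universe)))
  tab$padj <- NA_real_
  if (length(tested))
    tab$padj[tested] <- stats::p.adjust(tab$pvalue[tested], method = "BH")
  tab$predictable <- !is.na(tab$padj) & tab$padj <= fdr
  list(count = sum(tab$predictable), table = tab)
}

#' Map lineages to cell types by composition
#'
#' A lineage is assigned to every cell type making up at least `threshold`
#' of its cells (default 25%); a lineage may map to several types or none.
#'
#' @param composition numeric lineages-by-types matrix (or data.frame) of
#'   cell-type fractions in [0, 1], with dimnames.
#' @param threshold inclusive fraction cutoff, default 0.25.
#' @return Named list: for each lineage, the character vector of assigned
#'   cell types (possibly empty).
#' @export
mapLineageToCellType <- function(composition, threshold = 0.25) {
  m <- as.matrix(composition)
  if (any(m < 0 | m > 1)) stop("fractions must lie in [0, 1]")
  out <- apply(m, 1L, function(r) colnames(m)[r >= threshold],
               simplify = FALSE)
  names(out) <- rownames(m)
  out
}

#' Average-rank summary of models over a benchmark grid
#'
#' Ranks models within every (ground truth, k) cell by descending score
#' (rank 1 = best; ties get the mean rank), then averages each model's
#' ranks over cells and reports the mean and median.
#'
#' @param scoreTable data.frame with columns `model`, `truth`, `k`,
#'   `score`; every model must be scored on every (truth, k) cell.
#' @return List with `summary` (data.frame model / meanRank / medianRank)
#'   and `perCell` (models-by-cells rank matrix).
#' @export
averageRanks <- function(scoreTable) {
  need <- c("model", "truth", "k", "score")
  if (!all(need %in% names(scoreTable)))
    stop("scoreTable needs columns ", paste(need, collapse = ", "))
  models <- sort(unique(scoreTable$model))
  cellId <- paste(scoreTable$truth, scoreTable$k, sep = " | ")
  cells <- sort(unique(cellId))
  full <- expand.grid(model = models, cell = cells, stringsAsFactors = FALSE)
  have <- paste(scoreTable$model, cellId, sep = " @ ")
  miss <- full[!(paste(full$model, full$cell, sep = " @ ") %in% have), ]
  if (nrow(miss))
    stop("missing score cells: ",
         paste(paste(miss$model, miss$cell, sep = " @ "), collapse = "; "))
  R <- matrix(NA_real_, length(models), length(cells),
              dimnames = list(models, cells))
  for (cl in cells) {
    sub <- scoreTable[cellId == cl, ]
    R[match(sub$model, models), cl] <- rank(-sub$score,
                                            ties.method = "average")
  }
  list(summary = data.frame(model = models,
                            meanRank = rowMeans(R),
                            medianRank = apply(R, 1L, stats::median),
                            row.names = NULL, stringsAsFactors = FALSE),
       perCell = R)
}

#' AUROC of GRN scores for a planted edge set
#'
#' Ranks all off-diagonal gene pairs by absolute score and computes the
#' area under the ROC curve for recovering the given true edges — the
#' probability that a random true edge outscores a random non-edge
#' (rank-sum estimator; ties contribute 1/2).
#'
#' @param grn a \linkS4class{GRNMatrix}.
#' @param trueEdges data.frame (or \linkS4class{GroundTruthGRN}) of
#'   regulator/target pairs.
#' @return AUROC in [0, 1].
#' @export
edgeRecoveryAUROC <- function(grn, trueEdges) {
  if (is(trueEdges, "GroundTruthGRN")) trueEdges <- edges(trueEdges)
  S <- scores(grn)
  gn <- rownames(S)
  off <- which(row(S) != col(S))
  keys <- paste(gn[row(S)[off]], gn[col(S)[off]], sep = "\r")
  pos <- keys %in% paste(trueEdges$regulator, trueEdges$target, sep = "\r")
  if (!any(pos) || all(pos)) stop("need both true edges and non-edges")
  s <- abs(S[off])
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}
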