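mkRanking <- function(edgeDf, k = nrow(edgeDf), genes) {
  edgeDf$score <- seq(1, 0.5, length.out = nrow(edgeDf))
  edgeDf$rank <- seq_len(nrow(edgeDf))
  new("EdgeRanking", edges = edgeDf, k = as.integer(k), geneNames = genes)
}

# an edge universe large enough for the worked example: 30 genes
.genes <- paste0("g", 1:30)
.allPairs <- expand.grid(regulator = .genes, target = .genes,
                         stringsAsFactors = FALSE)
.allPairs <- .allPairs[.allPairs$regulator != .allPairs$target, ]

test_that("early F1 reproduces the worked precision/recall example", {
  # top-100 prediction, 50 true, truth of size 200 within the universe:
  # P = 0.5, R = 0.25, F1 = 1/3
  truth <- GroundTruthGRN(.allPairs[1:200, ])
  pred <- mkRanking(rbind(.allPairs[1:50, ], .allPairs[201:250, ]),
                    k = 100, genes = .genes)
  expect_equal(earlyF1(pred, truth), 1 / 3)
  # a perfect top-k equal to the truth scores 1
  perfect <- mkRanking(.allPairs[1:200, ], k = 200, genes = .genes)
  expect_equal(earlyF1(perfect, truth), 1)
  # zero overlap scores 0
  none <- mkRanking(.allPairs[301:400, ], k = 100, genes = .genes)
  expect_equal(earlyF1(none, truth), 0)
  # F1 ignores the order of edges inside the top-k set
  shuffled <- mkRanking(rbind(.allPairs[201:250, ], .allPairs[50:1, ]),
                        k = 100, genes = .genes)
  expect_equal(earlyF1(shuffled, truth), 1 / 3)
  # truth entirely outside the universe is an error
  outside <- GroundTruthGRN(data.frame(regulator = "x1", target = "x2"))
  expect_error(earlyF1(pred, outside), "universe")
})

test_that("hypergeometric p-values equal exact tail summation", {
  for (universe in c(10L, 25L, 40L, 60L)) {
    for (m in c(2L, 5L, universe %/% 2L)) {
      for (k in c(1L, 4L, universe %/% 3L)) {
        for (ov in 0:min(m, k)) {
          expect_equal(hypergeometricPValue(ov, m, k, universe),
                       tailHyper(ov, m, k, universe), tolerance = 1e-12)
        }
      }
    }
  }
  # full tail at zero overlap
  expect_equal(hypergeometricPValue(0, 10, 5, 50), 1)
  # degenerate: everything overlaps everything
  expect_equal(hypergeometricPValue(10, 10, 10, 10), 1)
  # worked case, universe 50 / successes 10 / draws 5 / overlap 3
  expect_equal(hypergeometricPValue(3, 10, 5, 50), tailHyper(3, 10, 5, 50))
  # monotone decreasing in the overlap
  ps <- vapply(0:5, hypergeometricPValue, 0, tfTruthTargets = 10,
               tfPredTargets = 5, universe = 50)
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeometricPValue(6, 10, 5, 50), "inconsistent")
})

test_that("predictable TFs counts BH-significant target overlaps", {
  # three TFs predicted exactly at their truth targets: all predictable
  tf3 <- do.call(rbind, lapply(c("g1", "g2", "g3"), function(tf)
    data.frame(regulator = tf, target = paste0("g", 10:14),
               stringsAsFactors = FALSE)))
  truth3 <- GroundTruthGRN(tf3)
  res <- predictableTFs(mkRanking(tf3, genes = .genes), truth3)
  expect_equal(res$count, 3L)
  # no predicted TF with truth targets: count 0
  resNone <- predictableTFs(
    mkRanking(data.frame(regulator = "g20", target = "g21",
                         stringsAsFactors = FALSE), genes = .genes), truth3)
  expect_equal(resNone$count, 0L)
  expect_false(any(resNone$table$testable))
  # single TF, universe 30, 10 truth targets, 5 predicted, overlap 3:
  # predictable iff the exact tail probability clears the cutoff
  truth1 <- GroundTruthGRN(data.frame(regulator = "g1",
                                      target = paste0("g", 11:20)))
  pred1 <- mkRanking(data.frame(
    regulator = "g1", target = paste0("g", c(11, 12, 13, 25, 26)),
    stringsAsFactors = FALSE), genes = .genes)
  res1 <- predictableTFs(pred1, truth1, fdr = 0.05)
  pExact <- tailHyper(3, 10, 5, 30)
  expect_equal(res1$table$pvalue, pExact)
  expect_equal(res1$count, as.integer(pExact <= 0.05))
  # monotone non-decreasing in the FDR cutoff
  counts <- vapply(c(0.01, 0.05, 0.2, 0.5, 0.9), function(a)
    predictableTFs(pred1, truth1, fdr = a)$count, 0L)
  expect_true(all(diff(counts) >= 0L))
})

test_that("lineages map to every cell type above the composition threshold", {
  comp <- rbind(lin1 = c(HSC = 0.3, CMP = 0.2, MEP = 0.5),
                lin2 = c(HSC = 0.1, CMP = 0.15, MEP = 0.75),
                lin3 = c(HSC = 0.25, CMP = 0.375, MEP = 0.375))
  m <- mapLineageToCellType(comp)
  expect_setequal(m$lin1, c("HSC", "MEP"))
  expect_equal(m$lin2, "MEP")
  # the boundary is inclusive ("at least")
  expect_true("HSC" %in% m$lin3)
  # all below threshold: empty assignment
  expect_length(mapLineageToCellType(comp, threshold = 0.9)$lin1, 0L)
  expect_error(mapLineageToCellType(comp * 2), "\\[0, 1\\]")
})

test_that("average ranks follow dominance, ties and the rank-sum identity", {
  grid <- expand.grid(truth = c("t1", "t2"), k = c(100, 200),
                      stringsAsFactors = FALSE)
  tabA <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(model = c("A", "B"), truth = grid$truth[i], k = grid$k[i],
               score = c(0.9, 0.1))))
  r <- averageRanks(tabA)
  expect_equal(r$summary$meanRank[r$summary$model == "A"], 1)
  expect_equal(r$summary$medianRank[r$summary$model == "B"], 2)
  # exact tie shares the mean rank
  tie <- data.frame(model = c("A", "B"), truth = "t", k = 100,
                    score = c(0.5, 0.5))
  expect_equal(unname(averageRanks(tie)$perCell[, 1L]), c(1.5, 1.5))
  # per-cell ranks always sum to m(m+1)/2
  set.seed(77)
  tab3 <- do.call(rbind, lapply(1:30, function(i)
    data.frame(model = c("A", "B", "C"), truth = paste0("t", i), k = 100,
               score = runif(3))))
  pc <- averageRanks(tab3)$perCell
  expect_equal(unname(colSums(pc)), rep(6, ncol(pc)))
  # random permutations: symmetric mean rank near (m + 1) / 2
  set.seed(78)
  tabSym <- do.call(rbind, lapply(1:400, function(i)
    data.frame(model = c("A", "B", "C"), truth = paste0("t", i), k = 1,
               score = sample(3))))
  expect_lt(max(abs(averageRanks(tabSym)$summary$meanRank - 2)), 0.15)
  # missing cells are reported
  expect_error(averageRanks(tabA[-1L, ]), "missing")
})

test_that("edge-recovery AUROC matches a pairwise comparison oracle", {
  set.seed(91)
  S <- matrix(rnorm(36), 6, 6,
              dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  grn <- new("GRNMatrix", scores = S, cellType = NA_character_)
  truth <- data.frame(regulator = c("g1", "g2", "g3"),
                      target = c("g2", "g3", "g4"))
  # brute force: fraction of (positive, negative) pairs won (+ half ties)
  off <- which(row(S) != col(S))
  keys <- paste(rownames(S)[row(S)[off]], colnames(S)[col(S)[off]])
  pos <- keys %in% paste(truth$regulator, truth$target)
  s <- abs(S[off])
  wins <- 0
  for (i in which(pos)) for (j in which(!pos))
    wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(edgeRecoveryAUROC(grn, truth),
               wins / (sum(pos) * sum(!pos)))
})
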