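# Independent oracles, deliberately written as plain loops / naive
# iterations so they share no code with the package implementation.

# Naive unstabilized Sinkhorn (iterative proportional fitting) for
# entropic linear OT; used as the independent reference for solveFGW at
# alpha = 0.
naiveSinkhorn <- function(C, p, q, eps, iters = 20000L) {
  K <- exp(-C / eps)
  u <- rep(1, nrow(C))
  v <- rep(1, ncol(C))
  for (i in seq_len(iters)) {
    u <- p / as.vector(K %*% v)
    v <- q / as.vector(t(K) %*% u)
  }
  diag(u) %*% K %*% diag(v)
}

# Exhaustive enumeration of permutation couplings for uniform-marginal
# linear OT on n <= 4 points: returns the permutation minimizing <C, T>.
bestPermutation <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  best <- NULL
  bestCost <- Inf
  for (pm in perms(seq_len(n))) {
    cost <- sum(C[cbind(seq_len(n), pm)]) / n
    if (cost < bestCost) {
      bestCost <- cost
      best <- pm
    }
  }
  list(perm = best, cost = bestCost)
}

# Explicit quadruple-loop evaluation of the (optionally cell
# type-weighted) time-lagged correlation; the contract oracle for the
# matrix-product implementation.
loopLaggedCorrelation <- function(vblocks, couplings, L = NULL) {
  N <- length(vblocks)
  g <- ncol(vblocks[[1L]])
  C <- matrix(0, g, g)
  for (k in seq_len(N - 1L)) {
    T <- couplings[[k]]
    if (inherits(T, "TransitionMatrix")) T <- coupling(T)
    for (g1 in seq_len(g)) for (g2 in seq_len(g)) {
      acc <- 0
      for (cc in seq_len(nrow(vblocks[[k]]))) {
        for (cb in seq_len(nrow(vblocks[[k + 1L]]))) {
          w <- T[cc, cb]
          if (!is.null(L)) w <- w * L[[k]][cc] * L[[k + 1L]][cb]
          acc <- acc + vblocks[[k]][cc, g1] * vblocks[[k + 1L]][cb, g2] * w
        }
      }
      C[g1, g2] <- C[g1, g2] + acc
    }
  }
  C / (N - 1L)
}

# Exact upper-tail hypergeometric probability by summing the mass
# function over the tail, with choose().
tailHyper <- function(overlap, m, k, universe) {
  hi <- min(m, k)
  if (overlap > hi) return(0)
  sum(vapply(overlap:hi, function(x)
    choose(m, x) * choose(universe - m, k - x) / choose(universe, k), 0))
}

# Small builders -----------------------------------------------------------

toyDataset <- function(N = 3L, cells = 4L, genes = 5L, seed = 42L,
                       spacing = 1) {
  set.seed(seed)
  tp <- seq_len(N) * spacing
  blocksList <- lapply(seq_len(N), function(k) {
    m <- matrix(rnorm(cells * genes), cells, genes)
    dimnames(m) <- list(sprintf("t%d_c%d", k, seq_len(cells)),
                        paste0("g", seq_len(genes)))
    m
  })
  TimeStampedExpression(blocksList, tp)
}

# uniform diagonal coupling list matching a dataset with equal block sizes
identityCouplings <- function(dataset) {
  tp <- timepoints(dataset)
  bl <- blocks(dataset)
  lapply(seq_len(length(tp) - 1L), function(k) {
    n <- nrow(bl[[k]])
    T <- diag(n) / n
    dimnames(T) <- list(rownames(bl[[k]]), rownames(bl[[k + 1L]]))
    new("TransitionMatrix", coupling = T, p = rep(1 / n, n),
        q = rep(1 / n, n), pair = tp[k:(k + 1L)], objective = numeric(0),
        converged = TRUE)
  })
}

# a VelocityField directly from blocks (marked standardized so the
# correlation functions accept it)
fieldFromBlocks <- function(vblocks, standardized = TRUE) {
  N <- length(vblocks)
  schemes <- if (N == 2L) c("forward", "backward")
             else c("forward", rep("center", N - 2L), "backward")
  new("VelocityField", perBlock = vblocks, schemes = schemes,
      standardized = standardized, degenerateGenes = character(0))
}

# fused GW objective recomputed independently (plain loops) for small
# instances
loopFGWObjective <- function(T, D, Ssrc, Stgt, alpha, eps) {
  lin <- sum((1 - alpha) * T * D)
  quad <- 0
  n <- nrow(T); m <- ncol(T)
  for (c1 in seq_len(n)) for (d1 in seq_len(n))
    for (c2 in seq_len(m)) for (d2 in seq_len(m))
      quad <- quad + (Ssrc[c1, d1] - Stgt[c2, d2])^2 * T[c1, c2] * T[d1, d2]
  ent <- -sum(ifelse(T > 0, T * (log(T) - 1), 0))
  lin + alpha * quad - eps * ent
}
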