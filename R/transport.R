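#' @include AllClasses.R AllGenerics.R
NULL

## Stabilized Sinkhorn scaling for the entropic linear OT subproblem
##   min_{T in Pi(p,q)} <C, T> - eps * H(T).
## Scaling vectors act on a kernel with warm-startable dual potentials
## (f, g) absorbed, so the outer FGW loop restarts cheaply; overflowing
## scalings are periodically folded back into the potentials.
.logSinkhorn <- function(C, p, q, eps, maxIter = 5000L, tol = 1e-9,
                         f = NULL, g = NULL) {
  n <- nrow(C); m <- ncol(C)
  if (is.null(f)) f <- numeric(n)
  if (is.null(g)) g <- numeric(m)
  ## exponent shifted so the kernel's max is 1; the global constant is
  ## absorbed by the scaling vectors and cannot overflow
  kernel <- function() {
    E <- -sweep(sweep(C, 1L, f, "-"), 2L, g, "-") / eps
    exp(E - max(E))
  }
  K <- kernel()
  u <- rep(1, n); v <- rep(1, m)
  viol <- Inf
  tiny <- 1e-300
  windowViol <- Inf
  for (it in seq_len(maxIter)) {
    Kv <- as.vector(K %*% v)
    viol <- max(abs(u * Kv - p))
    if (viol < tol) break
    ## very sharp kernels can stall at a numerical floor above tol; stop
    ## once a full window of iterations brings essentially no progress
    if (it %% 500L == 0L) {
      if (viol > 0.95 * windowViol) break
      windowViol <- viol
    }
    u <- p / pmax(Kv, tiny)
    v <- q / pmax(as.vector(crossprod(K, u)), tiny)
    if (max(abs(log(u))) > 40 || max(abs(log(v))) > 40) {
      f <- f + eps * log(u); g <- g + eps * log(v)
      K <- kernel()
      u <- rep(1, n); v <- rep(1, m)
    }
  }
  T <- K * (u %*% t(v))
  list(T = T, f = f + eps * log(u), g = g + eps * log(v),
       viol = max(abs(rowSums(T) - p)))
}

## Round a near-feasible nonnegative matrix onto Pi(p, q): scale rows and
## columns down where they exceed their marginal, then distribute the
## remaining deficit as a rank-one correction. Exact up to float rounding;
## the perturbation is bounded by the input's marginal violation.
.roundToFeasible <- function(T, p, q) {
  rs <- rowSums(T)
  T <- T * pmin(p / pmax(rs, 1e-300), 1)
  cs <- colSums(T)
  T <- sweep(T, 2L, pmin(q / pmax(cs, 1e-300), 1), "*")
  errR <- p - rowSums(T)
  errC <- q - colSums(T)
  s <- sum(errR)
  if (s > 0) T <- T + (errR %*% t(errC)) / s
  T
}

#' Transport cost matrices between two expression blocks
#'
#' Computes the cross-timepoint cost matrix D (pairwise distances between
#' source and target cells in gene-expression space) and the within-block
#' structure matrices S_src, S_tgt (pairwise distances among cells of one
#' timepoint) that enter the fused Gromov-Wasserstein objective. With
#' `reduceDim` set, both blocks are first projected onto the leading
#' principal components of their joint stack.
#'
#' @param Xsrc,Xtgt cells-by-genes matrices sharing the gene axis.
#' @param config a \linkS4class{TransportConfig}; `costMetric` selects
#'   squared-Euclidean (default) or Euclidean distances.
#' @return `list(D, Ssrc, Stgt)`; S matrices are symmetric with zero
#'   diagonal, all entries nonnegative.
#' @export
computeCosts <- function(Xsrc, Xtgt, config = transportConfig()) {
  if (nrow(Xsrc) == 0L || nrow(Xtgt) == 0L) stop("empty expression block")
  if (ncol(Xsrc) != ncol(Xtgt)) stop("blocks must share the gene axis")
  if (!is.na(config@reduceDim)) {
    joint <- rbind(Xsrc, Xtgt)
    d <- min(config@reduceDim, ncol(joint), nrow(joint) - 1L)
    pc <- stats::prcomp(joint, center = TRUE, rank. = d)
    Xsrc <- pc$x[seq_len(nrow(Xsrc)), , drop = FALSE]
    Xtgt <- pc$x[-seq_len(nrow(Xsrc)), , drop = FALSE]
  }
  sq <- function(A, B) {
    D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    pmax(D, 0)
  }
  D <- sq(Xsrc, Xtgt)
  Ssrc <- sq(Xsrc, Xsrc); Stgt <- sq(Xtgt, Xtgt)
  Ssrc <- (Ssrc + t(Ssrc)) / 2; Stgt <- (Stgt + t(Stgt)) / 2
  diag(Ssrc) <- 0; diag(Stgt) <- 0
  if (config@costMetric == "euclidean") {
    D <- sqrt(D); Ssrc <- sqrt(Ssrc); Stgt <- sqrt(Stgt)
  }
  list(D = D, Ssrc = Ssrc, Stgt = Stgt)
}

.fgwObjective <- function(T, D, Ssrc, Stgt, alpha, eps, constC) {
  lin <- sum(T * D)
  quad <- if (alpha > 0) sum(T * (constC - 2 * Ssrc %*% T %*% t(Stgt))) else 0
  Tl <- T[T > 0]
  ent <- -sum(Tl * (log(Tl) - 1))
  (1 - alpha) * lin + alpha * quad - eps * ent
}

#' Solve the entropic fused Gromov-Wasserstein problem
#'
#' Finds the coupling T in Pi(p, q) minimizing
#' \deqn{(1-\alpha)\langle T, D\rangle +
#'   \alpha \sum_{c,d,\bar c,\bar d} (S^{src}_{c,d} - S^{tgt}_{\bar c,\bar d})^2
#'   T_{c,\bar c} T_{d,\bar d} - \varepsilon H(T)}
#' by projected (mirror-descent) iterations: the quadratic term is
#' linearized at the current coupling and the resulting entropic linear OT
#' problem is solved by Sinkhorn scaling. Initialization is the independent
#' coupling T0 = p q^T, making the solver deterministic. At `alpha = 0` a
#' single Sinkhorn projection yields the entropic Wasserstein coupling
#' exactly.
#'
#' @param D cross cost matrix (c_src x c_tgt).
#' @param Ssrc,Stgt within-block structure matrices.
#' @param p,q source/target marginal distributions (default uniform).
#' @param config a \linkS4class{TransportConfig}. `epsilon = NA` auto-scales
#'   to 0.05 x mean(D).
#' @param pair the two timepoint stamps being coupled (metadata).
#' @return A \linkS4class{TransitionMatrix} with the objective trace
#'   attached.
#' @export
solveFGW <- function(D, Ssrc, Stgt, p = NULL, q = NULL,
                     config = transportConfig(), pair = c(NA_real_, NA_real_)) {
  if (any(!is.finite(D)) || any(!is.finite(Ssrc)) || any(!is.finite(Stgt)))
    stop("non-finite entries in cost matrices")
  n <- nrow(D); m <- ncol(D)
  if (is.null(p)) p <- rep(1 / n, n)
  if (is.null(q)) q <- rep(1 / m, m)
  if (length(p) != n || length(q) != m) stop("marginal lengths mismatch costs")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8 || any(p < 0) ||
      any(q < 0))
    stop("p and q must be probability distributions")
  alpha <- config@alpha
  eps <- if (is.na(config@epsilon)) 0.05 * mean(D) else config@epsilon
  if (eps <= 0) stop("epsilon must resolve to a positive value")
  T <- p %*% t(q)
  constC <- if (alpha > 0)
    (Ssrc^2 %*% p) %*% t(rep(1, m)) + rep(1, n) %*% t(Stgt^2 %*% q)
  else matrix(0, n, m)
  obj <- numeric(0)
  f <- g <- NULL
  converged <- FALSE
  finalTol <- config@tol / 10
  delta <- Inf
  gradAt <- function(T) {
    if (alpha > 0)
      (1 - alpha) * D + 2 * alpha * (constC - 2 * Ssrc %*% T %*% t(Stgt))
    else D
  }
  objAt <- function(T) .fgwObjective(T, D, Ssrc, Stgt, alpha, eps, constC)
  objCur <- objAt(T)
  for (it in seq_len(config@maxIter)) {
    ## inner projections are solved loosely while the outer iterate is far
    ## from its fixed point, tightly near it
    innerTol <- max(finalTol, min(1e-4, delta / 10))
    sk <- .logSinkhorn(gradAt(T), p, q, eps, tol = innerTol, f = f, g = g)
    f <- sk$f; g <- sk$g
    if (alpha == 0) {
      ## the subproblem is the whole problem: one projection solves it
      T <- sk$T
      obj <- c(obj, objAt(T))
      converged <- TRUE
      break
    }
    ## the GW quadratic is indefinite, so the mirror step is damped until
    ## the objective decreases; no admissible damping means stationarity
    accepted <- FALSE
    for (step in c(1, 0.5, 0.25, 0.1)) {
      Tc <- (1 - step) * T + step * sk$T
      objNew <- objAt(Tc)
      if (objNew <= objCur + 1e-12 * (1 + abs(objCur))) {
        delta <- sum(abs(Tc - T))
        T <- Tc
        objCur <- objNew
        obj <- c(obj, objNew)
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }
    if (delta < config@tol) { converged <- TRUE; break }
  }
  ## final polish and rounding so the returned coupling lies in Pi(p, q);
  ## the recorded objective trace refers to the pre-polish iterates
  sk <- .logSinkhorn(gradAt(T), p, q, eps, maxIter = 20000L,
                     tol = finalTol, f = f, g = g)
  polished <- .roundToFeasible(sk$T, p, q)
  if (alpha == 0 || objAt(polished) <= objCur + abs(objCur) * 1e-6)
    T <- polished
  else
    T <- .roundToFeasible(T, p, q)
  viol <- max(max(abs(rowSums(T) - p)), max(abs(colSums(T) - q)))
  if (!converged)
    warning(sprintf(
      "FGW solver did not fully converge in %d iterations (marginal violation %.3g)",
      config@maxIter, viol))
  dimnames(T) <- dimnames(D)
  new("TransitionMatrix", coupling = T, p = p, q = q,
      pair = as.numeric(pair), objective = obj, converged = converged)
}

#' Barycentric projection of source cells onto the next timepoint
#'
#' Predicts the descendant expression of every source cell as the
#' coupling-weighted (row-normalized) average of target-timepoint cells.
#'
#' @param tm a \linkS4class{TransitionMatrix} (or bare coupling matrix).
#' @param Xtgt target-block expression, cells-by-genes.
#' @return Matrix of shape (source cells x genes).
#' @export
barycentricProject <- function(tm, Xtgt) {
  T <- if (is(tm, "TransitionMatrix")) coupling(tm) else tm
  if (ncol(T) != nrow(Xtgt)) stop("coupling/target shape mismatch")
  rs <- rowSums(T)
  if (any(rs <= 0))
    stop("unmatched source cell(s) with zero coupling mass: row ",
         paste(which(rs <= 0), collapse = ", "))
  out <- (T %*% Xtgt) / rs
  rownames(out) <- rownames(T)
  out
}

#' Couple all consecutive timepoint pairs of a dataset
#'
#' Runs [computeCosts()] and [solveFGW()] for every pair (t_k, t_{k+1})
#' with uniform marginals over the cells of each timepoint.
#'
#' @param dataset a \linkS4class{TimeStampedExpression}.
#' @param config a \linkS4class{TransportConfig}.
#' @return List of N-1 \linkS4class{TransitionMatrix} objects in time order.
#' @export
computeAllTransitions <- function(dataset, config = transportConfig()) {
  tp <- timepoints(dataset)
  bl <- blocks(dataset)
  lapply(seq_len(length(tp) - 1L), function(k) {
    cst <- computeCosts(bl[[k]], bl[[k + 1L]], config)
    tm <- solveFGW(cst$D, cst$Ssrc, cst$Stgt, config = config,
                   pair = tp[k:(k + 1L)])
    dimnames(tm@coupling) <- list(rownames(bl[[k]]), rownames(bl[[k + 1L]]))
    tm
  })
}
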