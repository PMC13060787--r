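#' @include AllClasses.R AllGenerics.R transport.R
NULL

#' Forward finite-difference gene velocity
#'
#' Rate of change of expression from a cell's current state towards its
#' barycentrically projected descendant at the next timepoint:
#' (projection - x) / dt.
#'
#' @param X expression block at t_k, cells-by-genes.
#' @param projection barycentric image of the same cells at t_{k+1}.
#' @param dt positive stamp difference t_{k+1} - t_k.
#' @return Velocity matrix of the same shape.
#' @export
forwardVelocity <- function(X, projection, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(dim(X) == dim(projection))) stop("shape mismatch")
  (projection - X) / dt
}

#' Backward finite-difference gene velocity
#'
#' Rate of change from a cell's backward projection (its coupling-weighted
#' ancestor at t_{k-1}, via the transposed coupling) to its current state:
#' (x - projection_back) / dt. Oriented so a gene whose expression rose
#' since t_{k-1} has positive velocity, consistent with the forward scheme.
#'
#' @param X expression block at t_k.
#' @param projectionBack ancestor projection of the same cells at t_{k-1}.
#' @param dt positive stamp difference t_k - t_{k-1}.
#' @return Velocity matrix of the same shape.
#' @export
backwardVelocity <- function(X, projectionBack, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(dim(X) == dim(projectionBack))) stop("shape mismatch")
  (X - projectionBack) / dt
}

#' Centred gene velocity at an interior timepoint
#'
#' Convex combination of forward and backward velocities with weights
#' (t_k - t_{k-1}) / (t_{k+1} - t_{k-1}) on the forward part and
#' (t_{k+1} - t_k) / (t_{k+1} - t_{k-1}) on the backward part; under equal
#' spacing this is their arithmetic mean.
#'
#' @param vFwd,vBwd forward/backward velocity blocks at t_k.
#' @param tPrev,tK,tNext the three surrounding stamps, strictly increasing.
#' @return Velocity matrix of the same shape.
#' @export
centerVelocity <- function(vFwd, vBwd, tPrev, tK, tNext) {
  if (!(tPrev < tK && tK < tNext)) stop("timepoint stamps must be increasing")
  wF <- (tK - tPrev) / (tNext - tPrev)
  wB <- (tNext - tK) / (tNext - tPrev)
  wF * vFwd + wB * vBwd
}

#' Assemble the per-cell velocity field of a dataset
#'
#' Applies the boundary rule: the first timepoint gets the forward scheme,
#' the last the backward scheme, interior timepoints the centred scheme.
#'
#' @param dataset a \linkS4class{TimeStampedExpression}.
#' @param transitions list of N-1 \linkS4class{TransitionMatrix} objects
#'   covering every consecutive pair, as from [computeAllTransitions()].
#' @return An unstandardized \linkS4class{VelocityField}.
#' @export
assembleVelocities <- function(dataset, transitions) {
  tp <- timepoints(dataset)
  bl <- blocks(dataset)
  N <- length(tp)
  if (length(transitions) != N - 1L)
    stop("need one coupling per consecutive pair (", N - 1L, ")")
  for (k in seq_len(N - 1L)) {
    pr <- transitions[[k]]@pair
    if (!all(is.na(pr)) && !isTRUE(all.equal(pr, tp[k:(k + 1L)])))
      stop(sprintf("missing coupling for pair (%g, %g)", tp[k], tp[k + 1L]))
  }
  fwd <- function(k) {
    proj <- barycentricProject(transitions[[k]], bl[[k + 1L]])
    forwardVelocity(bl[[k]], proj, tp[k + 1L] - tp[k])
  }
  bwd <- function(k) {
    projBack <- barycentricProject(t(coupling(transitions[[k - 1L]])),
                                   bl[[k - 1L]])
    backwardVelocity(bl[[k]], projBack, tp[k] - tp[k - 1L])
  }
  perBlock <- vector("list", N)
  schemes <- character(N)
  perBlock[[1L]] <- fwd(1L); schemes[1L] <- "forward"
  perBlock[[N]] <- bwd(N); schemes[N] <- "backward"
  if (N > 2L) for (k in 2:(N - 1L)) {
    perBlock[[k]] <- centerVelocity(fwd(k), bwd(k),
                                    tp[k - 1L], tp[k], tp[k + 1L])
    schemes[k] <- "center"
  }
  new("VelocityField", perBlock = perBlock, schemes = schemes,
      standardized = FALSE, degenerateGenes = character(0))
}

#' Standardize a velocity field to unit per-gene spread
#'
#' Divides each gene's velocities by their pooled population standard
#' deviation over all cells of all timepoints (optionally after subtracting
#' the pooled mean), so genes with different expression scales contribute
#' comparably to the lagged correlation. Genes with pooled sd below 1e-12
#' are zeroed and recorded as degenerate.
#'
#' Centering is off by default: a gene driven in only one cell type has a
#' nonzero mean velocity there and near-zero velocity elsewhere, and
#' subtracting the pooled mean would hand every other cell type a constant
#' offset that leaks the signal into their type-specific networks.
#'
#' @param field an unstandardized \linkS4class{VelocityField}.
#' @param center subtract the pooled per-gene mean first (default FALSE).
#' @return A standardized \linkS4class{VelocityField}.
#' @export
standardizeVelocities <- function(field, center = FALSE) {
  if (field@standardized) stop("velocity field is already standardized")
  all <- do.call(rbind, field@perBlock)
  mu <- if (center) colMeans(all) else rep(0, ncol(all))
  ## degeneracy is judged on variation about the pooled mean either way:
  ## a constant velocity carries no co-variation signal
  sdAboutMean <- sqrt(colMeans(sweep(all, 2L, colMeans(all), "-")^2))
  degen <- sdAboutMean < 1e-12
  divisor <- sqrt(colMeans(sweep(all, 2L, mu, "-")^2))
  scale <- ifelse(degen, 0, 1 / pmax(divisor, 1e-300))
  perBlock <- lapply(field@perBlock, function(b)
    sweep(sweep(b, 2L, mu, "-"), 2L, scale, "*"))
  gn <- colnames(all)
  new("VelocityField", perBlock = perBlock, schemes = field@schemes,
      standardized = TRUE,
      degenerateGenes = if (is.null(gn)) as.character(which(degen))
                        else gn[degen])
}
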