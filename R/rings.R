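# Cyclic ring assembly: propagation of an asymmetric unit by a junction
# transform, with the three ring filters (chain length, internal clashing,
# closure error).

#' Ring closure error
#'
#' Deviation of the n-fold composition of the propagation transform from the
#' identity, measured as the RMSD between the probe's CA atoms and the same
#' atoms after applying the transform n times. Zero if and only if the
#' n-fold composition is the identity on the probe span; a pure axial
#' offset delta accumulates to exactly n * delta.
#'
#' @param transform per-step propagation \linkS4class{Transform}
#' @param n symmetry order (>= 2)
#' @param probe \linkS4class{BackboneModel} whose CA atoms measure the error
#' @return closure error in Angstrom
#' @examples
#' h <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 14))
#' ringClosureError(axisRotation(c(0, 0, 1), 120), 3, h)  # 0
#' @export
ringClosureError <- function(transform, n, probe) {
  stopifnot(n >= 2)
  P <- if (is.matrix(probe)) probe else caCoords(probe)
  if (!nrow(P)) stop("degenerate probe: no CA atoms")
  Tn <- transformPower(transform, n)
  rmsdRaw(P, applyTransform(P, Tn))
}

#' Ring filter thresholds
#'
#' @param maxCloseErr maximum closure error, Angstrom
#' @param maxClashes maximum inter-copy backbone heavy-atom pairs closer
#'   than \code{clashDist}
#' @param maxChainLen maximum residues in any chain of the asymmetric unit
#' @param clashDist clash distance, Angstrom
#' @return named list
#' @export
ringThresholds <- function(maxCloseErr = 1, maxClashes = 0,
                           maxChainLen = Inf, clashDist = 3.0) {
  list(maxCloseErr = maxCloseErr, maxClashes = maxClashes,
       maxChainLen = maxChainLen, clashDist = clashDist)
}

#' Build a cyclic ring from an asymmetric unit
#'
#' Propagates \code{n} copies of the unit by the junction transform,
#' computes the closure error on the unit's CA atoms, counts inter-copy
#' backbone clashes (the score0 analogue) and the per-chain lengths, and
#' accepts the ring only if every threshold is met. A transform whose
#' n-fold composition misses the identity shows up as a large closure error
#' and produces a rejection record, not an exception.
#'
#' @param unit asymmetric-unit \linkS4class{BackboneModel}
#' @param transform per-step propagation \linkS4class{Transform} (compose
#'   junction transforms for multi-junction units)
#' @param n symmetry order (C2-C5 in the design protocols)
#' @param thresholds from \code{\link{ringThresholds}}
#' @return a \linkS4class{RingSolution}
#' @export
buildRing <- function(unit, transform, n, thresholds = ringThresholds()) {
  n <- as.integer(n)
  stopifnot(n >= 2)
  closeErr <- ringClosureError(transform, n, unit)
  unitChains <- chainIds(unit)
  copies <- vector("list", n)
  chainCursor <- 0L
  allAtoms <- list()
  for (k in seq_len(n)) {
    m <- applyTransform(unit, transformPower(transform, k - 1L))
    a <- atoms(m)
    relabel <- setNames(LETTERS[chainCursor + seq_along(unitChains)],
                        unitChains)
    if (chainCursor + length(unitChains) > 26)
      relabel <- setNames(paste0(unitChains, k), unitChains)
    a$chain <- unname(relabel[a$chain])
    chainCursor <- chainCursor + length(unitChains)
    copies[[k]] <- a
    allAtoms[[k]] <- as.matrix(a[, c("x", "y", "z")])
  }
  clashes <- 0L
  cd2 <- thresholds$clashDist^2
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    P <- allAtoms[[i]]
    Q <- allAtoms[[j]]
    d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)
    clashes <- clashes + sum(d2 < cd2)
  }
  ring <- new("BackboneModel", atoms = do.call(rbind, copies),
              metadata = list(generator = "buildRing", n = n))
  lens <- chainLengths(unit)
  reasons <- character()
  if (closeErr > thresholds$maxCloseErr) reasons <- c(reasons, "close_err")
  if (clashes > thresholds$maxClashes) reasons <- c(reasons, "score0")
  if (any(lens > thresholds$maxChainLen)) reasons <- c(reasons, "chain_len")
  new("RingSolution", unit = unit, transform = transform, n = n,
      closeErr = closeErr, clashCount = as.integer(clashes),
      chainLen = as.integer(lens), ring = ring,
      accepted = !length(reasons), reasons = reasons)
}

#' Score table for ring solutions
#'
#' One row per solution with the three filter fields of the ring protocol:
#' chain_len, score0 and close_err.
#'
#' @param solutions list of \linkS4class{RingSolution}
#' @return data.frame
#' @export
ringScoreTable <- function(solutions) {
  do.call(rbind, lapply(solutions, function(s) data.frame(
    symmetry = paste0("C", s@n),
    chain_len = sum(s@chainLen),
    score0 = s@clashCount,
    close_err = s@closeErr,
    accepted = s@accepted, stringsAsFactors = FALSE)))
}
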