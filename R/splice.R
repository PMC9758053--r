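# Rigid helical splice fusion between building blocks.
#
# Two blocks are joined by superposing overlapping helical residue windows
# at their termini; the fused model keeps the upstream block up to the
# overlap and continues with the (transformed) downstream block, so the
# overlap region takes the acceptor's geometry.

#' Describe a splice site on a building block
#'
#' @param chain chain carrying the terminus
#' @param terminus "N" or "C"
#' @param window residue indices available for splicing (must be helical in
#'   the block model)
#' @return list describing the site
#' @export
spliceSite <- function(chain, terminus = c("C", "N"), window) {
  terminus <- match.arg(terminus)
  stopifnot(length(window) >= 1)
  list(chain = chain, terminus = terminus, window = sort(window))
}

# Backbone coordinates (N, CA, C) of a run of residues, for overlap fitting.
windowCoords <- function(model, chain, resis) {
  a <- atoms(model)
  a <- a[a$chain == chain & a$resi %in% resis &
           a$elety %in% c("N", "CA", "C"), ]
  a <- a[order(a$resi, match(a$elety, c("N", "CA", "C"))), ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Enumerate splice solutions between two blocks
#'
#' Joins the C-terminal site of \code{blockA} to the N-terminal site of
#' \code{blockB}. For every allowed deletion pair (residues removed from
#' each block's terminus) and every overlap length at least
#' \code{minOverlap}, the overlapping windows are superposed on their
#' backbone (N, CA, C) atoms; solutions are returned sorted by overlap RMSD.
#' Deletion limits mirror the fusion protocol: up to one heptad (7 residues)
#' on a heterotrimer block, up to one full repeat on a repeat-protein block.
#'
#' @param blockA upstream \linkS4class{BackboneModel} (donates its N side)
#' @param siteA C-terminal \code{\link{spliceSite}} on blockA
#' @param blockB downstream \linkS4class{BackboneModel}
#' @param siteB N-terminal \code{\link{spliceSite}} on blockB
#' @param maxDeleteA,maxDeleteB maximum residues deletable from each
#'   terminus
#' @param minOverlap minimum overlap length, residues
#' @param maxSolutions keep at most this many solutions
#' @return list of junction solutions sorted by RMSD ascending; each has
#'   rmsd, deleteA, deleteB, overlap, transform (applied to blockB),
#'   model (the fused single chain), junction (residue index in the fused
#'   chain where blockB geometry begins)
#' @export
enumerateSplices <- function(blockA, siteA, blockB, siteB,
                             maxDeleteA = 7, maxDeleteB = 7,
                             minOverlap = 8, maxSolutions = 50) {
  if (siteA$terminus != "C" || siteB$terminus != "N")
    stop("splicing requires a C-terminal site on blockA and an N-terminal ",
         "site on blockB")
  aResis <- sort(unique(atoms(blockA)$resi[atoms(blockA)$chain == siteA$chain]))
  bResis <- sort(unique(atoms(blockB)$resi[atoms(blockB)$chain == siteB$chain]))
  sols <- list()
  for (dA in 0:maxDeleteA) for (dB in 0:maxDeleteB) {
    aKeep <- utils::head(aResis, length(aResis) - dA)
    bKeep <- utils::tail(bResis, length(bResis) - dB)
    winA <- intersect(siteA$window, aKeep)
    winB <- intersect(siteB$window, bKeep)
    ov <- min(length(winA), length(winB))
    if (ov < minOverlap) next
    ovA <- utils::tail(aKeep, ov)      # last ov residues of trimmed A
    ovB <- utils::head(bKeep, ov)      # first ov residues of trimmed B
    if (!all(ovA %in% siteA$window) || !all(ovB %in% siteB$window)) next
    P <- windowCoords(blockB, siteB$chain, ovB)
    Q <- windowCoords(blockA, siteA$chain, ovA)
    if (nrow(P) != nrow(Q) || nrow(P) < 9) next
    fit <- superpose(P, Q)
    # fused chain: A before the overlap, then transformed B from the overlap
    aPart <- atoms(blockA)
    aPart <- aPart[aPart$chain == siteA$chain &
                     aPart$resi %in% setdiff(aKeep, ovA), ]
    bMoved <- applyTransform(blockB, fit$transform)
    bPart <- atoms(bMoved)
    bPart <- bPart[bPart$chain == siteB$chain & bPart$resi %in% bKeep, ]
    bPart$resi <- bPart$resi - min(bPart$resi) + 1L +
      length(setdiff(aKeep, ovA))
    bPart$chain <- siteA$chain
    fused <- new("BackboneModel", atoms = rbind(aPart, bPart),
                 metadata = list(generator = "enumerateSplices"))
    sols[[length(sols) + 1L]] <- list(
      rmsd = fit$rmsd, deleteA = dA, deleteB = dB, overlap = ov,
      transform = fit$transform, model = fused,
      junction = length(setdiff(aKeep, ovA)) + 1L)
  }
  if (!length(sols))
    stop("no overlap of at least ", minOverlap,
         " residues within the deletion limits")
  sols <- sols[order(vapply(sols, `[[`, numeric(1), "rmsd"))]
  utils::head(sols, maxSolutions)
}

#' Flag residues near a splice junction for redesign
#'
#' Residues of a fused model whose CA lies within \code{radius} of the
#' junction residue's CA gained or lost packing contacts during fusion and
#' should be re-assigned by the layer-sequence rules.
#'
#' @param model fused \linkS4class{BackboneModel}
#' @param junction residue index where the downstream block begins
#' @param chain chain of the fused model
#' @param radius Angstrom
#' @return integer vector of residue indices
#' @export
junctionRedesignSet <- function(model, junction, chain = chainIds(model)[1],
                                radius = 5) {
  ca <- caCoords(model, chain = chain)
  key <- paste0(chain, junction)
  if (!key %in% rownames(ca)) stop("junction residue not in model")
  ref <- ca[key, ]
  d <- sqrt(rowSums(sweep(ca, 2, ref)^2))
  sort(as.integer(sub(paste0("^", chain), "", rownames(ca)[d <= radius])))
}
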