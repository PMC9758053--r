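# Backbone parameter grids and the staged six-helix search.
#
# Grids are generated by integer index times step (no floating-point drift),
# inclusive of both endpoints, and enumerated in a fixed lexicographic order
# so a search is resumable by index.

#' Inclusive arithmetic grid
#'
#' \code{gridSeq(min, max, step)} returns \code{min + step * (0:k)} with both
#' endpoints included; values come from integer multiples of the step so
#' repeated enumeration is drift-free.
#'
#' @param from,to range endpoints (inclusive)
#' @param by step (> 0)
#' @return numeric vector
#' @examples
#' gridSeq(-100, 100, 20)  # 11 helical-phase values
#' gridSeq(6.5, 7.5, 0.25) # 5 supercoil radii
#' @export
gridSeq <- function(from, to, by) {
  stopifnot(by > 0, from <= to)
  k <- floor((to - from) / by + 1e-9)
  from + by * (0:k)
}

#' Parameter grid over the helices of a bundle
#'
#' Defines, per helix, the sampled values of the helical phase
#' \code{dphi1}, the supercoil radius \code{R} and the axial offset
#' \code{zOff}; the supercoil phase of each helix is fixed on the design
#' lattice. Enumeration order is lexicographic with helix 1 slowest and,
#' within a helix, dphi1 then R then zOff (zOff fastest).
#'
#' @slot phases supercoil phase per helix, degrees
#' @slot dims per-helix list of named value vectors (dphi1, R, zOff)
#' @slot length helix length, residues
#' @slot omega0,omega1 twists, degrees per residue
#' @slot inverted logical per helix
#' @export
setClass("ParamGrid",
  representation(phases = "numeric", dims = "list", length = "integer",
                 omega0 = "numeric", omega1 = "numeric",
                 inverted = "logical"))

setValidity("ParamGrid", function(object) {
  if (length(object@dims) != length(object@phases))
    return("one dims entry per helix required")
  for (d in object@dims) {
    if (!all(c("dphi1", "R", "zOff") %in% names(d)))
      return("each dims entry needs dphi1, R, zOff")
    if (!all(lengths(d) >= 1)) return("empty grid dimension")
  }
  TRUE
})

setMethod("show", "ParamGrid", function(object) {
  cat(sprintf("ParamGrid: %d helices, %s specs, helix length %d\n",
              length(object@phases), format(gridSize(object), big.mark = ","),
              object@length))
  for (i in seq_along(object@phases))
    cat(sprintf("  phase %5.1f: %d x %d x %d (dphi1 x R x zOff)%s\n",
                object@phases[i], length(object@dims[[i]]$dphi1),
                length(object@dims[[i]]$R), length(object@dims[[i]]$zOff),
                if (object@inverted[i]) " inv" else ""))
})

#' Construct a parameter grid
#'
#' @param phases supercoil phases, degrees (design lattice values)
#' @param dphi1 helical-phase values, or list of vectors (one per helix)
#' @param R supercoil-radius values, or list per helix
#' @param zOff axial-offset values for helices 2..n, or list per helix;
#'   helix 1 is always fixed at zOff = 0
#' @param length helix length in residues
#' @param omega0,omega1 twists, degrees per residue
#' @param inverted logical per helix (recycled)
#' @return a \linkS4class{ParamGrid}
#' @export
paramGrid <- function(phases, dphi1, R, zOff, length = 77,
                      omega0 = -2.85, omega1 = 102.85, inverted = FALSE) {
  nh <- base::length(phases)
  rep_dim <- function(v) if (is.list(v)) v else rep(list(v), nh)
  dphi1 <- rep_dim(dphi1)
  R <- rep_dim(R)
  zOff <- rep_dim(zOff)
  zOff[[1]] <- 0 # first helix anchors the axial frame
  dims <- lapply(seq_len(nh), function(i)
    list(dphi1 = dphi1[[i]], R = R[[i]], zOff = zOff[[i]]))
  new("ParamGrid", phases = as.numeric(phases), dims = dims,
      length = as.integer(length), omega0 = omega0, omega1 = omega1,
      inverted = rep_len(inverted, nh))
}

#' The three-helix coiled-coil sampling grid
#'
#' Default ranges are the published coiled-coil search: helical phase -100 to
#' 100 degrees in 20 degree steps, supercoil radius 6.5 to 7.5 Angstrom in
#' 0.25 Angstrom steps, axial offsets \{-1.5, 0, 1.5\} Angstrom for helices 2
#' and 3, 77-residue helices at supercoil phases 0/120/240.
#'
#' @param dphi1,R,zOff value vectors (see \code{\link{paramGrid}})
#' @param length helix length
#' @param antiparallel invert the third helix (phase 240)
#' @return a \linkS4class{ParamGrid}
#' @examples
#' gridSize(coiledCoilGrid())  # 1,497,375
#' @export
coiledCoilGrid <- function(dphi1 = gridSeq(-100, 100, 20),
                           R = gridSeq(6.5, 7.5, 0.25),
                           zOff = c(-1.5, 0, 1.5),
                           length = 77, antiparallel = FALSE) {
  paramGrid(phases = c(0, 120, 240), dphi1 = dphi1, R = R, zOff = zOff,
            length = length,
            inverted = c(FALSE, FALSE, antiparallel))
}

#' Stage-1 grid of the stepwise six-helix search
#'
#' Three inner helices (phases 0/120/240, R 6.5-7.25 step 0.375) plus one
#' outer helix at phase 60 (R 12.25-13.25 step 0.5); helical phase -100..100
#' step 20 everywhere; zOff \{-1.5, 0, 1.5\} for helices 2-4; 35-residue
#' helices.
#'
#' @param antiparallel invert the third (inner, phase 240) helix
#' @return a \linkS4class{ParamGrid}
#' @export
bundleStage1Grid <- function(antiparallel = FALSE) {
  paramGrid(phases = c(0, 120, 240, 60),
            dphi1 = gridSeq(-100, 100, 20),
            R = list(gridSeq(6.5, 7.25, 0.375), gridSeq(6.5, 7.25, 0.375),
                     gridSeq(6.5, 7.25, 0.375), gridSeq(12.25, 13.25, 0.5)),
            zOff = c(-1.5, 0, 1.5),
            length = 35,
            inverted = c(FALSE, FALSE, antiparallel, FALSE))
}

#' Outer-helix grid for stages 2 and 3
#'
#' The fifth (phase 180) and sixth (phase 300) helices are sampled across the
#' same ranges as the fourth helix.
#'
#' @param phase 180 (stage 2) or 300 (stage 3)
#' @param inverted invert the new helix (the sixth helix, for antiparallel
#'   bundles)
#' @return named list of value vectors (dphi1, R, zOff) plus phase/flags
#' @export
outerHelixGrid <- function(phase, inverted = FALSE) {
  list(phase = phase, dphi1 = gridSeq(-100, 100, 20),
       R = gridSeq(12.25, 13.25, 0.5), zOff = c(-1.5, 0, 1.5),
       inverted = inverted)
}

#' Number of specs in a grid
#'
#' Closed-form product of the per-dimension counts.
#'
#' @param grid a \linkS4class{ParamGrid}
#' @return numeric count
#' @export
gridSize <- function(grid) {
  prod(vapply(grid@dims, function(d) prod(lengths(d)), numeric(1)))
}

#' The i-th BundleSpec of a grid
#'
#' Mixed-radix decoding of the 1-based lexicographic index (helix 1 slowest;
#' within a helix dphi1, then R, then zOff).
#'
#' @param grid a \linkS4class{ParamGrid}
#' @param i 1-based index in [1, gridSize(grid)]
#' @return a \linkS4class{BundleSpec}
#' @export
gridSpec <- function(grid, i) {
  n <- gridSize(grid)
  stopifnot(i >= 1, i <= n)
  radices <- unlist(lapply(grid@dims, lengths)) # dphi1, R, zOff per helix
  idx <- integer(length(radices))
  rem <- i - 1
  for (k in rev(seq_along(radices))) {
    idx[k] <- rem %% radices[k]
    rem <- rem %/% radices[k]
  }
  helices <- vector("list", length(grid@phases))
  labels <- bundleChainLabels(grid@phases)
  for (h in seq_along(grid@phases)) {
    o <- (h - 1) * 3
    d <- grid@dims[[h]]
    helices[[h]] <- CrickParams(
      R = d$R[idx[o + 2] + 1], dphi0 = grid@phases[h],
      dphi1 = d$dphi1[idx[o + 1] + 1], zOff = d$zOff[idx[o + 3] + 1],
      omega0 = grid@omega0, omega1 = grid@omega1,
      length = grid@length, inverted = grid@inverted[h])
  }
  BundleSpec(helices, chainMap = labels)
}

# Inner helices (R on the inner ring) are labelled A, B, C in phase order;
# outer helices D, E, F in phase order. For a three-helix coiled coil this
# reduces to A, B, C.
bundleChainLabels <- function(phases) {
  inner <- phases %in% c(0, 120, 240)
  lab <- character(length(phases))
  lab[inner] <- LETTERS[rank(phases[inner])]
  if (any(!inner)) lab[!inner] <- LETTERS[3 + rank(phases[!inner])]
  lab
}

#' Iterate over grid specs
#'
#' @param grid a \linkS4class{ParamGrid}
#' @param indices which specs to realize (default: all; beware the full
#'   coiled-coil grid has 1,497,375 entries)
#' @return list of \linkS4class{BundleSpec}
#' @export
gridSpecs <- function(grid, indices = seq_len(gridSize(grid))) {
  lapply(indices, function(i) gridSpec(grid, i))
}

specKey <- function(spec, digits = 3) {
  paste(vapply(spec@helices, function(h)
    sprintf("%s|%s|%s|%s|%d", format(round(h@dphi0, digits)),
            format(round(h@R, digits)), format(round(h@dphi1, digits)),
            format(round(h@zOff, digits)), as.integer(h@inverted)),
    character(1)), collapse = "//")
}

#' Stepwise six-helix bundle search
#'
#' Stage 1 evaluates a joint grid over the three inner helices plus the
#' first outer helix; stages 2 and 3 sample only the newly added outer helix
#' (phases 180 and 300) against the specs retained by the previous stage.
#' A candidate survives a stage when \code{networkTest(spec)} returns TRUE
#' (or a list with element \code{pass = TRUE}, whose remaining elements are
#' kept as per-spec network evidence). Survivors are deduplicated on
#' parameters rounded to 3 decimals.
#'
#' @param stage1 a \linkS4class{ParamGrid} over four helices (see
#'   \code{\link{bundleStage1Grid}})
#' @param stage2,stage3 outer-helix grids (see \code{\link{outerHelixGrid}})
#' @param networkTest callback taking a \linkS4class{BundleSpec}
#' @param stage1Indices optional subset of stage-1 indices to evaluate
#'   (defaults to the full grid)
#' @return list of three stage results, each a list with elements
#'   \code{stage}, \code{specs}, \code{evidence}
#' @export
stepwiseBundleSearch <- function(stage1, stage2 = outerHelixGrid(180),
                                 stage3 = outerHelixGrid(300),
                                 networkTest,
                                 stage1Indices = seq_len(gridSize(stage1))) {
  runTest <- function(spec) {
    res <- tryCatch(networkTest(spec), error = function(e)
      stop("network test failed on spec ", specKey(spec), ": ",
           conditionMessage(e), call. = FALSE))
    if (is.logical(res)) list(pass = isTRUE(res)) else res
  }
  filterStage <- function(cands, stage) {
    specs <- list()
    evid <- list()
    seen <- character()
    for (sp in cands) {
      res <- runTest(sp)
      if (isTRUE(res$pass)) {
        key <- specKey(sp)
        if (!key %in% seen) {
          seen <- c(seen, key)
          specs[[length(specs) + 1L]] <- sp
          evid[[length(evid) + 1L]] <- res[setdiff(names(res), "pass")]
        }
      }
    }
    list(stage = stage, specs = specs, evidence = evid)
  }
  s1 <- filterStage(gridSpecs(stage1, stage1Indices), 1L)
  extend <- function(parents, og) {
    out <- list()
    for (sp in parents$specs) {
      for (p1 in og$dphi1) for (r in og$R) for (z in og$zOff) {
        h <- CrickParams(R = r, dphi0 = og$phase, dphi1 = p1, zOff = z,
                         omega0 = sp@helices[[1]]@omega0,
                         omega1 = sp@helices[[1]]@omega1,
                         length = sp@helices[[1]]@length,
                         inverted = isTRUE(og$inverted))
        hs <- c(sp@helices, list(h))
        phases <- vapply(hs, function(x) x@dphi0, numeric(1))
        out[[length(out) + 1L]] <- BundleSpec(hs, bundleChainLabels(phases))
      }
    }
    out
  }
  s2 <- filterStage(extend(s1, stage2), 2L)
  s3 <- filterStage(extend(s2, stage3), 3L)
  list(s1, s2, s3)
}
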