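#' @import methods
NULL

#' Generalized Crick parameters for one helix of a supercoiled bundle
#'
#' Holds the per-helix parameters of the generalized Crick coiled-coil
#' parameterization: the supercoil radius \code{R} (distance of the helix axis
#' from the superhelical z axis, in Angstrom), the supercoil phase
#' \code{dphi0} (azimuthal placement about the z axis, degrees), the helical
#' phase \code{dphi1} (rotation of the helix about its own axis, degrees), the
#' axial offset \code{zOff} (Angstrom), the supercoil twist \code{omega0} and
#' the helical twist \code{omega1} (degrees per residue). The minor helix
#' radius \code{r1} and the rise per residue \code{d} are conventional
#' ideal-alpha-helix constants. Negative \code{omega0} produces a left-handed
#' supercoil; the default twists (-2.85, 102.85) give 3.5 residues per helical
#' turn and a seven-residue (heptad) periodicity across two turns.
#'
#' @slot R supercoil radius, Angstrom (>= 0)
#' @slot dphi0 supercoil phase, degrees
#' @slot dphi1 helical phase, degrees
#' @slot zOff offset along the supercoil axis, Angstrom
#' @slot omega0 supercoil twist, degrees per residue
#' @slot omega1 helical twist, degrees per residue
#' @slot length residue count (>= 7)
#' @slot inverted logical; if TRUE the helix is flipped for an antiparallel
#'   orientation (180 degree rotation about an in-plane axis through its
#'   midpoint)
#' @slot r1 minor helix radius, Angstrom
#' @slot d rise per residue along the helix axis, Angstrom
#' @export
setClass("CrickParams",
  representation(R = "numeric", dphi0 = "numeric", dphi1 = "numeric",
                 zOff = "numeric", omega0 = "numeric", omega1 = "numeric",
                 length = "integer", inverted = "logical",
                 r1 = "numeric", d = "numeric"),
  prototype(R = 7, dphi0 = 0, dphi1 = 0, zOff = 0,
            omega0 = -2.85, omega1 = 102.85, length = 77L,
            inverted = FALSE, r1 = 2.26, d = 1.51))

setValidity("CrickParams", function(object) {
  msg <- character()
  vals <- c(object@R, object@dphi0, object@dphi1, object@zOff,
            object@omega0, object@omega1, object@r1, object@d)
  if (!all(is.finite(vals))) msg <- c(msg, "all parameters must be finite")
  if (length(object@length) != 1L || is.na(object@length) ||
      object@length < 7L)
    msg <- c(msg, "length must be a single integer >= 7")
  if (all(is.finite(vals))) {
    if (object@R < 0) msg <- c(msg, "R must be >= 0")
    if (object@r1 <= 0) msg <- c(msg, "r1 must be > 0")
    if (object@d <= 0) msg <- c(msg, "d must be > 0")
    if (abs(object@R * rad(object@omega0) / object@d) > 1)
      msg <- c(msg, "R * omega0 exceeds the rise per residue; no pitch angle")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a multi-helix bundle
#'
#' An ordered list of \linkS4class{CrickParams}, one per helix, with chain
#' labels assigned in supercoil-phase order. Supercoil phases are restricted
#' to the hexagonal design lattice \{0, 60, 120, 180, 240, 300\} degrees and
#' the first helix carries a zero axial offset.
#'
#' @slot helices list of \linkS4class{CrickParams}
#' @slot chainMap character vector of chain labels, one per helix
#' @slot handedness free-text note ("left" for omega0 < 0)
#' @export
setClass("BundleSpec",
  representation(helices = "list", chainMap = "character",
                 handedness = "character"),
  prototype(helices = list(), chainMap = character(), handedness = "left"))

setValidity("BundleSpec", function(object) {
  msg <- character()
  if (!length(object@helices)) msg <- c(msg, "at least one helix required")
  if (!all(vapply(object@helices, is, logical(1), "CrickParams")))
    msg <- c(msg, "helices must all be CrickParams")
  if (length(object@chainMap) != length(object@helices))
    msg <- c(msg, "chainMap length must equal helix count")
  lattice <- c(0, 60, 120, 180, 240, 300)
  if (length(object@helices)) {
    ph <- vapply(object@helices, function(h) h@dphi0 %% 360, numeric(1))
    if (!all(vapply(ph, function(p) any(abs(p - lattice) < 1e-6), logical(1))))
      msg <- c(msg, "supercoil phases must lie on the 0/60/.../300 lattice")
    if (abs(object@helices[[1]]@zOff) > 1e-9)
      msg <- c(msg, "first helix must have zOff = 0")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-chain backbone model
#'
#' Backbone coordinates (N, CA, C, O, CB per residue) for one or more chains,
#' with 1-based residue numbering per chain, optional heptad register letters
#' and free-form provenance metadata.
#'
#' @slot atoms data.frame with columns chain, resi, resn, elety, x, y, z
#' @slot register data.frame with columns chain, resi, letter (possibly empty)
#' @slot metadata named list (provenance, warnings, generator parameters)
#' @export
setClass("BackboneModel",
  representation(atoms = "data.frame", register = "data.frame",
                 metadata = "list"),
  prototype(atoms = data.frame(chain = character(), resi = integer(),
                               resn = character(), elety = character(),
                               x = numeric(), y = numeric(), z = numeric(),
                               stringsAsFactors = FALSE),
            register = data.frame(chain = character(), resi = integer(),
                                  letter = character(),
                                  stringsAsFactors = FALSE),
            metadata = list()))

setValidity("BackboneModel", function(object) {
  need <- c("chain", "resi", "resn", "elety", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(object@atoms) &&
      !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  TRUE
})

#' Rigid-body transform
#'
#' A proper rotation (det = +1) plus translation, applied as
#' \code{x' = R x + t}.
#'
#' @slot rotation 3x3 orthonormal matrix
#' @slot translation length-3 numeric, Angstrom
#' @export
setClass("Transform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("Transform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (length(object@translation) != 3) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-7) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
  TRUE
})

#' Hydrogen-bond network
#'
#' A set of polar sidechain placements connected by detected hydrogen bonds.
#' The placement table records position, residue type and chi angles; the
#' hydrogen-bond table records donor/acceptor atoms with their geometry.
#'
#' @slot placements data.frame (chain, resi, type, chi string, placement id)
#' @slot hbonds data.frame (donor/acceptor placement ids and atom names,
#'   distance, donor and acceptor angles)
#' @slot chains character; chains spanned by the network
#' @slot aromatics integer; number of Tyr/Trp members
#' @slot satisfaction numeric in [0, 1] or NA if not yet evaluated
#' @slot placementList the underlying rotamer placements (internal
#'   representation used for geometry re-checks)
#' @export
setClass("HBNetwork",
  representation(placements = "data.frame", hbonds = "data.frame",
                 chains = "character", aromatics = "integer",
                 satisfaction = "numeric", placementList = "list"),
  prototype(chains = character(), aromatics = 0L, satisfaction = NA_real_,
            placementList = list()))

#' Off-target species bookkeeping
#'
#' All alternative (non-target) chain compositions of size 1..maxSize over a
#' chain alphabet, stored as unordered multisets.
#'
#' @slot alphabet chain labels
#' @slot maxSize largest assembly size enumerated
#' @slot target the on-target composition (sorted character vector)
#' @slot convention "full" or "paper-trimer" (the latter omits homotypic
#'   dimers, matching the printed three-chain listing)
#' @slot members list of sorted character vectors
#' @export
setClass("SpeciesSet",
  representation(alphabet = "character", maxSize = "integer",
                 target = "character", convention = "character",
                 members = "list"))

setValidity("SpeciesSet", function(object) {
  keys <- vapply(object@members, function(m) paste(sort(m), collapse = ""),
                 character(1))
  if (anyDuplicated(keys)) return("members must be unique as multisets")
  if (length(object@target) &&
      paste(sort(object@target), collapse = "") %in% keys)
    return("target composition must not be a member")
  TRUE
})

#' Cyclic ring solution
#'
#' A spliced asymmetric unit together with the transform that propagates it,
#' the symmetry order, the ring-closure error measured on the unit's CA atoms,
#' the inter-copy backbone clash count (the score0 analogue) and per-chain
#' lengths. \code{accepted} records whether all thresholds were met.
#'
#' @slot unit asymmetric-unit \linkS4class{BackboneModel}
#' @slot transform propagation \linkS4class{Transform}
#' @slot n symmetry order
#' @slot closeErr ring closure error, Angstrom
#' @slot clashCount inter-copy backbone heavy-atom pairs closer than the
#'   clash distance
#' @slot chainLen residue count per chain of the asymmetric unit
#' @slot ring full ring \linkS4class{BackboneModel} (n copies)
#' @slot accepted logical
#' @slot reasons character; which filters failed (empty when accepted)
#' @export
setClass("RingSolution",
  representation(unit = "BackboneModel", transform = "Transform",
                 n = "integer", closeErr = "numeric", clashCount = "integer",
                 chainLen = "integer", ring = "BackboneModel",
                 accepted = "logical", reasons = "character"))
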