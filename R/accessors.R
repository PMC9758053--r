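#' Construct CrickParams
#'
#' @param R supercoil radius, Angstrom
#' @param dphi0 supercoil phase, degrees
#' @param dphi1 helical phase, degrees
#' @param zOff axial offset, Angstrom
#' @param omega0 supercoil twist, degrees/residue (ideal left-handed: -2.85)
#' @param omega1 helical twist, degrees/residue (ideal: 102.85)
#' @param length residue count
#' @param inverted flip the helix for an antiparallel orientation
#' @param r1 minor helix radius, Angstrom
#' @param d rise per residue, Angstrom
#' @return a \linkS4class{CrickParams} object
#' @examples
#' CrickParams(R = 7, dphi0 = 120, dphi1 = -40, length = 77)
#' @export
CrickParams <- function(R = 7, dphi0 = 0, dphi1 = 0, zOff = 0,
                        omega0 = -2.85, omega1 = 102.85, length = 77,
                        inverted = FALSE, r1 = 2.26, d = 1.51) {
  new("CrickParams", R = R, dphi0 = dphi0, dphi1 = dphi1, zOff = zOff,
      omega0 = omega0, omega1 = omega1, length = as.integer(length),
      inverted = inverted, r1 = r1, d = d)
}

#' Pitch angle of a Crick helix
#'
#' The angle between the helix axis and the supercoil (z) axis, determined by
#' \code{sin(alpha) = R * omega0 / d} with \code{omega0} in radians per
#' residue. Zero for a straight helix (\code{omega0 = 0} or \code{R = 0}).
#'
#' @param params a \linkS4class{CrickParams}
#' @return pitch angle in degrees
#' @export
pitchAngle <- function(params) {
  stopifnot(is(params, "CrickParams"))
  deg(asin(params@R * rad(params@omega0) / params@d))
}

#' Construct a BundleSpec
#'
#' @param helices list of \linkS4class{CrickParams}, in supercoil-phase order
#' @param chainMap chain labels, one per helix; defaults to A, B, C, ...
#' @return a \linkS4class{BundleSpec}
#' @export
BundleSpec <- function(helices, chainMap = NULL) {
  if (is(helices, "CrickParams")) helices <- list(helices)
  if (is.null(chainMap)) chainMap <- LETTERS[seq_along(helices)]
  hand <- if (all(vapply(helices, function(h) h@omega0, numeric(1)) < 0))
    "left" else "mixed-or-right"
  new("BundleSpec", helices = helices, chainMap = chainMap, handedness = hand)
}

#' Atom table of a BackboneModel
#' @param x a \linkS4class{BackboneModel}
#' @return data.frame with columns chain, resi, resn, elety, x, y, z
#' @export
atoms <- function(x) {
  stopifnot(is(x, "BackboneModel"))
  x@atoms
}

#' Chain labels present in a model
#' @param x a \linkS4class{BackboneModel}
#' @return character vector of chain identifiers, in order of appearance
#' @export
chainIds <- function(x) unique(atoms(x)$chain)

#' Residue counts per chain
#' @param x a \linkS4class{BackboneModel}
#' @return named integer vector
#' @export
chainLengths <- function(x) {
  a <- atoms(x)
  vapply(split(a$resi, a$chain)[chainIds(x)],
         function(r) length(unique(r)), integer(1))
}

#' CA coordinates of a model
#'
#' @param x a \linkS4class{BackboneModel}
#' @param chain optional chain filter
#' @return numeric matrix (n x 3), rows in chain/residue order
#' @export
caCoords <- function(x, chain = NULL) {
  a <- atoms(x)
  a <- a[a$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste0(a$chain, a$resi)
  m
}

#' All coordinates of a model as a matrix
#' @param x a \linkS4class{BackboneModel}
#' @return numeric matrix (n_atoms x 3)
#' @export
coords <- function(x) as.matrix(atoms(x)[, c("x", "y", "z")])

#' Register letters of a model
#' @param x a \linkS4class{BackboneModel}
#' @return data.frame (chain, resi, letter); zero rows if unassigned
#' @export
registerTable <- function(x) {
  stopifnot(is(x, "BackboneModel"))
  x@register
}

setMethod("show", "CrickParams", function(object) {
  cat(sprintf(
    "CrickParams: R=%.2f A, dphi0=%.1f, dphi1=%.1f, Zoff=%.2f A, %d res%s\n",
    object@R, object@dphi0, object@dphi1, object@zOff, object@length,
    if (object@inverted) " (inverted)" else ""))
  cat(sprintf("  omega0=%.2f, omega1=%.2f deg/res; alpha=%.2f deg\n",
              object@omega0, object@omega1, pitchAngle(object)))
})

setMethod("show", "BundleSpec", function(object) {
  cat(sprintf("BundleSpec: %d helices (%s-handed supercoil)\n",
              length(object@helices), object@handedness))
  for (i in seq_along(object@helices)) {
    h <- object@helices[[i]]
    cat(sprintf("  %s: phase %5.1f  R %5.2f  dphi1 %6.1f  Zoff %5.2f  %d res%s\n",
                object@chainMap[i], h@dphi0, h@R, h@dphi1, h@zOff, h@length,
                if (h@inverted) " inv" else ""))
  }
})

setMethod("show", "BackboneModel", function(object) {
  cl <- chainLengths(object)
  cat(sprintf("BackboneModel: %d chains (%s), %d atoms\n",
              length(cl),
              paste(sprintf("%s:%d", names(cl), cl), collapse = ", "),
              nrow(object@atoms)))
  if (nrow(object@register))
    cat("  register assigned\n")
  w <- object@metadata$warnings
  if (length(w)) cat("  warnings:", paste(w, collapse = "; "), "\n")
})

setMethod("show", "Transform", function(object) {
  ang <- deg(acos(max(-1, min(1, (sum(diag(object@rotation)) - 1) / 2))))
  cat(sprintf("Transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "HBNetwork", function(object) {
  cat(sprintf(
    "HBNetwork: %d residues on chains %s; %d H-bonds; %d aromatics%s\n",
    nrow(object@placements), paste(object@chains, collapse = ""),
    nrow(object@hbonds), object@aromatics,
    if (is.na(object@satisfaction)) ""
    else sprintf("; satisfaction %.2f", object@satisfaction)))
})

setMethod("show", "SpeciesSet", function(object) {
  cat(sprintf("SpeciesSet: %d alternative species over {%s}, max size %d (%s)\n",
              length(object@members), paste(object@alphabet, collapse = ","),
              object@maxSize, object@convention))
})

setMethod("show", "RingSolution", function(object) {
  cat(sprintf(
    "RingSolution: C%d, close_err %.3g A, score0 %d, chain_len %s -> %s\n",
    object@n, object@closeErr, object@clashCount,
    paste(object@chainLen, collapse = "+"),
    if (object@accepted) "accepted"
    else paste("rejected:", paste(object@reasons, collapse = ","))))
})
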