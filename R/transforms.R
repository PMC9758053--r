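#' Construct a rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix
#' @param translation length-3 translation, Angstrom
#' @return a \linkS4class{Transform}
#' @export
Transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("Transform", rotation = rotation, translation = as.numeric(translation))
}

#' Rotation about an axis through a point
#'
#' Convenience constructor: rotate by \code{angle} degrees about \code{axis}
#' passing through \code{center}, then translate by \code{shift}.
#'
#' @param axis rotation axis (need not be unit length)
#' @param angle degrees
#' @param center point on the axis
#' @param shift additional translation applied after the rotation
#' @return a \linkS4class{Transform}
#' @export
axisRotation <- function(axis = c(0, 0, 1), angle = 0, center = c(0, 0, 0),
                         shift = c(0, 0, 0)) {
  Rm <- rotationMatrix(axis, angle)
  Transform(Rm, as.numeric(center - Rm %*% center + shift))
}

#' Apply a transform
#'
#' Applies \code{x' = R x + t} to a coordinate matrix or to every atom of a
#' \linkS4class{BackboneModel}.
#'
#' @param x n x 3 matrix or \linkS4class{BackboneModel}
#' @param tf a \linkS4class{Transform}
#' @return object of the same class as \code{x}
#' @export
applyTransform <- function(x, tf) {
  stopifnot(is(tf, "Transform"))
  if (is(x, "BackboneModel")) {
    xyz <- coords(x)
    xyz <- sweep(xyz %*% t(tf@rotation), 2, tf@translation, `+`)
    a <- x@atoms
    a[, c("x", "y", "z")] <- xyz
    return(new("BackboneModel", atoms = a, register = x@register,
               metadata = x@metadata))
  }
  sweep(x %*% t(tf@rotation), 2, tf@translation, `+`)
}

#' Compose two transforms
#'
#' \code{composeTransform(a, b)} is the transform that applies \code{a}
#' first, then \code{b}.
#'
#' @param a,b \linkS4class{Transform} objects
#' @return a \linkS4class{Transform}
#' @export
composeTransform <- function(a, b) {
  Transform(b@rotation %*% a@rotation,
            as.numeric(b@rotation %*% a@translation) + b@translation)
}

#' Integer power of a transform
#'
#' @param tf a \linkS4class{Transform}
#' @param n non-negative integer
#' @return \code{tf} composed with itself \code{n} times
#' @export
transformPower <- function(tf, n) {
  stopifnot(n >= 0)
  out <- Transform()
  for (i in seq_len(n)) out <- composeTransform(out, tf)
  out
}

#' Invert a transform
#' @param tf a \linkS4class{Transform}
#' @return the inverse \linkS4class{Transform}
#' @export
invertTransform <- function(tf) {
  Rt <- t(tf@rotation)
  Transform(Rt, as.numeric(-Rt %*% tf@translation))
}

# Kabsch least-squares rotation (proper, no reflection) mapping P onto Q.
kabsch <- function(P, Q) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Transform(Rm, as.numeric(qc - Rm %*% pc))
}

# Extract matched coordinate selections from two models.
selectionCoords <- function(model, elety = "CA", chains = NULL, resi = NULL) {
  a <- atoms(model)
  keep <- a$elety %in% elety
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(resi)) keep <- keep & a$resi %in% resi
  as.matrix(a[keep, c("x", "y", "z")])
}

#' Least-squares rigid superposition
#'
#' Kabsch superposition of \code{model} onto \code{target} over a matched
#' atom selection (CA atoms by default). Returns the proper rigid transform
#' (no reflection) and the minimized RMSD.
#'
#' @param model moving \linkS4class{BackboneModel} (or n x 3 matrix)
#' @param target fixed \linkS4class{BackboneModel} (or n x 3 matrix)
#' @param elety atom names to match (ignored for matrix input)
#' @param chains optional chain filter applied to both models
#' @return list with elements \code{transform} (a \linkS4class{Transform})
#'   and \code{rmsd} (Angstrom)
#' @examples
#' h <- buildHelix(CrickParams(length = 21))
#' superpose(h, h)$rmsd
#' @export
superpose <- function(model, target, elety = "CA", chains = NULL) {
  P <- if (is.matrix(model)) model else
    selectionCoords(model, elety = elety, chains = chains)
  Q <- if (is.matrix(target)) target else
    selectionCoords(target, elety = elety, chains = chains)
  if (nrow(P) != nrow(Q)) stop("selection size mismatch: ",
                               nrow(P), " vs ", nrow(Q))
  if (nrow(P) < 3) stop("need at least 3 points to superpose")
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) selection")
  tf <- kabsch(P, Q)
  Pm <- applyTransform(P, tf)
  list(transform = tf, rmsd = sqrt(mean(rowSums((Pm - Q)^2))))
}

#' RMSD between two matched coordinate sets without fitting
#' @param P,Q n x 3 matrices
#' @return RMSD in Angstrom
#' @export
rmsdRaw <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q))
  sqrt(mean(rowSums((P - Q)^2)))
}
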