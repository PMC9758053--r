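# Crick backbone generation.
#
# CA traces follow the generalized Crick parameterization of a supercoiled
# alpha-helix; full backbones (N, C, O, CB) are completed by transferring an
# ideal alpha-helical residue frame onto each CA triplet. All angles in
# degrees, lengths in Angstrom.

# Ideal backbone internal coordinates (standard amide geometry).
.BB <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_CACB = 1.527,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.8,
  a_CCACB = 110.3, d_NCCACB = -122.7,
  phi = -60, psi = -45, omega = 180)

# CA coordinates of a Crick helix at (possibly fractional) residue indices t.
crickCA <- function(params, tvec) {
  w0 <- rad(params@omega0)
  w1 <- rad(params@omega1)
  a <- asin(params@R * w0 / params@d)  # pitch angle, radians
  phi0 <- w0 * tvec + rad(params@dphi0)
  phi1 <- w1 * tvec + rad(params@dphi1)
  R0 <- params@R
  R1 <- params@r1
  x <- R0 * cos(phi0) + R1 * cos(phi0) * cos(phi1) -
    R1 * cos(a) * sin(phi0) * sin(phi1)
  y <- R0 * sin(phi0) + R1 * sin(phi0) * cos(phi1) +
    R1 * cos(a) * cos(phi0) * sin(phi1)
  z <- params@d * cos(a) * tvec - R1 * sin(a) * sin(phi1)
  cbind(x = x, y = y, z = z)
}

# Local-frame template of one ideal alpha-helical residue: coordinates of
# N, C, O, CB relative to the frame spanned by the flanking CA atoms.
# Computed once per session from a NeRF-built ideal helix.
.templateEnv <- new.env(parent = emptyenv())

caFrame <- function(caPrev, ca, caNext) {
  a <- caNext - ca
  b <- caPrev - ca
  e1 <- unitv(a - b)
  e3 <- unitv(cross3(a, b))
  e2 <- cross3(e3, e1)
  rbind(e1, e2, e3)
}

idealResidueTemplate <- function() {
  if (!is.null(.templateEnv$tmpl)) return(.templateEnv$tmpl)
  g <- .BB
  n <- 9L
  # NeRF chain build of an ideal helix: atoms N, CA, C per residue + O.
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCA, 0, 0)
  # seed C in the xy plane
  C[1, ] <- CA[1, ] + g$b_CAC *
    c(cos(rad(180 - g$a_NCAC)), sin(rad(180 - g$a_NCAC)), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], g$b_CN, g$a_CACN, g$psi)
    CA[i + 1, ] <- placeAtom(CA[i, ], C[i, ], N[i + 1, ], g$b_NCA, g$a_CNCA,
                             g$omega)
    C[i + 1, ] <- placeAtom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_CAC,
                            g$a_NCAC, g$phi)
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ], g$b_CO, g$a_CACO,
                        g$psi + 180)
  }
  i <- 5L  # central residue
  Fm <- caFrame(CA[i - 1, ], CA[i, ], CA[i + 1, ])
  CB <- placeAtom(N[i, ], C[i, ], CA[i, ], g$b_CACB, g$a_CCACB, g$d_NCCACB)
  loc <- function(p) as.numeric(Fm %*% (p - CA[i, ]))
  .templateEnv$tmpl <- list(N = loc(N[i, ]), C = loc(C[i, ]),
                            O = loc(O[i, ]), CB = loc(CB))
  .templateEnv$tmpl
}

# Complete N/C/O/CB for a CA trace. `caAll` has one virtual CA before and
# after the real trace (rows 1 and nrow are virtual).
completeFromCA <- function(caAll, chain = "A", resn = "ALA") {
  tmpl <- idealResidueTemplate()
  nres <- nrow(caAll) - 2L
  recs <- vector("list", nres)
  for (i in seq_len(nres)) {
    ca <- caAll[i + 1, ]
    Fm <- caFrame(caAll[i, ], ca, caAll[i + 2, ])
    glob <- function(l) ca + as.numeric(t(Fm) %*% l)
    xyz <- rbind(glob(tmpl$N), ca, glob(tmpl$C), glob(tmpl$O), glob(tmpl$CB))
    recs[[i]] <- data.frame(chain = chain, resi = i, resn = resn,
                            elety = c("N", "CA", "C", "O", "CB"),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Build a single helix from Crick parameters
#'
#' Generates a poly-alanine helix whose CA trace follows the generalized
#' Crick parameterization. The axial offset is applied as a pure translation
#' along the supercoil (z) axis; \code{inverted} flips the helix by a 180
#' degree rotation about the radial axis through its midpoint (residue
#' numbering still runs N to C).
#'
#' @param params a \linkS4class{CrickParams}
#' @param chain chain label for the output model
#' @return a \linkS4class{BackboneModel} with N, CA, C, O, CB per residue
#' @examples
#' h <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 14))
#' range(dist(caCoords(h))[1:13])
#' @export
buildHelix <- function(params, chain = "A") {
  stopifnot(is(params, "CrickParams"))
  validObject(params)
  tvec <- seq(-1L, params@length) # one virtual residue each side
  caAll <- crickCA(params, tvec)
  stopifnot_finite(caAll, "Crick CA trace")
  atoms <- completeFromCA(caAll, chain = chain)
  if (params@inverted) {
    ca <- caAll[seq(2, nrow(caAll) - 1), , drop = FALSE]
    mid <- colMeans(ca)
    axis <- c(mid[1], mid[2], 0)
    if (vnorm(axis) < 1e-9) axis <- c(1, 0, 0)
    Rm <- rotationMatrix(axis, 180)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, mid) %*% t(Rm), 2, mid, `+`)
    atoms[, c("x", "y", "z")] <- xyz
  }
  atoms$z <- atoms$z + params@zOff
  new("BackboneModel", atoms = atoms,
      metadata = list(params = params, generator = "buildHelix"))
}

#' Assemble a multi-helix bundle
#'
#' Builds every helix of a \linkS4class{BundleSpec} and concatenates them
#' into one multi-chain model. Helix axes closer than \code{clashDist} are
#' reported as a warning in the model metadata (not an error): parametric
#' sampling legitimately visits near-clashing geometries that downstream
#' filters remove.
#'
#' @param spec a \linkS4class{BundleSpec}
#' @param clashDist axis-axis warning distance, Angstrom
#' @return a multi-chain \linkS4class{BackboneModel}
#' @examples
#' spec <- BundleSpec(lapply(c(0, 120, 240), function(p)
#'   CrickParams(R = 7, dphi0 = p, length = 21)))
#' assembleBundle(spec)
#' @export
assembleBundle <- function(spec, clashDist = 6) {
  stopifnot(is(spec, "BundleSpec"))
  validObject(spec)
  models <- mapply(function(h, ch) buildHelix(h, chain = ch),
                   spec@helices, spec@chainMap, SIMPLIFY = FALSE)
  atoms <- do.call(rbind, lapply(models, atoms))
  warns <- character()
  nh <- length(spec@helices)
  if (nh > 1) {
    for (i in seq_len(nh - 1)) for (j in seq(i + 1, nh)) {
      hi <- spec@helices[[i]]
      hj <- spec@helices[[j]]
      dd <- sqrt(hi@R^2 + hj@R^2 -
                   2 * hi@R * hj@R * cos(rad(hi@dphi0 - hj@dphi0)))
      if (dd < clashDist)
        warns <- c(warns, sprintf("helix axes %s-%s %.1f A apart",
                                  spec@chainMap[i], spec@chainMap[j], dd))
    }
  }
  new("BackboneModel", atoms = atoms,
      metadata = list(spec = spec, generator = "assembleBundle",
                      warnings = warns))
}

#' Backbone phi/psi dihedrals
#'
#' @param model a \linkS4class{BackboneModel}
#' @return data.frame (chain, resi, phi, psi); NA at chain termini
#' @export
phiPsi <- function(model) {
  a <- atoms(model)
  out <- list()
  for (ch in chainIds(model)) {
    b <- a[a$chain == ch, ]
    resis <- sort(unique(b$resi))
    get <- function(r, e) {
      row <- b[b$resi == r & b$elety == e, ]
      if (!nrow(row)) return(NULL)
      as.numeric(row[1, c("x", "y", "z")])
    }
    for (k in seq_along(resis)) {
      r <- resis[k]
      phi <- psi <- NA_real_
      if (k > 1 && !is.null(get(resis[k - 1], "C")))
        phi <- dihedral4(get(resis[k - 1], "C"), get(r, "N"),
                         get(r, "CA"), get(r, "C"))
      if (k < length(resis) && !is.null(get(resis[k + 1], "N")))
        psi <- dihedral4(get(r, "N"), get(r, "CA"),
                         get(r, "C"), get(resis[k + 1], "N"))
      out[[length(out) + 1L]] <- data.frame(chain = ch, resi = r,
                                            phi = phi, psi = psi)
    }
  }
  do.call(rbind, out)
}

#' Smoothed supercoil trace of a chain
#'
#' Running centroid of the CA trace over a window of one heptad, which
#' averages out the minor-helix winding and leaves the path of the helix axis
#' around the supercoil. Used to test supercoil handedness.
#'
#' @param model a \linkS4class{BackboneModel}
#' @param chain chain to trace
#' @param window centroid window in residues (default one heptad)
#' @return matrix (m x 3) of axis points
#' @export
supercoilTrace <- function(model, chain = chainIds(model)[1], window = 7L) {
  ca <- caCoords(model, chain = chain)
  n <- nrow(ca)
  if (n < window) stop("chain shorter than the smoothing window")
  m <- n - window + 1L
  out <- matrix(NA_real_, m, 3)
  for (i in seq_len(m))
    out[i, ] <- colMeans(ca[i:(i + window - 1L), , drop = FALSE])
  out
}
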