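# Discrete sidechain rotamer placement for the polar network search.
#
# Sidechains are built onto the backbone frame by internal coordinates
# (NeRF), with staggered sp3 chi values, sp2 terminal chis at -90/0/90 and
# ring chis on a 30 degree grid. Heavy atoms only; hydrogens are implicit in
# the hydrogen-bond criteria.

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

# Default polar search alphabet: all polar residues plus the acidic charged
# types; Lys/Arg are excluded by default (see allowLysArg).
POLAR_TYPES <- c("S", "T", "N", "Q", "H", "Y", "W", "D", "E")

# Sidechain internal-coordinate templates. Each atom: reference atoms
# (a, b, c), bond length to c, bond angle b-c-x, and dihedral a-b-c-x given
# either as a chi index (chi, offset) or a fixed value (fix).
.SC_TEMPLATES <- list(
  S = list(
    list(n = "OG",  r = c("N", "CA", "CB"), b = 1.417, a = 110.8, chi = 1)),
  T = list(
    list(n = "OG1", r = c("N", "CA", "CB"), b = 1.433, a = 109.5, chi = 1),
    list(n = "CG2", r = c("N", "CA", "CB"), b = 1.521, a = 110.5, chi = 1,
         off = -120)),
  N = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.516, a = 112.6, chi = 1),
    list(n = "OD1", r = c("CA", "CB", "CG"), b = 1.231, a = 120.8, chi = 2),
    list(n = "ND2", r = c("CA", "CB", "CG"), b = 1.328, a = 116.4, chi = 2,
         off = 180)),
  D = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.516, a = 112.6, chi = 1),
    list(n = "OD1", r = c("CA", "CB", "CG"), b = 1.249, a = 118.4, chi = 2),
    list(n = "OD2", r = c("CA", "CB", "CG"), b = 1.249, a = 118.4, chi = 2,
         off = 180)),
  Q = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.520, a = 114.1, chi = 1),
    list(n = "CD",  r = c("CA", "CB", "CG"), b = 1.516, a = 112.6, chi = 2),
    list(n = "OE1", r = c("CB", "CG", "CD"), b = 1.231, a = 120.8, chi = 3),
    list(n = "NE2", r = c("CB", "CG", "CD"), b = 1.328, a = 116.4, chi = 3,
         off = 180)),
  E = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.520, a = 114.1, chi = 1),
    list(n = "CD",  r = c("CA", "CB", "CG"), b = 1.516, a = 112.6, chi = 2),
    list(n = "OE1", r = c("CB", "CG", "CD"), b = 1.249, a = 118.4, chi = 3),
    list(n = "OE2", r = c("CB", "CG", "CD"), b = 1.249, a = 118.4, chi = 3,
         off = 180)),
  H = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.497, a = 113.8, chi = 1),
    list(n = "ND1", r = c("CA", "CB", "CG"), b = 1.378, a = 122.7, chi = 2),
    list(n = "CD2", r = c("CA", "CB", "CG"), b = 1.354, a = 131.0, chi = 2,
         off = 180),
    list(n = "CE1", r = c("CB", "CG", "ND1"), b = 1.321, a = 109.3,
         fix = 180),
    list(n = "NE2", r = c("CB", "CG", "CD2"), b = 1.374, a = 107.2,
         fix = 180)),
  Y = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.512, a = 113.9, chi = 1),
    list(n = "CD1", r = c("CA", "CB", "CG"), b = 1.389, a = 120.8, chi = 2),
    list(n = "CD2", r = c("CA", "CB", "CG"), b = 1.389, a = 120.8, chi = 2,
         off = 180),
    list(n = "CE1", r = c("CB", "CG", "CD1"), b = 1.382, a = 121.2,
         fix = 180),
    list(n = "CE2", r = c("CB", "CG", "CD2"), b = 1.382, a = 121.2,
         fix = 180),
    list(n = "CZ",  r = c("CG", "CD1", "CE1"), b = 1.378, a = 119.6,
         fix = 0),
    list(n = "OH",  r = c("CD1", "CE1", "CZ"), b = 1.376, a = 119.9,
         fix = 180)),
  W = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.498, a = 113.6, chi = 1),
    list(n = "CD1", r = c("CA", "CB", "CG"), b = 1.365, a = 126.9, chi = 2),
    list(n = "CD2", r = c("CA", "CB", "CG"), b = 1.433, a = 126.7, chi = 2,
         off = 180),
    list(n = "NE1", r = c("CB", "CG", "CD1"), b = 1.374, a = 110.2,
         fix = 180),
    list(n = "CE2", r = c("CB", "CG", "CD2"), b = 1.409, a = 107.2,
         fix = 180),
    list(n = "CE3", r = c("CB", "CG", "CD2"), b = 1.398, a = 133.9,
         fix = 0),
    list(n = "CZ2", r = c("CG", "CD2", "CE2"), b = 1.398, a = 122.4,
         fix = 180),
    list(n = "CZ3", r = c("CG", "CD2", "CE3"), b = 1.382, a = 118.6,
         fix = 180),
    list(n = "CH2", r = c("CD2", "CE2", "CZ2"), b = 1.368, a = 117.5,
         fix = 180)),
  K = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.520, a = 114.1, chi = 1),
    list(n = "CD",  r = c("CA", "CB", "CG"), b = 1.520, a = 111.3, chi = 2),
    list(n = "CE",  r = c("CB", "CG", "CD"), b = 1.520, a = 111.3, chi = 3),
    list(n = "NZ",  r = c("CG", "CD", "CE"), b = 1.489, a = 111.9, chi = 4)),
  R = list(
    list(n = "CG",  r = c("N", "CA", "CB"), b = 1.520, a = 114.1, chi = 1),
    list(n = "CD",  r = c("CA", "CB", "CG"), b = 1.520, a = 111.3, chi = 2),
    list(n = "NE",  r = c("CB", "CG", "CD"), b = 1.460, a = 111.5, chi = 3),
    list(n = "CZ",  r = c("CG", "CD", "NE"), b = 1.330, a = 124.2, chi = 4),
    list(n = "NH1", r = c("CD", "NE", "CZ"), b = 1.330, a = 120.0, fix = 0),
    list(n = "NH2", r = c("CD", "NE", "CZ"), b = 1.330, a = 120.0,
         fix = 180)))

# Polar heavy atoms per type: role and the antecedent atom used for the
# implicit-hydrogen angle criterion.
.POLAR_ATOMS <- list(
  S = data.frame(atom = "OG", role = "both", ante = "CB"),
  T = data.frame(atom = "OG1", role = "both", ante = "CB"),
  N = data.frame(atom = c("OD1", "ND2"), role = c("acceptor", "donor"),
                 ante = c("CG", "CG")),
  D = data.frame(atom = c("OD1", "OD2"), role = "acceptor", ante = "CG"),
  Q = data.frame(atom = c("OE1", "NE2"), role = c("acceptor", "donor"),
                 ante = c("CD", "CD")),
  E = data.frame(atom = c("OE1", "OE2"), role = "acceptor", ante = "CD"),
  H = data.frame(atom = c("ND1", "NE2"), role = "both",
                 ante = c("CG", "CD2")),
  Y = data.frame(atom = "OH", role = "both", ante = "CZ"),
  W = data.frame(atom = "NE1", role = "donor", ante = "CD1"),
  K = data.frame(atom = "NZ", role = "donor", ante = "CE"),
  R = data.frame(atom = c("NE", "NH1", "NH2"), role = "donor",
                 ante = c("CZ", "CZ", "CZ")))

# Number of chi angles per type.
.N_CHI <- c(S = 1, T = 1, N = 2, D = 2, Q = 3, E = 3, H = 2, Y = 2, W = 2,
            K = 4, R = 4)

# Chi grids: staggered sp3 values; the terminal chi of amide/carboxyl groups
# on -90/0/90; ring chi2 of His/Trp on a 30 degree grid (Tyr on half of it,
# by ring-flip symmetry). Extra-rotamer mode adds +/-20 degree sub-rotamers
# around each staggered sp3 value.
chiGrids <- function(type, extraRotamers = FALSE) {
  sp3 <- c(-60, 60, 180)
  if (extraRotamers)
    sp3 <- sort(as.vector(outer(sp3, c(-20, 0, 20), `+`)))
  sp2 <- c(-90, 0, 90)
  ring <- seq(-180, 150, by = 30)
  switch(type,
    S = , T = list(sp3),
    N = , D = list(sp3, sp2),
    Q = , E = list(sp3, sp3, sp2),
    H = , W = list(sp3, ring),
    Y = list(sp3, seq(-90, 60, by = 30)),
    K = list(sp3, sp3, sp3, sp3),
    R = list(sp3, sp3, sp3, sp2),
    stop("unknown residue type: ", type))
}

# Backbone frame (N, CA, C, CB) of one residue from a model.
residueFrame <- function(model, chain, resi) {
  a <- atoms(model)
  b <- a[a$chain == chain & a$resi == resi, ]
  if (!nrow(b)) stop("residue ", chain, resi, " not in model")
  g <- function(e) {
    row <- b[b$elety == e, ]
    if (!nrow(row)) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  fr <- list(N = g("N"), CA = g("CA"), C = g("C"), CB = g("CB"))
  if (is.null(fr$CB)) {
    bb <- .BB
    fr$CB <- placeAtom(fr$N, fr$C, fr$CA, bb$b_CACB, bb$a_CCACB, bb$d_NCCACB)
  }
  fr
}

# Build sidechain heavy atoms for one residue type at given chi angles.
buildSidechain <- function(frame, type, chis) {
  tmpl <- .SC_TEMPLATES[[type]]
  if (is.null(tmpl)) stop("unknown residue type: ", type)
  pos <- frame # named list of coordinates, grows with placed atoms
  out <- matrix(NA_real_, length(tmpl), 3,
                dimnames = list(vapply(tmpl, `[[`, character(1), "n"), NULL))
  for (k in seq_along(tmpl)) {
    at <- tmpl[[k]]
    dih <- if (!is.null(at$fix)) at$fix
           else chis[at$chi] + (at$off %||% 0)
    p <- placeAtom(pos[[at$r[1]]], pos[[at$r[2]]], pos[[at$r[3]]],
                   at$b, at$a, dih)
    pos[[at$n]] <- p
    out[k, ] <- p
  }
  out
}

# Backbone heavy-atom coordinates excluding one residue (used for the
# rotamer clash filter).
backboneCoordsExcluding <- function(model, chain, resi) {
  a <- atoms(model)
  keep <- !(a$chain == chain & a$resi == resi)
  as.matrix(a[keep, c("x", "y", "z")])
}

#' Enumerate sidechain rotamer placements at a position
#'
#' Builds every discrete rotamer of the allowed residue types at one
#' backbone position and drops placements whose sidechain heavy atoms clash
#' with the backbone (any atom within \code{clashDist} of a backbone heavy
#' atom of another residue).
#'
#' @param model a \linkS4class{BackboneModel}
#' @param chain,resi the position
#' @param types one-letter residue types to consider (default: all polar
#'   plus Asp/Glu; Lys/Arg via \code{allowLysArg})
#' @param extraRotamers add +/-20 degree sub-rotamers around sp3 chis
#' @param clashDist backbone clash distance, Angstrom
#' @param allowLysArg include Lys and Arg in the allowed set
#' @return list of placements; each has chain, resi, type, chis, atoms
#'   (matrix with named rows), donors, acceptors (data.frames with atom,
#'   ante)
#' @examples
#' h <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 14))
#' length(enumerateRotamers(h, "A", 7, types = "S"))  # 3 chi1 values
#' @export
enumerateRotamers <- function(model, chain, resi, types = POLAR_TYPES,
                              extraRotamers = FALSE, clashDist = 2.8,
                              allowLysArg = FALSE) {
  if (allowLysArg) types <- union(types, c("K", "R"))
  bad <- setdiff(types, names(.SC_TEMPLATES))
  if (length(bad)) stop("unknown residue type(s): ", paste(bad, collapse = ","))
  fr <- residueFrame(model, chain, resi)
  bb <- backboneCoordsExcluding(model, chain, resi)
  out <- list()
  for (ty in types) {
    grids <- chiGrids(ty, extraRotamers)
    combos <- as.matrix(expand.grid(rev(grids)))[, rev(seq_along(grids)),
                                                 drop = FALSE]
    pa <- .POLAR_ATOMS[[ty]]
    for (ci in seq_len(nrow(combos))) {
      chis <- as.numeric(combos[ci, ])
      atomsSc <- buildSidechain(fr, ty, chis)
      # hard-sphere clash filter against the rest of the backbone
      dmin <- min(vapply(seq_len(nrow(atomsSc)), function(i)
        min(sqrt(rowSums(sweep(bb, 2, atomsSc[i, ])^2))), numeric(1)))
      if (dmin < clashDist) next
      out[[length(out) + 1L]] <- list(
        chain = chain, resi = resi, type = ty, chis = chis,
        atoms = rbind(CB = fr$CB, atomsSc),
        donors = pa[pa$role %in% c("donor", "both"), , drop = FALSE],
        acceptors = pa[pa$role %in% c("acceptor", "both"), , drop = FALSE])
    }
  }
  out
}
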