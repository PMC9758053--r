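# Geometric hydrogen-bond detection and network satisfaction accounting.

#' Hydrogen-bond geometric criteria
#'
#' Donor-acceptor heavy-atom distance window plus minimum angles at the
#' donor (with the hydrogen implicit at ideal geometry) and at the acceptor.
#'
#' @param distMin,distMax heavy-atom distance window, Angstrom
#' @param donorAngleMin minimum antecedent-donor-acceptor angle, degrees
#' @param acceptorAngleMin minimum antecedent-acceptor-donor angle, degrees
#' @return named list of criteria
#' @export
hbondCriteria <- function(distMin = 2.6, distMax = 3.3,
                          donorAngleMin = 120, acceptorAngleMin = 90) {
  list(distMin = distMin, distMax = distMax,
       donorAngleMin = donorAngleMin, acceptorAngleMin = acceptorAngleMin)
}

# Flatten donor or acceptor atoms of a placement list into one table with
# coordinates and antecedent coordinates.
polarAtomTable <- function(placements, role) {
  rows <- list()
  for (i in seq_along(placements)) {
    p <- placements[[i]]
    tab <- if (role == "donor") p$donors else p$acceptors
    if (!nrow(tab)) next
    for (k in seq_len(nrow(tab))) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = i, chain = p$chain, resi = p$resi, type = p$type,
        atom = tab$atom[k],
        x = p$atoms[tab$atom[k], 1], y = p$atoms[tab$atom[k], 2],
        z = p$atoms[tab$atom[k], 3],
        ax = p$atoms[tab$ante[k], 1], ay = p$atoms[tab$ante[k], 2],
        az = p$atoms[tab$ante[k], 3], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id = integer(), chain = character(), resi = integer(),
                      type = character(), atom = character(), x = numeric(),
                      y = numeric(), z = numeric(), ax = numeric(),
                      ay = numeric(), az = numeric()))
  do.call(rbind, rows)
}

# Backbone polar atoms (amide N donors, carbonyl O acceptors) as pseudo
# placements with id 0 and negative ids keyed by residue.
backbonePolarTable <- function(model, role) {
  a <- atoms(model)
  rows <- list()
  for (ch in chainIds(model)) {
    b <- a[a$chain == ch, ]
    for (r in sort(unique(b$resi))) {
      res <- b[b$resi == r, ]
      g <- function(e) as.numeric(res[res$elety == e, c("x", "y", "z")][1, ])
      if (role == "donor" && any(res$elety == "N") && any(res$elety == "CA"))
        rows[[length(rows) + 1L]] <- data.frame(
          id = 0L, chain = ch, resi = r, type = "bb", atom = "N",
          x = g("N")[1], y = g("N")[2], z = g("N")[3],
          ax = g("CA")[1], ay = g("CA")[2], az = g("CA")[3])
      if (role == "acceptor" && any(res$elety == "O") && any(res$elety == "C"))
        rows[[length(rows) + 1L]] <- data.frame(
          id = 0L, chain = ch, resi = r, type = "bb", atom = "O",
          x = g("O")[1], y = g("O")[2], z = g("O")[3],
          ax = g("C")[1], ay = g("C")[2], az = g("C")[3])
    }
  }
  if (!length(rows)) return(polarAtomTable(list(), role))
  do.call(rbind, rows)
}

#' Detect hydrogen bonds among sidechain placements
#'
#' Returns every donor/acceptor heavy-atom pair satisfying the geometric
#' criteria: distance within the window, antecedent-donor-acceptor angle at
#' least \code{donorAngleMin} and antecedent-acceptor-donor angle at least
#' \code{acceptorAngleMin}. Sidechain-sidechain by default; backbone amide
#' and carbonyl groups are included when \code{model} is supplied with
#' \code{includeBackbone = TRUE}.
#'
#' @param placements list of placements from \code{\link{enumerateRotamers}}
#' @param model optional \linkS4class{BackboneModel} for backbone partners
#' @param criteria from \code{\link{hbondCriteria}}
#' @param includeBackbone also consider sidechain-backbone hydrogen bonds
#' @return data.frame (donorId, donorChain, donorResi, donorAtom,
#'   acceptorId, acceptorChain, acceptorResi, acceptorAtom, distance,
#'   donorAngle, acceptorAngle); placement id 0 denotes a backbone atom
#' @export
detectHBonds <- function(placements, model = NULL,
                         criteria = hbondCriteria(),
                         includeBackbone = FALSE) {
  don <- polarAtomTable(placements, "donor")
  acc <- polarAtomTable(placements, "acceptor")
  if (includeBackbone) {
    if (is.null(model)) stop("includeBackbone requires a model")
    don <- rbind(don, backbonePolarTable(model, "donor"))
    acc <- rbind(acc, backbonePolarTable(model, "acceptor"))
  }
  empty <- data.frame(donorId = integer(), donorChain = character(),
                      donorResi = integer(), donorAtom = character(),
                      acceptorId = integer(), acceptorChain = character(),
                      acceptorResi = integer(), acceptorAtom = character(),
                      distance = numeric(), donorAngle = numeric(),
                      acceptorAngle = numeric())
  if (!nrow(don) || !nrow(acc)) return(empty)
  stopifnot_finite(as.matrix(don[, c("x", "y", "z")]), "donor coordinates")
  stopifnot_finite(as.matrix(acc[, c("x", "y", "z")]), "acceptor coordinates")
  D <- as.matrix(don[, c("x", "y", "z")])
  A <- as.matrix(acc[, c("x", "y", "z")])
  d2 <- outer(rowSums(D^2), rowSums(A^2), `+`) - 2 * D %*% t(A)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  cand <- which(dist >= criteria$distMin & dist <= criteria$distMax,
                arr.ind = TRUE)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]
    j <- cand[k, 2]
    # never bond a residue to itself
    if (don$chain[i] == acc$chain[j] && don$resi[i] == acc$resi[j]) next
    dp <- c(don$x[i], don$y[i], don$z[i])
    da <- c(don$ax[i], don$ay[i], don$az[i])
    ap <- c(acc$x[j], acc$y[j], acc$z[j])
    aa <- c(acc$ax[j], acc$ay[j], acc$az[j])
    dAng <- angle3(da, dp, ap)
    if (dAng < criteria$donorAngleMin) next
    aAng <- angle3(aa, ap, dp)
    if (aAng < criteria$acceptorAngleMin) next
    rows[[length(rows) + 1L]] <- data.frame(
      donorId = don$id[i], donorChain = don$chain[i],
      donorResi = don$resi[i], donorAtom = don$atom[i],
      acceptorId = acc$id[j], acceptorChain = acc$chain[j],
      acceptorResi = acc$resi[j], acceptorAtom = acc$atom[j],
      distance = dist[i, j], donorAngle = dAng, acceptorAngle = aAng,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# Pairwise clash test between two placements (any heavy-atom pair closer
# than clashDist; CB excluded from the moving sets would be too lenient, so
# it is included).
placementsClash <- function(p, q, clashDist = 2.8) {
  P <- p$atoms
  Q <- q$atoms
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * P %*% t(Q)
  min(d2) < clashDist^2
}

#' Hydrogen-bond network satisfaction
#'
#' Fraction of polar heavy atoms among the network sidechains that either
#' participate in at least one detected hydrogen bond (within the network,
#' plus sidechain-backbone bonds when a model is given) or are solvent
#' exposed under the distance proxy: an atom further than
#' \code{burialRadius} from the supercoil axis is considered exposed. The
#' network passes when every buried polar atom is satisfied.
#'
#' @param network a \linkS4class{HBNetwork} or list of placements
#' @param model \linkS4class{BackboneModel} the network sits on
#' @param burialRadius Angstrom; conventionally outer-helix radius + 3
#' @param axis,axisPoint supercoil axis
#' @param criteria hydrogen-bond criteria
#' @param includeBackbone count sidechain-backbone bonds as satisfying
#' @return list(fraction, pass, atoms) where atoms is the per-atom ledger
#' @export
networkSatisfaction <- function(network, model, burialRadius = 10,
                                axis = c(0, 0, 1), axisPoint = c(0, 0, 0),
                                criteria = hbondCriteria(),
                                includeBackbone = TRUE) {
  placements <- if (is(network, "HBNetwork")) network@placementList
                else network
  if (!length(placements)) stop("no placements to evaluate")
  axis <- unitv(axis)
  hb <- detectHBonds(placements, model = model, criteria = criteria,
                     includeBackbone = includeBackbone)
  ledger <- list()
  for (i in seq_along(placements)) {
    p <- placements[[i]]
    polar <- rbind(p$donors, p$acceptors)
    polar <- polar[!duplicated(polar$atom), , drop = FALSE]
    for (k in seq_len(nrow(polar))) {
      at <- polar$atom[k]
      xyz <- p$atoms[at, ]
      v <- xyz - axisPoint
      axDist <- vnorm(v - sum(v * axis) * axis)
      exposed <- axDist > burialRadius
      bonded <- any((hb$donorChain == p$chain & hb$donorResi == p$resi &
                       hb$donorAtom == at) |
                    (hb$acceptorChain == p$chain & hb$acceptorResi == p$resi &
                       hb$acceptorAtom == at))
      ledger[[length(ledger) + 1L]] <- data.frame(
        chain = p$chain, resi = p$resi, type = p$type, atom = at,
        buried = !exposed, bonded = bonded,
        satisfied = bonded || exposed, stringsAsFactors = FALSE)
    }
  }
  led <- do.call(rbind, ledger)
  frac <- mean(led$satisfied)
  list(fraction = frac, pass = all(led$satisfied[led$buried]), atoms = led)
}
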