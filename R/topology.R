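# Off-target species enumeration, chain trimming, hairpin pairing and loop
# feasibility.

# All multisets of size s over alphabet, as sorted character vectors.
multisetsOfSize <- function(alphabet, s) {
  k <- length(alphabet)
  idx <- utils::combn(k + s - 1, s, simplify = FALSE) # stars and bars
  lapply(idx, function(cb) sort(alphabet[cb - seq_len(s) + 1L]))
}

#' Enumerate alternative (off-target) species
#'
#' All multiset compositions of sizes 1..\code{maxSize} over the chain
#' alphabet, minus the on-target composition. Convention \code{"full"}
#' excludes nothing else; convention \code{"paper-trimer"} additionally
#' omits the homotypic dimers (AA, BB, CC), matching the printed listing
#' convention for the three-chain system. A two-chain AB design under
#' \code{"full"} gives the four alternatives A, B, AA, BB; a three-chain ABC
#' design under \code{"paper-trimer"} gives 15.
#'
#' @param alphabet chain labels, e.g. \code{c("A","B","C")}
#' @param maxSize largest assembly size enumerated
#' @param target on-target composition (character vector of chain labels),
#'   or NULL for none
#' @param convention "full" or "paper-trimer"
#' @return a \linkS4class{SpeciesSet}
#' @examples
#' speciesCount(enumerateSpecies(c("A", "B"), 2, c("A", "B")))        # 4
#' speciesCount(enumerateSpecies(c("A", "B", "C"), 3, c("A", "B", "C"),
#'                               convention = "paper-trimer"))        # 15
#' @export
enumerateSpecies <- function(alphabet, maxSize, target = NULL,
                             convention = c("full", "paper-trimer")) {
  convention <- match.arg(convention)
  if (!length(alphabet)) stop("empty chain alphabet")
  maxSize <- as.integer(maxSize)
  stopifnot(maxSize >= 1)
  if (!is.null(target) && length(target) > maxSize)
    stop("target size exceeds maxSize")
  members <- unlist(lapply(seq_len(maxSize), multisetsOfSize,
                           alphabet = alphabet), recursive = FALSE)
  keys <- vapply(members, paste, character(1), collapse = "")
  drop <- rep(FALSE, length(members))
  if (!is.null(target))
    drop <- drop | keys == paste(sort(target), collapse = "")
  if (convention == "paper-trimer") {
    homodimer <- lengths(members) == 2L &
      vapply(members, function(m) m[1] == m[2], logical(1))
    drop <- drop | homodimer
  }
  new("SpeciesSet", alphabet = alphabet, maxSize = maxSize,
      target = if (is.null(target)) character() else sort(target),
      convention = convention, members = members[!drop])
}

#' Number of species in a SpeciesSet
#' @param x a \linkS4class{SpeciesSet}
#' @return integer count
#' @export
speciesCount <- function(x) length(x@members)

#' Species compositions as strings
#' @param x a \linkS4class{SpeciesSet}
#' @return character vector, e.g. c("A", "AB", "AAB")
#' @export
speciesLabels <- function(x)
  vapply(x@members, paste, character(1), collapse = "")

#' Trim chains by whole heptads
#'
#' Removes \code{7 * heptads} residues from the specified end of each named
#' chain and renumbers the remaining residues from 1. Register annotation is
#' carried over (letters are per-residue properties and survive the shift).
#'
#' @param model a \linkS4class{BackboneModel}
#' @param trims named numeric vector: heptads to trim per chain, e.g.
#'   \code{c(A = 4, B = 2)}
#' @param end "C" (default) or "N"; may be a named vector per chain
#' @return trimmed \linkS4class{BackboneModel}
#' @examples
#' b <- assembleBundle(BundleSpec(lapply(c(0, 120, 240), function(p)
#'   CrickParams(dphi0 = p, length = 77))))
#' chainLengths(trimChains(b, c(A = 4, B = 2)))  # 49 63 77
#' @export
trimChains <- function(model, trims, end = "C") {
  a <- atoms(model)
  reg <- registerTable(model)
  endFor <- function(ch) {
    if (length(end) == 1 && is.null(names(end))) return(end)
    (end[ch] %||% "C")
  }
  for (ch in names(trims)) {
    nres <- trims[[ch]] * 7L
    if (nres == 0) next
    resis <- sort(unique(a$resi[a$chain == ch]))
    if (!length(resis)) stop("chain ", ch, " not in model")
    if (nres >= length(resis))
      stop("trimming ", trims[[ch]], " heptads would remove all of chain ",
           ch)
    e <- match.arg(endFor(ch), c("C", "N"))
    gone <- if (e == "C") utils::tail(resis, nres) else utils::head(resis, nres)
    a <- a[!(a$chain == ch & a$resi %in% gone), ]
    if (nrow(reg)) reg <- reg[!(reg$chain == ch & reg$resi %in% gone), ]
    if (e == "N") {
      shift <- nres
      a$resi[a$chain == ch] <- a$resi[a$chain == ch] - shift
      if (nrow(reg))
        reg$resi[reg$chain == ch] <- reg$resi[reg$chain == ch] - shift
    }
  }
  new("BackboneModel", atoms = a, register = reg,
      metadata = c(model@metadata, list(trims = trims)))
}

#' Hairpin pairing scheme for a six-helix bundle
#'
#' Inner helices A-C (supercoil phases 0/120/240) are joined to outer
#' helices D-F (60/180/300) by short loops, closing the bundle into three
#' helical hairpin chains: clockwise pairs A-D, B-E, C-F; counterclockwise
#' pairs A-F, B-E, C-D. \code{loopSide} records whether the loops all face
#' the same terminal end of the bundle or alternate between opposing ends.
#'
#' @param direction "clockwise" or "counterclockwise"
#' @param loopSide "same-side" or "opposing-ends"
#' @param inner,outer helix labels
#' @return list with elements pairs (list of label pairs), direction,
#'   loopSide
#' @export
hairpinPairings <- function(direction = c("clockwise", "counterclockwise"),
                            loopSide = c("same-side", "opposing-ends"),
                            inner = c("A", "B", "C"),
                            outer = c("D", "E", "F")) {
  direction <- match.arg(direction)
  loopSide <- match.arg(loopSide)
  pairs <- if (direction == "clockwise")
    list(c(inner[1], outer[1]), c(inner[2], outer[2]), c(inner[3], outer[3]))
  else
    list(c(inner[1], outer[3]), c(inner[2], outer[2]), c(inner[3], outer[1]))
  list(pairs = pairs, direction = direction, loopSide = loopSide)
}

# Terminus CA with end adjustment: negative adjust deletes residues,
# positive extends by linear extrapolation of the last CA-CA step.
terminusCA <- function(ca, end, adjust) {
  n <- nrow(ca)
  if (end == "C") {
    i <- n + min(adjust, 0)
    if (i < 2) return(NULL)
    p <- ca[i, ]
    if (adjust > 0) p <- p + adjust * (ca[n, ] - ca[n - 1, ])
  } else {
    i <- 1 - min(adjust, 0)
    if (i > n - 1) return(NULL)
    p <- ca[i, ]
    if (adjust > 0) p <- p + adjust * (ca[1, ] - ca[2, ])
  }
  p
}

#' Loop feasibility between paired helices
#'
#' For each pair of a pairing scheme, tests whether a short loop of 2-5
#' residues can bridge the joined termini, allowing each terminus to be
#' trimmed by up to 3 residues or extended by up to 2 (extension positions
#' extrapolated along the terminal helix direction). A loop of length L is
#' feasible when the terminus-terminus CA distance does not exceed
#' \code{dMaxPerResidue * (L + 1)}. Both join directions (C of the first
#' helix to N of the second, and vice versa) are reported.
#'
#' @param model a \linkS4class{BackboneModel} with the paired chains
#' @param scheme from \code{\link{hairpinPairings}}
#' @param loopLens candidate loop lengths, residues
#' @param endAdjust allowed terminus adjustments, residues
#' @param dMaxPerResidue maximum span per loop residue, Angstrom
#' @return data.frame, one row per pair and direction: the best (shortest
#'   distance) option with its adjustments, minimal feasible loop length and
#'   feasibility flag
#' @export
loopFeasibility <- function(model, scheme, loopLens = 2:5,
                            endAdjust = -3:2, dMaxPerResidue = 3.3) {
  rows <- list()
  for (pr in scheme$pairs) {
    for (dir in 1:2) {
      from <- pr[dir]
      to <- pr[3 - dir]
      caF <- caCoords(model, chain = from)
      caT <- caCoords(model, chain = to)
      best <- NULL
      for (aF in endAdjust) for (aT in endAdjust) {
        p <- terminusCA(caF, "C", aF)
        q <- terminusCA(caT, "N", aT)
        if (is.null(p) || is.null(q)) next
        d <- vnorm(p - q)
        if (is.null(best) || d < best$distance)
          best <- list(adjustFrom = aF, adjustTo = aT, distance = d)
      }
      feasLens <- loopLens[dMaxPerResidue * (loopLens + 1) >= best$distance]
      rows[[length(rows) + 1L]] <- data.frame(
        from = from, fromEnd = "C", to = to, toEnd = "N",
        adjustFrom = best$adjustFrom, adjustTo = best$adjustTo,
        distance = best$distance,
        minLoopLen = if (length(feasLens)) min(feasLens) else NA_integer_,
        feasible = length(feasLens) > 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
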