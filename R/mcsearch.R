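# Monte Carlo hydrogen-bond network search.
#
# All rotamer placements at the searchable positions are enumerated once;
# pairwise hydrogen-bond and clash relations between placements are
# precomputed into adjacency lists. Each Monte Carlo trial then seeds a
# random placement and stochastically extends it along hydrogen-bond edges
# with clash-free placements until no extension is possible. Trials are
# independently seeded from a single integer seed by a counter, so results
# are reproducible and accumulate monotonically with the trial count.

#' Per-network and cross-network search constraints
#'
#' Defaults are the heterotrimer coiled-coil search: every network must span
#' all three chains and contain at least three residues; three networks are
#' required across the trimer, with at least two Trp/Tyr residues among
#' them (at least two networks contributing one aromatic each).
#'
#' @param minResidues minimum residues per network
#' @param spanChains chains every network must touch
#' @param nNetworks networks required across the design
#' @param minAromatics minimum total Trp/Tyr over the selected networks
#' @param minAromaticNetworks minimum number of selected networks that
#'   contribute at least one Trp/Tyr
#' @return named list of constraints
#' @export
networkConstraints <- function(minResidues = 3,
                               spanChains = c("A", "B", "C"),
                               nNetworks = 3, minAromatics = 2,
                               minAromaticNetworks = 2) {
  list(minResidues = minResidues, spanChains = spanChains,
       nNetworks = nNetworks, minAromatics = minAromatics,
       minAromaticNetworks = minAromaticNetworks)
}

# Precompute placements and their pairwise hydrogen-bond / clash relations.
# Position pairs whose CA atoms are farther apart than reachCutoff cannot
# interact and are skipped.
hbnetPrecompute <- function(model, mask, types = POLAR_TYPES,
                            extraRotamers = FALSE,
                            criteria = hbondCriteria(), clashDist = 2.8,
                            allowLysArg = FALSE, reachCutoff = 16) {
  sites <- mask[mask$searchable, c("chain", "resi")]
  if (!nrow(sites)) return(list(placements = list(), sites = sites,
                                hb = list(), clash = list()))
  placements <- list()
  siteOf <- integer()
  for (s in seq_len(nrow(sites))) {
    pl <- enumerateRotamers(model, sites$chain[s], sites$resi[s],
                            types = types, extraRotamers = extraRotamers,
                            clashDist = clashDist, allowLysArg = allowLysArg)
    placements <- c(placements, pl)
    siteOf <- c(siteOf, rep(s, length(pl)))
  }
  np <- length(placements)
  hb <- vector("list", np)
  clash <- vector("list", np)
  if (np) {
    ca <- caCoords(model)
    siteXYZ <- ca[paste0(sites$chain, sites$resi), , drop = FALSE]
    for (s1 in seq_len(nrow(sites) - 1L)) for (s2 in seq(s1 + 1L, nrow(sites))) {
      if (vnorm(siteXYZ[s1, ] - siteXYZ[s2, ]) > reachCutoff) next
      i1 <- which(siteOf == s1)
      i2 <- which(siteOf == s2)
      if (!length(i1) || !length(i2)) next
      sub <- c(i1, i2)
      hbp <- detectHBonds(placements[sub], criteria = criteria)
      # map the sub-list bond records back to global placement indices
      if (nrow(hbp)) {
        gd <- sub[hbp$donorId]
        ga <- sub[hbp$acceptorId]
        cross <- (siteOf[gd] != siteOf[ga])
        for (k in which(cross)) {
          a <- gd[k]; b <- ga[k]
          hb[[a]] <- c(hb[[a]], b)
          hb[[b]] <- c(hb[[b]], a)
        }
      }
      for (a in i1) for (b in i2) {
        if (placementsClash(placements[[a]], placements[[b]], clashDist)) {
          clash[[a]] <- c(clash[[a]], b)
          clash[[b]] <- c(clash[[b]], a)
        }
      }
    }
    hb <- lapply(hb, function(v) sort(unique(v)))
    clash <- lapply(clash, function(v) sort(unique(v)))
  }
  list(placements = placements, sites = sites, siteOf = siteOf,
       hb = hb, clash = clash, criteria = criteria)
}

networkKey <- function(placements) {
  paste(sort(vapply(placements, function(p)
    paste0(p$chain, p$resi, ":", p$type), character(1))), collapse = "|")
}

# Assemble an HBNetwork object from placement indices.
buildNetworkObject <- function(pre, idx) {
  pls <- pre$placements[idx]
  hbdf <- detectHBonds(pls, criteria = pre$criteria)
  ptab <- do.call(rbind, lapply(pls, function(p) data.frame(
    chain = p$chain, resi = p$resi, type = p$type,
    chis = paste(p$chis, collapse = ","), stringsAsFactors = FALSE)))
  new("HBNetwork", placements = ptab, hbonds = hbdf,
      chains = sort(unique(ptab$chain)),
      aromatics = sum(ptab$type %in% c("Y", "W")),
      placementList = pls)
}

#' Monte Carlo hydrogen-bond network search
#'
#' Runs \code{trials} seeded growth attempts over the searchable positions
#' of \code{mask} and returns the distinct networks that satisfy the
#' per-network constraints (minimum size and chain span). Networks are
#' deduplicated on their position-to-residue-type map. The search is
#' deterministic for a given seed, and the set of networks found by
#' \code{trials = n} is a subset of that found by any larger trial count
#' with the same seed.
#'
#' @param model a \linkS4class{BackboneModel}
#' @param mask search mask from \code{\link{buildSearchMask}}
#' @param constraints from \code{\link{networkConstraints}}
#' @param trials number of Monte Carlo trials
#' @param seed integer seed
#' @param types allowed residue types (one-letter)
#' @param extraRotamers add +/-20 degree sp3 sub-rotamers
#' @param criteria hydrogen-bond criteria
#' @param clashDist hard-sphere clash distance, Angstrom
#' @param allowLysArg include Lys/Arg in the allowed set
#' @param precomputed optionally reuse a previous precompute (internal)
#' @return list of \linkS4class{HBNetwork}, in order of first discovery
#' @export
mcNetworkSearch <- function(model, mask, constraints = networkConstraints(),
                            trials = 1000, seed = 0, types = POLAR_TYPES,
                            extraRotamers = FALSE,
                            criteria = hbondCriteria(), clashDist = 2.8,
                            allowLysArg = FALSE, precomputed = NULL) {
  stopifnot(trials >= 1)
  nSearch <- sum(mask$searchable)
  if (nSearch < 1) return(list())
  if (constraints$minResidues > nSearch)
    stop("impossible constraints: minResidues (", constraints$minResidues,
         ") exceeds the ", nSearch, " searchable positions")
  maskChains <- unique(mask$chain[mask$searchable])
  if (!all(constraints$spanChains %in% maskChains))
    stop("impossible constraints: required chains ",
         paste(setdiff(constraints$spanChains, maskChains), collapse = ","),
         " have no searchable positions")
  pre <- precomputed %||%
    hbnetPrecompute(model, mask, types = types,
                    extraRotamers = extraRotamers, criteria = criteria,
                    clashDist = clashDist, allowLysArg = allowLysArg)
  np <- length(pre$placements)
  if (!np) return(list())
  found <- list()
  seen <- character()
  chainOf <- vapply(pre$placements, `[[`, character(1), "chain")
  for (trial in seq_len(trials)) {
    set.seed((seed + trial) %% .Machine$integer.max)
    cur <- sample.int(np, 1)
    posUsed <- pre$siteOf[cur]
    repeat {
      cand <- unique(unlist(pre$hb[cur]))
      if (length(cand)) {
        bad <- pre$siteOf[cand] %in% posUsed |
          vapply(cand, function(j) any(unlist(pre$clash[j]) %in% cur),
                 logical(1))
        cand <- cand[!bad]
      }
      if (!length(cand)) break
      nxt <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      cur <- c(cur, nxt)
      posUsed <- c(posUsed, pre$siteOf[nxt])
    }
    if (length(cur) < constraints$minResidues) next
    if (!all(constraints$spanChains %in% chainOf[cur])) next
    key <- networkKey(pre$placements[cur])
    if (key %in% seen) next
    seen <- c(seen, key)
    found[[length(found) + 1L]] <- buildNetworkObject(pre, cur)
  }
  found
}

#' Select combinations of disjoint networks meeting cross-network rules
#'
#' Evaluates combinations of \code{nNetworks} position-disjoint,
#' mutually compatible networks and keeps those meeting the aromatic
#' requirements: at least \code{minAromatics} Trp/Tyr in total and at least
#' \code{minAromaticNetworks} networks contributing one or more.
#'
#' @param networks list of \linkS4class{HBNetwork}
#' @param constraints from \code{\link{networkConstraints}}
#' @param maxCombos stop after this many passing combinations
#' @return list of integer index vectors into \code{networks}
#' @export
selectNetworkSets <- function(networks, constraints = networkConstraints(),
                              maxCombos = 100) {
  k <- constraints$nNetworks
  if (length(networks) < k) return(list())
  posSets <- lapply(networks, function(n)
    paste0(n@placements$chain, n@placements$resi))
  arom <- vapply(networks, function(n) n@aromatics, integer(1))
  out <- list()
  combos <- utils::combn(length(networks), k, simplify = FALSE)
  for (cb in combos) {
    allPos <- unlist(posSets[cb])
    if (anyDuplicated(allPos)) next
    if (sum(arom[cb]) < constraints$minAromatics) next
    if (sum(arom[cb] >= 1) < constraints$minAromaticNetworks) next
    out[[length(out) + 1L]] <- cb
    if (length(out) >= maxCombos) break
  }
  out
}
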