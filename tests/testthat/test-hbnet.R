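# Synthetic placement helper: a bare rotamer-placement record.
syntheticPlacement <- function(chain, resi, type, atoms, donors = NULL,
                               acceptors = NULL) {
  list(chain = chain, resi = resi, type = type, chis = 0,
       atoms = atoms,
       donors = donors %||% data.frame(atom = character(),
                                       ante = character()),
       acceptors = acceptors %||% data.frame(atom = character(),
                                             ante = character()))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rotamer grids have the expected cardinalities", {
  h <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 14))
  # residue 1 is unobstructed: all chi1 values survive the clash filter
  expect_length(enumerateRotamers(h, "A", 1, types = "S"), 3)
  expect_length(enumerateRotamers(h, "A", 1, types = "S",
                                  extraRotamers = TRUE), 9)
  expect_error(enumerateRotamers(h, "A", 1, types = "Z"), "unknown residue")
})

test_that("the default polar alphabet excludes Lys/Arg unless enabled", {
  h <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 14))
  types <- unique(vapply(enumerateRotamers(h, "A", 1), `[[`, character(1),
                         "type"))
  expect_setequal(types, c("S", "T", "N", "Q", "H", "Y", "W", "D", "E"))
  typesKR <- unique(vapply(enumerateRotamers(h, "A", 1, allowLysArg = TRUE),
                           `[[`, character(1), "type"))
  expect_true(all(c("K", "R") %in% typesKR))
})

test_that("constructed donor/acceptor pairs obey the geometric criteria", {
  ser <- syntheticPlacement("A", 1, "S",
    rbind(CB = c(-1.4, 0, 0), OG = c(0, 0, 0)),
    donors = data.frame(atom = "OG", ante = "CB"),
    acceptors = data.frame(atom = "OG", ante = "CB"))
  glu28 <- syntheticPlacement("B", 1, "E",
    rbind(CD = c(2.8 + 0.625, 1.083, 0), OE1 = c(2.8, 0, 0)),
    acceptors = data.frame(atom = "OE1", ante = "CD"))
  hb <- detectHBonds(list(ser, glu28))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)
  expect_gte(hb$donorAngle, 120)
  expect_gte(hb$acceptorAngle, 90)

  glu45 <- glu28
  glu45$atoms["OE1", ] <- c(4.5, 0, 0)
  glu45$atoms["CD", ] <- c(4.5 + 0.625, 1.083, 0)
  expect_equal(nrow(detectHBonds(list(ser, glu45))), 0)
})

test_that("detectHBonds equals the exhaustive all-pairs oracle", {
  for (seed in 1:20) {
    pls <- randomPlacementSet(seed)
    if (length(pls) < 2) next
    mine <- detectHBonds(pls)
    oracle <- bruteForceHBonds(pls)
    keyM <- sort(paste(mine$donorId, mine$donorAtom, mine$acceptorId,
                       mine$acceptorAtom))
    keyO <- sort(paste(oracle$donorId, oracle$donorAtom, oracle$acceptorId,
                       oracle$acceptorAtom))
    expect_identical(keyM, keyO)
  }
})

test_that("the planted triad is recovered within 1,000 trials at seed 0", {
  fx <- triadFixture()
  nets <- mcNetworkSearch(fx$model, fx$mask,
                          networkConstraints(minResidues = 3,
                                             spanChains = c("A", "B", "C"),
                                             nNetworks = 1,
                                             minAromatics = 0,
                                             minAromaticNetworks = 0),
                          trials = 1000, seed = 0,
                          types = c("S", "T", "N"), extraRotamers = TRUE)
  expect_gte(length(nets), 1)
  n1 <- nets[[1]]
  expect_setequal(n1@chains, c("A", "B", "C"))
  expect_gte(nrow(n1@placements), 3)
  # the hydrogen-bond graph is connected over the member residues
  members <- paste0(n1@placements$chain, n1@placements$resi)
  edges <- cbind(paste0(n1@hbonds$donorChain, n1@hbonds$donorResi),
                 paste0(n1@hbonds$acceptorChain, n1@hbonds$acceptorResi))
  reached <- members[1]
  repeat {
    nxt <- unique(c(edges[edges[, 1] %in% reached, 2],
                    edges[edges[, 2] %in% reached, 1]))
    grown <- union(reached, nxt)
    if (length(grown) == length(reached)) break
    reached <- grown
  }
  expect_setequal(reached, members)
})

test_that("the search is deterministic and monotone in the trial count", {
  fx <- triadFixture()
  cons <- networkConstraints(minResidues = 3, spanChains = c("A", "B", "C"),
                             nNetworks = 1, minAromatics = 0,
                             minAromaticNetworks = 0)
  a <- mcNetworkSearch(fx$model, fx$mask, cons, trials = 300, seed = 0,
                       types = c("S", "T", "N"), extraRotamers = TRUE)
  b <- mcNetworkSearch(fx$model, fx$mask, cons, trials = 300, seed = 0,
                       types = c("S", "T", "N"), extraRotamers = TRUE)
  keys <- function(nets) vapply(nets, function(n)
    BundleForge:::networkKey(n@placementList), character(1))
  expect_identical(keys(a), keys(b))
  more <- mcNetworkSearch(fx$model, fx$mask, cons, trials = 600, seed = 0,
                          types = c("S", "T", "N"), extraRotamers = TRUE)
  expect_true(all(keys(a) %in% keys(more)))
})

test_that("search results are invariant under rigid-body motion", {
  fx <- triadFixture()
  cons <- networkConstraints(minResidues = 3, spanChains = c("A", "B", "C"),
                             nNetworks = 1, minAromatics = 0,
                             minAromaticNetworks = 0)
  set.seed(23)
  moved <- applyTransform(fx$model, randomTransform())
  keys <- function(nets) sort(vapply(nets, function(n)
    BundleForge:::networkKey(n@placementList), character(1)))
  a <- mcNetworkSearch(fx$model, fx$mask, cons, trials = 300, seed = 0,
                       types = c("S", "T", "N"), extraRotamers = TRUE)
  b <- mcNetworkSearch(moved, fx$mask, cons, trials = 300, seed = 0,
                       types = c("S", "T", "N"), extraRotamers = TRUE)
  expect_identical(keys(a), keys(b))
})

test_that("degenerate masks and impossible constraints are handled", {
  fx <- triadFixture()
  maskN <- fx$mask
  maskN$searchable <- FALSE
  expect_length(mcNetworkSearch(fx$model, maskN, trials = 10, seed = 0), 0)
  expect_error(
    mcNetworkSearch(fx$model, fx$mask,
                    networkConstraints(minResidues = 100), trials = 10,
                    seed = 0),
    "impossible constraints")
})

test_that("satisfaction accounting distinguishes bonded, buried and exposed", {
  serA <- syntheticPlacement("A", 1, "S",
    rbind(CB = c(-1.4, 0, 0), OG = c(0, 0, 0)),
    donors = data.frame(atom = "OG", ante = "CB"),
    acceptors = data.frame(atom = "OG", ante = "CB"))
  serB <- syntheticPlacement("B", 1, "S",
    rbind(CB = c(2.8 + 0.99, 0.99, 0), OG = c(2.8, 0, 0)),
    donors = data.frame(atom = "OG", ante = "CB"),
    acceptors = data.frame(atom = "OG", ante = "CB"))
  sat <- networkSatisfaction(list(serA, serB), model = NULL,
                             burialRadius = 10, includeBackbone = FALSE)
  expect_equal(sat$fraction, 1)
  expect_true(sat$pass)

  lone <- syntheticPlacement("C", 1, "S",
    rbind(CB = c(0, 6, 0), OG = c(0, 7.2, 0)),
    donors = data.frame(atom = "OG", ante = "CB"),
    acceptors = data.frame(atom = "OG", ante = "CB"))
  sat2 <- networkSatisfaction(list(serA, serB, lone), model = NULL,
                              burialRadius = 10, includeBackbone = FALSE)
  expect_lt(sat2$fraction, 1)
  expect_false(sat2$pass)

  tyrOut <- syntheticPlacement("C", 2, "Y",
    rbind(CZ = c(11, 0, 0), OH = c(12.4, 0, 0)),
    donors = data.frame(atom = "OH", ante = "CZ"),
    acceptors = data.frame(atom = "OH", ante = "CZ"))
  sat3 <- networkSatisfaction(list(serA, serB, tyrOut), model = NULL,
                              burialRadius = 10, includeBackbone = FALSE)
  expect_equal(sat3$fraction, 1)
  expect_true(sat3$pass)
})

test_that("disjoint network sets respect the aromatic rules", {
  mkNet <- function(chain, resis, types) {
    new("HBNetwork",
        placements = data.frame(chain = chain, resi = resis, type = types,
                                chis = "0"),
        hbonds = data.frame(),
        chains = unique(chain),
        aromatics = sum(types %in% c("Y", "W")),
        placementList = list())
  }
  nets <- list(
    mkNet(c("A", "B", "C"), c(1, 1, 1), c("S", "Y", "N")),
    mkNet(c("A", "B", "C"), c(8, 8, 8), c("W", "T", "S")),
    mkNet(c("A", "B", "C"), c(15, 15, 15), c("S", "T", "N")),
    mkNet(c("A", "B", "C"), c(1, 8, 15), c("Y", "Y", "Y")))  # overlaps 1-3
  sets <- selectNetworkSets(nets, networkConstraints(nNetworks = 3,
                                                     minAromatics = 2,
                                                     minAromaticNetworks = 2))
  expect_equal(sets, list(1:3))
})
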