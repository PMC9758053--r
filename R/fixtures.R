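# Deterministic generation of synthetic test inputs. Every fixture verifies
# its own planted ground truth with the corresponding module operation
# before it is returned, and records the claims in a manifest.

#' Generate a self-verifying synthetic fixture
#'
#' Kinds:
#' \describe{
#'   \item{planted-triad}{A C3 three-helix bundle (21-residue chains,
#'     R = 7 Angstrom, helical phase -20 degrees) on which a Ser/Thr/Asn
#'     hydrogen-bond network spanning all three chains exists at the core
#'     positions of the central heptad. The triad is re-discovered with
#'     \code{\link{mcNetworkSearch}} and re-verified with
#'     \code{\link{detectHBonds}} at generation time.}
#'   \item{c3-wedge}{A two-helix wedge (straight 21-residue helices at
#'     bundle radius 15 Angstrom, azimuths 0 and 40 degrees) whose junction
#'     transform is the exact 120 degree rotation about z, so a C3 ring
#'     closes with zero error and no inter-copy clashes.}
#'   \item{toy-dhr}{A synthetic straight-helix repeat protein: 4 repeats of
#'     two antiparallel 16-residue helices, with N- and C-terminal helical
#'     splice windows of at least 14 residues.}
#' }
#'
#' @param kind fixture kind
#' @param seed integer seed (fixtures are deterministic; the seed feeds the
#'   Monte Carlo verification search)
#' @return list with elements \code{kind}, \code{model} (and for the wedge
#'   \code{transform}), and \code{manifest} (named list of planted ground
#'   truth)
#' @export
makeFixture <- function(kind = c("planted-triad", "c3-wedge", "toy-dhr"),
                        seed = 0) {
  kind <- match.arg(kind)
  switch(kind,
         "planted-triad" = fixturePlantedTriad(seed),
         "c3-wedge" = fixtureC3Wedge(),
         "toy-dhr" = fixtureToyDHR())
}

fixturePlantedTriad <- function(seed = 0) {
  spec <- BundleSpec(lapply(c(0, 120, 240), function(p)
    CrickParams(R = 7, dphi0 = p, dphi1 = -20, length = 21)))
  model <- assembleBundle(spec)
  ann <- assignRegister(model)
  mask <- buildSearchMask(ann, "NPN")
  cons <- networkConstraints(minResidues = 3, spanChains = c("A", "B", "C"),
                             nNetworks = 1, minAromatics = 0,
                             minAromaticNetworks = 0)
  nets <- mcNetworkSearch(model, mask, cons, trials = 300, seed = seed,
                          types = c("S", "T", "N"), extraRotamers = TRUE)
  if (!length(nets))
    stop("planted-triad fixture failed self-verification: no 3-chain ",
         "network found")
  net <- nets[[1]]
  hb <- detectHBonds(net@placementList)
  if (!nrow(hb))
    stop("planted-triad fixture failed self-verification: detectHBonds ",
         "finds no bonds")
  list(kind = "planted-triad", model = model, mask = mask, network = net,
       manifest = list(
         chains = chainIds(model), R = 7, dphi1 = -20, length = 21,
         pattern = "NPN", searchTypes = c("S", "T", "N"),
         triad = net@placements, nHBonds = nrow(hb),
         spans = net@chains, seed = seed))
}

fixtureC3Wedge <- function() {
  mk <- function(azimuth, chain) {
    h <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 21),
                    chain = chain)
    applyTransform(h, axisRotation(c(0, 0, 1), azimuth,
                                   shift = c(15 * cos(rad(azimuth)),
                                             15 * sin(rad(azimuth)), 0)))
  }
  a <- mk(0, "A")
  b <- mk(40, "B")
  unit <- new("BackboneModel", atoms = rbind(atoms(a), atoms(b)),
              metadata = list(generator = "fixtureC3Wedge"))
  tf <- axisRotation(c(0, 0, 1), 120)
  err <- ringClosureError(tf, 3, unit)
  if (err > 1e-9)
    stop("c3-wedge fixture failed self-verification: closure error ", err)
  list(kind = "c3-wedge", model = unit, transform = tf,
       manifest = list(symmetry = 3, rotation = 120, radius = 15,
                       azimuths = c(0, 40), closeErr = err))
}

fixtureToyDHR <- function() {
  nrep <- 4L
  helixLen <- 16L
  spacing <- 10.5
  pieces <- list()
  resOff <- 0L
  for (r in seq_len(nrep)) {
    up <- buildHelix(CrickParams(R = 0, omega0 = 0, length = helixLen))
    dn <- buildHelix(CrickParams(R = 0, omega0 = 0, length = helixLen,
                                 inverted = TRUE))
    aUp <- atoms(applyTransform(up, Transform(diag(3),
                                              c((r - 1) * spacing, 0, 0))))
    aDn <- atoms(applyTransform(dn, Transform(diag(3),
                                              c((r - 1) * spacing + 5, 4.5, 0))))
    aUp$resi <- aUp$resi + resOff
    resOff <- resOff + helixLen
    aDn$resi <- aDn$resi + resOff
    resOff <- resOff + helixLen
    aUp$chain <- aDn$chain <- "A"
    pieces[[length(pieces) + 1L]] <- rbind(aUp, aDn)
  }
  model <- new("BackboneModel", atoms = do.call(rbind, pieces),
               metadata = list(generator = "fixtureToyDHR",
                               note = "synthetic repeat block; helices are
 not loop-connected"))
  nWin <- seq_len(helixLen)                 # first helix
  cWin <- resOff - helixLen + seq_len(helixLen) # last helix
  list(kind = "toy-dhr", model = model,
       sites = list(nTerm = spliceSite("A", "N", nWin),
                    cTerm = spliceSite("A", "C", cWin)),
       manifest = list(repeats = nrep, helixLen = helixLen,
                       repeatLen = 2L * helixLen,
                       spliceWindowLen = helixLen))
}

#' Write a fixture to disk
#'
#' Emits the fixture model as PDB plus a plain-text manifest of the planted
#' ground truth.
#'
#' @param fixture from \code{\link{makeFixture}}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeFixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pdb <- file.path(dir, paste0(fixture$kind, ".pdb"))
  writeModel(fixture$model, pdb)
  man <- file.path(dir, paste0(fixture$kind, ".manifest.txt"))
  lines <- c(paste0("kind = ", fixture$kind),
             vapply(names(fixture$manifest), function(k) {
               v <- fixture$manifest[[k]]
               if (is.data.frame(v))
                 v <- paste(apply(v, 1, paste, collapse = ":"),
                            collapse = " ")
               paste0(k, " = ", paste(unlist(v), collapse = " "))
             }, character(1)))
  writeLines(lines, man)
  invisible(c(pdb, man))
}
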