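# Heptad register assignment, N/P search masks and rule-based layer design.

HEPTAD <- letters[1:7]

# One-letter amino acid alphabets for layer design. Only the two-Phe rule is
# a published constraint; the alphabets are standard layer-design choices.
CORE_ALPHABET <- c("A", "I", "L", "V", "F", "M", "W")
SURFACE_ALPHABET <- c("E", "K", "R", "D", "Q", "N", "S", "T")
BOUNDARY_ALPHABET <- setdiff(union(CORE_ALPHABET, SURFACE_ALPHABET), "W")

# Mean CA pseudo-dihedral of an alpha-helical trace is ~ +50 degrees.
assertHelical <- function(ca, chain) {
  n <- nrow(ca)
  if (n < 7) stop("chain ", chain, " too short for register assignment")
  dih <- vapply(seq_len(n - 3), function(i)
    dihedral4(ca[i, ], ca[i + 1, ], ca[i + 2, ], ca[i + 3, ]), numeric(1))
  if (mean(dih) < 30 || mean(dih) > 70)
    stop("chain ", chain, " is not alpha-helical (mean CA pseudo-dihedral ",
         sprintf("%.1f", mean(dih)), " deg)")
}

#' Supercoil-local helical phase of each residue
#'
#' The phase of a residue about its own helix axis, measured in the frame
#' that co-rotates with the supercoil: \code{(omega1 * (i - 1) + dphi1)}
#' modulo 360. With the ideal twist of 102.85 degrees per residue this phase
#' repeats every 7 residues to within 0.05 degrees — the heptad periodicity.
#'
#' @param params a \linkS4class{CrickParams}
#' @return numeric vector of phases in [0, 360)
#' @export
localPhases <- function(params) {
  (params@omega1 * (seq_len(params@length) - 1) + params@dphi1) %% 360
}

#' Assign heptad register letters
#'
#' In each chain the residue whose CA-to-CB vector points most directly at
#' the bundle axis anchors letter 'a'; letters then advance cyclically
#' a, b, ..., g with residue index. The anchoring offset is chosen to
#' maximize the mean axis alignment over all residues that receive letter
#' 'a'. Core-facing positions are the letters in \code{coreLetters}: a and d
#' by classical coiled-coil geometry, plus g, which participates in the
#' packed core at trimeric interfaces.
#'
#' @param model a \linkS4class{BackboneModel} with CB atoms
#' @param axis bundle (supercoil) axis direction
#' @param axisPoint a point on the axis
#' @param coreLetters letters flagged core-facing
#' @return data.frame (chain, resi, letter, heptad, core)
#' @examples
#' b <- assembleBundle(BundleSpec(lapply(c(0, 120, 240), function(p)
#'   CrickParams(dphi0 = p, length = 21))))
#' table(assignRegister(b)$letter)
#' @export
assignRegister <- function(model, axis = c(0, 0, 1),
                           axisPoint = c(0, 0, 0),
                           coreLetters = c("a", "d", "g")) {
  axis <- unitv(axis)
  a <- atoms(model)
  out <- list()
  for (ch in chainIds(model)) {
    b <- a[a$chain == ch, ]
    resis <- sort(unique(b$resi))
    ca <- as.matrix(b[b$elety == "CA", c("x", "y", "z")][order(b$resi[b$elety == "CA"]), ])
    cb <- as.matrix(b[b$elety == "CB", c("x", "y", "z")][order(b$resi[b$elety == "CB"]), ])
    if (nrow(cb) != nrow(ca))
      stop("chain ", ch, " is missing CB atoms for register assignment")
    assertHelical(ca, ch)
    # cosine of the angle between CA->CB and CA->axis-foot, per residue
    align <- vapply(seq_len(nrow(ca)), function(i) {
      p <- ca[i, ]
      foot <- axisPoint + sum((p - axisPoint) * axis) * axis
      toAxis <- foot - p
      if (vnorm(toAxis) < 1e-6) return(1)
      sum(unitv(cb[i, ] - p) * unitv(toAxis))
    }, numeric(1))
    scores <- vapply(0:6, function(o)
      mean(align[(seq_along(resis) - 1L) %% 7L == o]), numeric(1))
    best <- which.max(scores) - 1L
    letter <- HEPTAD[((seq_along(resis) - 1L - best) %% 7L) + 1L]
    out[[length(out) + 1L]] <- data.frame(
      chain = ch, resi = resis, letter = letter,
      heptad = ((seq_along(resis) - 1L) %/% 7L) + 1L,
      core = letter %in% coreLetters, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Attach register letters to a model
#' @param model a \linkS4class{BackboneModel}
#' @param annotation output of \code{\link{assignRegister}}
#' @return the model with its register slot filled
#' @export
setRegister <- function(model, annotation) {
  new("BackboneModel", atoms = model@atoms,
      register = annotation[, c("chain", "resi", "letter")],
      metadata = model@metadata)
}

#' Build an N/P heptad search mask
#'
#' Classifies each heptad of each chain as nonpolar (N) or polar-searchable
#' (P) according to \code{pattern}, a string such as "NPNPNPNPN" (the
#' coiled-coil search) or "NPPPN" (the six-helix bundle search). Patterns
#' shorter than the chain are centered on its heptads, ties broken toward
#' the N terminus; heptads outside the pattern are N. Searchable positions
#' are the core-facing residues of P heptads.
#'
#' @param annotation output of \code{\link{assignRegister}}
#' @param pattern character string of N and P
#' @return data.frame (chain, resi, letter, heptad, polarity, searchable)
#' @export
buildSearchMask <- function(annotation, pattern) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  if (!all(pat %in% c("N", "P"))) stop("pattern must contain only N and P")
  out <- list()
  for (ch in unique(annotation$chain)) {
    ann <- annotation[annotation$chain == ch, ]
    nhept <- max(ann$heptad)
    if (length(pat) > nhept)
      stop("pattern (", length(pat), " heptads) longer than chain ", ch,
           " (", nhept, " heptads)")
    offset <- floor((nhept - length(pat)) / 2)
    pol <- rep("N", nhept)
    pol[offset + seq_along(pat)] <- pat
    ann$polarity <- pol[ann$heptad]
    ann$searchable <- ann$polarity == "P" & ann$core
    out[[length(out) + 1L]] <- ann
  }
  do.call(rbind, out)[, c("chain", "resi", "letter", "heptad", "core",
                          "polarity", "searchable")]
}

#' Rule-based layer sequence assignment
#'
#' Assigns an amino acid to every position by burial class, holding
#' hydrogen-bond-network positions fixed: core-facing non-network positions
#' get nonpolar residues with at least \code{minPhe} phenylalanines per
#' design (placed at the most buried core positions), N-heptad core
#' positions are fully nonpolar, surface positions (letters b, c, f) get
#' charged residues alternating Glu/Lys, and remaining boundary positions
#' get alanine. A network position that the mask also demands nonpolar is
#' kept as the network residue, with a warning.
#'
#' @param model a \linkS4class{BackboneModel}
#' @param mask output of \code{\link{buildSearchMask}}
#' @param networkPositions data.frame (chain, resi, type) of fixed network
#'   residues; one-letter types
#' @param minPhe minimum phenylalanine count at the core
#' @param axis,axisPoint bundle axis (for burial ranking of Phe placement)
#' @return data.frame (chain, resi, letter, layer, aa)
#' @export
layerSequence <- function(model, mask, networkPositions = NULL,
                          minPhe = 2, axis = c(0, 0, 1),
                          axisPoint = c(0, 0, 0)) {
  axis <- unitv(axis)
  net <- networkPositions
  if (is.null(net)) net <- data.frame(chain = character(), resi = integer(),
                                      type = character())
  netKey <- paste(net$chain, net$resi)
  df <- mask
  df$layer <- ifelse(df$core, "core",
                     ifelse(df$letter %in% c("b", "c", "f"),
                            "surface", "boundary"))
  df$aa <- NA_character_
  isNet <- paste(df$chain, df$resi) %in% netKey
  conflict <- isNet & df$layer == "core" & df$polarity == "N"
  if (any(conflict))
    warning(sum(conflict), " network position(s) fall in nonpolar heptads; ",
            "network residues kept")
  df$aa[isNet] <- net$type[match(paste(df$chain, df$resi)[isNet], netKey)]
  df$layer[isNet] <- "network"
  df$aa[!isNet & df$layer == "core"] <- "L"
  df$aa[!isNet & df$layer == "boundary"] <- "A"
  surf <- !isNet & df$layer == "surface"
  df$aa[surf] <- ifelse(df$resi[surf] %% 2 == 0, "E", "K")
  # enforce the minimum phenylalanine count at the most buried core positions
  ca <- caCoords(model)
  key <- paste0(df$chain, df$resi)
  axDist <- vapply(seq_len(nrow(df)), function(i) {
    p <- ca[key[i], ]
    vnorm((p - axisPoint) - sum((p - axisPoint) * axis) * axis)
  }, numeric(1))
  coreFree <- which(!isNet & df$layer == "core")
  nPhe <- sum(df$aa[coreFree] == "F")
  if (nPhe < minPhe && length(coreFree)) {
    ord <- coreFree[order(axDist[coreFree])]
    take <- head(ord, min(minPhe - nPhe, length(ord)))
    df$aa[take] <- "F"
  }
  df[, c("chain", "resi", "letter", "layer", "aa")]
}
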