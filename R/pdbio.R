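# PDB input/output (through bio3d) and key-value run configuration.

#' Read a backbone model from a PDB file
#'
#' Reads ATOM records via bio3d, keeping the backbone heavy atoms (N, CA, C,
#' O, CB). Residues missing a CB (other than glycine) get one rebuilt from
#' the ideal residue frame; chains containing only CA atoms have their
#' N/C/O/CB completed by the same ideal-frame rule used by the generator.
#'
#' @param path PDB file
#' @return a \linkS4class{BackboneModel}
#' @export
readModel <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed PDB file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% c("N", "CA", "C", "O", "CB"), ]
  if (!nrow(at)) stop("no backbone ATOM records in ", path)
  at$chain[is.na(at$chain)] <- "A"
  df <- data.frame(chain = at$chain, resi = as.integer(at$resno),
                   resn = at$resid, elety = at$elety,
                   x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(df$chain)) {
    b <- df[df$chain == ch, ]
    if (all(b$elety == "CA") && nrow(b) >= 3) {
      ca <- as.matrix(b[order(b$resi), c("x", "y", "z")])
      # quadratic extrapolation keeps the flank off the terminal CA-CA line
      n <- nrow(ca)
      flank0 <- 3 * ca[1, ] - 3 * ca[2, ] + ca[3, ]
      flank1 <- 3 * ca[n, ] - 3 * ca[n - 1, ] + ca[n - 2, ]
      comp <- completeFromCA(rbind(flank0, ca, flank1), chain = ch,
                             resn = b$resn[1])
      comp$resi <- sort(b$resi)[comp$resi]
      out[[length(out) + 1L]] <- comp
      next
    }
    for (r in sort(unique(b$resi))) {
      res <- b[b$resi == r, ]
      if (!"CB" %in% res$elety && res$resn[1] != "GLY" &&
          all(c("N", "CA", "C") %in% res$elety)) {
        g <- function(e) as.numeric(res[res$elety == e, c("x", "y", "z")][1, ])
        cb <- placeAtom(g("N"), g("C"), g("CA"), .BB$b_CACB, .BB$a_CCACB,
                        .BB$d_NCCACB)
        res <- rbind(res, data.frame(chain = ch, resi = r, resn = res$resn[1],
                                     elety = "CB", x = cb[1], y = cb[2],
                                     z = cb[3], stringsAsFactors = FALSE))
      }
      out[[length(out) + 1L]] <- res
    }
  }
  new("BackboneModel", atoms = do.call(rbind, out),
      metadata = list(source = path))
}

#' Write a backbone model as PDB
#'
#' ATOM records with 1-based residue numbering, TER between chains,
#' occupancy 1.00 and B-factor 0.00.
#'
#' @param model a \linkS4class{BackboneModel}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeModel <- function(model, path) {
  a <- atoms(model)
  ord <- order(match(a$chain, chainIds(model)), a$resi,
               match(a$elety, c("N", "CA", "C", "O", "CB")))
  a <- a[ord, ]
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resi, chain = a$chain,
                   resid = a$resn, elety = a$elety,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   chainter = TRUE)
  invisible(path)
}

#' Write a run configuration as key = value text
#'
#' @param config named list; CrickParams entries are expanded to their
#'   fields (degrees/Angstrom)
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeConfig <- function(config, path) {
  flat <- list()
  for (k in names(config)) {
    v <- config[[k]]
    if (is(v, "CrickParams"))
      v <- c(R = v@R, dphi0 = v@dphi0, dphi1 = v@dphi1, zOff = v@zOff,
             omega0 = v@omega0, omega1 = v@omega1, length = v@length,
             inverted = as.integer(v@inverted))
    if (!is.null(names(v)) && length(v) > 1) {
      for (kk in names(v))
        flat[[paste0(k, ".", kk)]] <- v[[kk]]
    } else flat[[k]] <- v
  }
  writeLines(vapply(names(flat), function(k)
    paste0(k, " = ", paste(flat[[k]], collapse = " ")), character(1)), path)
  invisible(path)
}

#' Read a key = value configuration file
#'
#' @param path file written by \code{\link{writeConfig}} or hand-edited in
#'   the same format; numeric values are converted
#' @return named list
#' @export
readConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- strsplit(val, "[[:space:]]+")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}
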