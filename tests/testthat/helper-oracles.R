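# Independent oracles and shared fixtures for the test suite.

# Horn's closed-form quaternion method for least-squares rotation: an
# algorithm genuinely different from the SVD route used by superpose().
hornSuperpose <- function(P, Q) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  A <- sweep(P, 2, pc)
  B <- sweep(Q, 2, qc)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  moved <- A %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((moved - B)^2))))
}

# Brute-force all-pairs hydrogen-bond oracle: loops over every donor and
# acceptor atom of every placement pair and re-derives the geometry from
# first principles (no shared code with detectHBonds beyond the criteria
# numbers).
bruteForceHBonds <- function(placements, distMin = 2.6, distMax = 3.3,
                             donorAngleMin = 120, acceptorAngleMin = 90) {
  ang <- function(a, b, c) {
    u <- (a - b) / sqrt(sum((a - b)^2))
    v <- (c - b) / sqrt(sum((c - b)^2))
    acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  }
  out <- list()
  for (i in seq_along(placements)) for (j in seq_along(placements)) {
    if (i == j) next
    pd <- placements[[i]]
    pa <- placements[[j]]
    if (pd$chain == pa$chain && pd$resi == pa$resi) next
    for (kd in seq_len(nrow(pd$donors))) for (ka in seq_len(nrow(pa$acceptors))) {
      d <- pd$atoms[pd$donors$atom[kd], ]
      dAnte <- pd$atoms[pd$donors$ante[kd], ]
      a <- pa$atoms[pa$acceptors$atom[ka], ]
      aAnte <- pa$atoms[pa$acceptors$ante[ka], ]
      dist <- sqrt(sum((d - a)^2))
      if (dist < distMin || dist > distMax) next
      if (ang(dAnte, d, a) < donorAngleMin) next
      if (ang(aAnte, a, d) < acceptorAngleMin) next
      out[[length(out) + 1L]] <- data.frame(
        donorId = i, donorAtom = pd$donors$atom[kd],
        acceptorId = j, acceptorAtom = pa$acceptors$atom[ka],
        distance = dist)
    }
  }
  if (!length(out))
    return(data.frame(donorId = integer(), donorAtom = character(),
                      acceptorId = integer(), acceptorAtom = character(),
                      distance = numeric()))
  do.call(rbind, out)
}

randomRotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

randomTransform <- function() {
  Transform(randomRotation(), rnorm(3, sd = 10))
}

# Shared fixtures, built once per test run.
.cache <- new.env()

c3Bundle <- function(len = 21, R = 7, dphi1 = 0) {
  key <- paste("c3", len, R, dphi1)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- assembleBundle(BundleSpec(lapply(c(0, 120, 240),
      function(p) CrickParams(R = R, dphi0 = p, dphi1 = dphi1, length = len))))
  .cache[[key]]
}

triadFixture <- function() {
  if (is.null(.cache$triad)) .cache$triad <- makeFixture("planted-triad")
  .cache$triad
}

# A small set of random polar placements scattered on a straight helix pair,
# used for the oracle-equivalence checks.
randomPlacementSet <- function(seed, n = 6) {
  set.seed(seed)
  h <- c3Bundle(len = 14, R = 6.5)
  sites <- expand.grid(chain = c("A", "B", "C"), resi = c(4, 7, 11),
                       stringsAsFactors = FALSE)
  pls <- list()
  for (k in sample(nrow(sites), min(n, nrow(sites)))) {
    cand <- enumerateRotamers(h, sites$chain[k], sites$resi[k],
                              types = sample(c("S", "T", "N", "Q", "D",
                                               "E", "Y", "H", "W"), 3))
    if (length(cand)) pls[[length(pls) + 1L]] <- cand[[sample(length(cand), 1)]]
  }
  pls
}
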