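test_that("degenerate supercoil gives a straight ideal alpha-helix", {
  h <- buildHelix(CrickParams(R = 0, omega0 = 0, omega1 = 102.85,
                              length = 14))
  ca <- caCoords(h)
  radii <- sqrt(ca[, 1]^2 + ca[, 2]^2)
  expect_equal(radii, rep(2.26, 14), tolerance = 1e-9, ignore_attr = TRUE)
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))
})

test_that("supercoil phase shift of 120 degrees is a 120 degree rotation", {
  p <- CrickParams(R = 7, omega0 = -2.85, omega1 = 102.85, length = 77)
  h1 <- buildHelix(p)
  p2 <- p
  p2@dphi0 <- p@dphi0 + 120
  h2 <- buildHelix(p2)
  rotated <- applyTransform(h1, axisRotation(c(0, 0, 1), 120))
  expect_lt(rmsdRaw(coords(rotated), coords(h2)), 1e-9)
})

test_that("supercoil-local phase repeats with heptad period", {
  p <- CrickParams(R = 7, omega0 = -2.85, omega1 = 102.85, length = 77)
  ph <- localPhases(p)
  dphase <- (ph[8:77] - ph[1:70]) %% 360
  dphase <- pmin(dphase, 360 - dphase)
  expect_true(all(dphase < 0.2))
})

test_that("helical twist of 102.85 deg/res gives 3.5 residues per turn", {
  expect_equal(360 / 102.85, 3.5, tolerance = 5e-4)
})

test_that("generated backbones have sane peptide geometry", {
  for (p in list(CrickParams(R = 0, omega0 = 0, length = 14),
                 CrickParams(R = 7, dphi1 = -60, length = 77),
                 CrickParams(R = 13, dphi1 = 40, length = 35))) {
    h <- buildHelix(p)
    steps <- sqrt(rowSums(diff(caCoords(h))^2))
    expect_true(all(abs(steps - 3.80) < 0.15))
    pp <- phiPsi(h)
    expect_true(all(abs(pp$phi + 60) < 20, na.rm = TRUE))
    expect_true(all(abs(pp$psi + 45) < 20, na.rm = TRUE))
  }
})

test_that("build is deterministic and zOff acts as a pure z translation", {
  p <- CrickParams(R = 7, dphi1 = 20, length = 21)
  expect_identical(coords(buildHelix(p)), coords(buildHelix(p)))
  pz <- p
  pz@zOff <- 2.5
  expect_equal(coords(buildHelix(pz)),
               sweep(coords(buildHelix(p)), 2, c(0, 0, 2.5), `+`),
               tolerance = 1e-12)
})

test_that("negative supercoil twist winds left-handed", {
  h <- buildHelix(CrickParams(R = 7, omega0 = -2.85, length = 77))
  tr <- supercoilTrace(h)
  crossZ <- sum(vapply(seq_len(nrow(tr) - 1), function(i)
    tr[i, 1] * tr[i + 1, 2] - tr[i, 2] * tr[i + 1, 1], numeric(1)))
  expect_lt(crossZ, 0) # clockwise seen down +z
})

test_that("C3 bundles are C3-symmetric and antiparallel helices flip", {
  b <- c3Bundle(len = 21)
  rot <- applyTransform(b, axisRotation(c(0, 0, 1), 120))
  perm <- rbind(caCoords(b, "B"), caCoords(b, "C"), caCoords(b, "A"))
  expect_lt(rmsdRaw(rbind(caCoords(rot, "A"), caCoords(rot, "B"),
                          caCoords(rot, "C")), perm), 1e-6)

  spec <- BundleSpec(list(
    CrickParams(dphi0 = 0, length = 21),
    CrickParams(dphi0 = 120, length = 21),
    CrickParams(dphi0 = 240, length = 21, inverted = TRUE)))
  ab <- assembleBundle(spec)
  caA <- caCoords(ab, "A")
  caC <- caCoords(ab, "C")
  expect_lt(caA[1, 3], caA[21, 3])  # parallel helix runs up
  expect_gt(caC[1, 3], caC[21, 3])  # inverted helix runs down
})

test_that("outer helices sit at larger radius than inner ones", {
  spec <- BundleSpec(c(
    lapply(c(0, 120, 240), function(p) CrickParams(R = 7, dphi0 = p,
                                                   length = 35)),
    lapply(c(60, 180, 300), function(p) CrickParams(R = 13, dphi0 = p,
                                                    length = 35))))
  b <- assembleBundle(spec)
  radial <- function(ch) {
    ca <- caCoords(b, ch)
    mean(sqrt(ca[, 1]^2 + ca[, 2]^2))
  }
  inner <- vapply(c("A", "B", "C"), radial, numeric(1))
  outer <- vapply(c("D", "E", "F"), radial, numeric(1))
  expect_true(all(outer - inner > 5))
})

test_that("axis clashes are warnings in metadata, not failures", {
  spec <- BundleSpec(list(CrickParams(R = 2, dphi0 = 0, length = 21),
                          CrickParams(R = 2, dphi0 = 120, length = 21)))
  b <- assembleBundle(spec)
  expect_true(length(b@metadata$warnings) > 0)
})

test_that("invalid Crick parameters are rejected", {
  expect_error(buildHelix(CrickParams(length = 5)), "length")
  expect_error(CrickParams(R = NaN), "finite")
  expect_error(CrickParams(R = -1), "R must")
})
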