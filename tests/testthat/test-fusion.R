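test_that("splicing a helix onto itself has zero best overlap RMSD", {
  h <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 21))
  sols <- enumerateSplices(h, spliceSite("A", "C", 8:21),
                           h, spliceSite("A", "N", 1:14),
                           maxDeleteA = 0, maxDeleteB = 0)
  expect_equal(sols[[1]]$rmsd, 0, tolerance = 1e-6)
})

test_that("deletion limits are enforced and solutions sorted by RMSD", {
  fx <- makeFixture("toy-dhr")
  blk <- fx$model
  tri <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 21))
  sols <- enumerateSplices(tri, spliceSite("A", "C", 1:21),
                           blk, fx$sites$nTerm,
                           maxDeleteA = 7, maxDeleteB = 16)
  expect_true(all(vapply(sols, `[[`, numeric(1), "deleteA") <= 7))
  expect_true(all(vapply(sols, `[[`, numeric(1), "deleteB") <= 16))
  rmsds <- vapply(sols, `[[`, numeric(1), "rmsd")
  expect_false(is.unsorted(rmsds))
  expect_error(
    enumerateSplices(tri, spliceSite("A", "C", 18:21),
                     blk, fx$sites$nTerm, minOverlap = 8,
                     maxDeleteA = 0, maxDeleteB = 0),
    "no overlap")
})

test_that("perturbed splice RMSD matches a brute-force oracle within 10%", {
  h <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 21))
  set.seed(31)
  a <- atoms(h)
  a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) +
    matrix(rnorm(nrow(a) * 3, sd = 0.3), ncol = 3)
  hNoisy <- new("BackboneModel", atoms = a)
  sols <- enumerateSplices(hNoisy, spliceSite("A", "C", 8:21),
                           h, spliceSite("A", "N", 1:14),
                           maxDeleteA = 0, maxDeleteB = 0)
  best <- sols[[1]]$rmsd
  # oracle: exhaustively fit every equal-length window pair with the
  # quaternion method and take the smallest RMSD
  oracle <- Inf
  for (ov in 8:14) {
    P <- BundleForge:::windowCoords(h, "A", seq_len(ov))
    Q <- BundleForge:::windowCoords(hNoisy, "A", 21 - ov + seq_len(ov))
    oracle <- min(oracle, hornSuperpose(P, Q)$rmsd)
  }
  expect_lt(abs(best - oracle) / oracle, 0.10)
})

test_that("closure error has its closed forms", {
  probe <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 14))
  expect_equal(ringClosureError(axisRotation(c(0, 0, 1), 120), 3, probe), 0,
               tolerance = 1e-9)
  # pure axial accumulation: delta per step gives exactly n * delta
  tf <- axisRotation(c(0, 0, 1), 120, shift = c(0, 0, 1))
  expect_equal(ringClosureError(tf, 3, probe), 3, tolerance = 1e-9)
  # wrong symmetry order: T^3 for a 90 degree step is a 270 vs 360 rotation
  t90 <- axisRotation(c(0, 0, 1), 90)
  direct <- rmsdRaw(caCoords(probe),
                    applyTransform(caCoords(probe),
                                   axisRotation(c(0, 0, 1), 270)))
  expect_equal(ringClosureError(t90, 3, probe), direct, tolerance = 1e-9)
  expect_gte(ringClosureError(t90, 3, probe), 0)
})

test_that("the exact C3 wedge closes as C3 and fails as C4", {
  fx <- makeFixture("c3-wedge")
  ring <- buildRing(fx$model, fx$transform, 3,
                    ringThresholds(maxCloseErr = 1e-6, maxClashes = 0))
  expect_true(ring@accepted)
  expect_lt(ring@closeErr, 1e-6)
  expect_equal(ring@clashCount, 0L)
  expect_length(chainIds(ring@ring), 6) # three copies of a two-chain unit
  # closed ring is invariant under rotation by 360/n (copies permute)
  rot <- applyTransform(ring@ring, axisRotation(c(0, 0, 1), 120))
  nUnit <- nrow(caCoords(fx$model))
  expect_lt(rmsdRaw(caCoords(rot)[seq_len(2 * nUnit), ],
                    caCoords(ring@ring)[nUnit + seq_len(2 * nUnit), ]),
            1e-6)

  asC4 <- buildRing(fx$model, fx$transform, 4,
                    ringThresholds(maxCloseErr = 1e-6, maxClashes = 0))
  expect_false(asC4@accepted)
  expect_true("close_err" %in% asC4@reasons)

  open <- buildRing(fx$model, fx$transform, 4,
                    ringThresholds(maxCloseErr = Inf, maxClashes = Inf,
                                   maxChainLen = Inf))
  expect_true(open@accepted) # infinite thresholds pass everything
})

test_that("ring score tables carry the three filter fields", {
  fx <- makeFixture("c3-wedge")
  tab <- ringScoreTable(list(
    buildRing(fx$model, fx$transform, 3),
    buildRing(fx$model, fx$transform, 4)))
  expect_named(tab, c("symmetry", "chain_len", "score0", "close_err",
                      "accepted"))
  expect_equal(tab$accepted, c(TRUE, FALSE))
})
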