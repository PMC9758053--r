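test_that("published grid dimensions enumerate to the printed counts", {
  expect_length(gridSeq(-100, 100, 20), 11)
  expect_length(gridSeq(6.5, 7.5, 0.25), 5)
  expect_length(gridSeq(6.5, 7.25, 0.375), 3)
  expect_length(gridSeq(12.25, 13.25, 0.5), 3)
  expect_equal(gridSize(coiledCoilGrid()), (11 * 5)^3 * 3^2) # 1,497,375
  expect_equal(gridSize(coiledCoilGrid()), 1497375)
})

test_that("grid enumeration is lexicographic, complete and resumable", {
  g <- paramGrid(phases = c(0, 120, 240), dphi1 = c(-20, 0, 20),
                 R = c(6.5, 7), zOff = c(-1.5, 0, 1.5), length = 21)
  n <- gridSize(g)
  expect_equal(n, (3 * 2 * 1) * (3 * 2 * 3)^2)
  keys <- vapply(gridSpecs(g), BundleForge:::specKey, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_length(keys, n)
  # restartable: re-decoding the same indices reproduces the same specs
  idx <- c(1, 17, n)
  again <- vapply(gridSpecs(g, idx), BundleForge:::specKey, character(1))
  expect_identical(again, keys[idx])
  # first helix anchors the axial frame
  expect_true(all(vapply(gridSpecs(g, 1:20), function(s)
    s@helices[[1]]@zOff == 0, logical(1))))
})

test_that("stage-1 grid matches the published bundle search dimensions", {
  g <- bundleStage1Grid()
  expect_equal(g@phases, c(0, 120, 240, 60))
  expect_equal(g@length, 35L)
  expect_equal(gridSize(g), (11 * 3) * (11 * 3 * 3)^2 * (11 * 3 * 3))
})

test_that("pass-through and fail-all callbacks bound the staged search", {
  tiny <- paramGrid(phases = c(0, 120, 240, 60),
                    dphi1 = 0, R = list(7, 7, 7, 12.75),
                    zOff = list(0, c(-1.5, 0), 0, 0), length = 35)
  og2 <- list(phase = 180, dphi1 = c(-20, 20), R = 12.75, zOff = 0,
              inverted = FALSE)
  og3 <- list(phase = 300, dphi1 = 0, R = c(12.25, 13.25), zOff = 0,
              inverted = FALSE)
  res <- stepwiseBundleSearch(tiny, og2, og3, function(spec) TRUE)
  expect_length(res[[1]]$specs, 2)       # full stage-1 grid survives
  expect_length(res[[2]]$specs, 2 * 2)   # times the new helix grid
  expect_length(res[[3]]$specs, 4 * 2)
  # chains labelled inner A-C, outer D-F in phase order
  expect_equal(res[[3]]$specs[[1]]@chainMap, c("A", "B", "C", "D", "E", "F"))

  res0 <- stepwiseBundleSearch(tiny, og2, og3, function(spec) FALSE)
  expect_length(res0[[1]]$specs, 0)
  expect_length(res0[[2]]$specs, 0)
  expect_length(res0[[3]]$specs, 0)
})

test_that("tightening the network test never enlarges a stage result", {
  tiny <- paramGrid(phases = c(0, 120, 240, 60),
                    dphi1 = list(c(-20, 20), 0, 0, 0),
                    R = list(7, 7, 7, 12.75),
                    zOff = list(0, c(-1.5, 0), 0, 0), length = 35)
  og2 <- list(phase = 180, dphi1 = 0, R = 12.75, zOff = c(-1.5, 0),
              inverted = FALSE)
  og3 <- list(phase = 300, dphi1 = 0, R = 12.75, zOff = 0, inverted = FALSE)
  loose <- function(spec) spec@helices[[1]]@dphi1 >= -20
  tight <- function(spec) spec@helices[[1]]@dphi1 >= -20 &&
    spec@helices[[2]]@zOff == 0
  rl <- stepwiseBundleSearch(tiny, og2, og3, loose)
  rt <- stepwiseBundleSearch(tiny, og2, og3, tight)
  for (s in 1:3) {
    keysL <- vapply(rl[[s]]$specs, BundleForge:::specKey, character(1))
    keysT <- vapply(rt[[s]]$specs, BundleForge:::specKey, character(1))
    expect_true(all(keysT %in% keysL))
  }
})

test_that("callback failures propagate with the offending spec attached", {
  tiny <- paramGrid(phases = c(0, 120, 240), dphi1 = 0, R = 7, zOff = 0,
                    length = 21)
  expect_error(
    stepwiseBundleSearch(tiny, list(phase = 180, dphi1 = 0, R = 12.75,
                                    zOff = 0, inverted = FALSE),
                         list(phase = 300, dphi1 = 0, R = 12.75, zOff = 0,
                              inverted = FALSE),
                         function(spec) stop("boom")),
    "network test failed on spec")
})
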