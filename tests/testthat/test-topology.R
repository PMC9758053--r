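test_that("alternative species counts match the printed bookkeeping", {
  ab <- enumerateSpecies(c("A", "B"), 2, target = c("A", "B"))
  expect_equal(speciesCount(ab), 4)
  expect_setequal(speciesLabels(ab), c("A", "B", "AA", "BB"))

  abc <- enumerateSpecies(c("A", "B", "C"), 3, target = c("A", "B", "C"),
                          convention = "paper-trimer")
  expect_equal(speciesCount(abc), 15)
  expect_setequal(speciesLabels(abc),
                  c("A", "B", "C", "AB", "AC", "BC", "AAA", "BBB", "CCC",
                    "AAB", "ABB", "AAC", "ACC", "BBC", "BCC"))

  full <- enumerateSpecies(c("A", "B", "C"), 3)
  expect_equal(speciesCount(full), 3 + 6 + 10)
})

test_that("species counts follow the closed-form multiset formula", {
  for (k in 2:4) for (m in 1:3) {
    alpha <- LETTERS[seq_len(k)]
    target <- alpha[seq_len(min(m, k))]
    s <- enumerateSpecies(alpha, m, target = target)
    expected <- sum(vapply(seq_len(m), function(sz)
      choose(k + sz - 1, sz), numeric(1))) - 1
    expect_equal(speciesCount(s), expected)
  }
  expect_error(enumerateSpecies(character(), 2), "empty chain alphabet")
  expect_error(enumerateSpecies(c("A", "B"), 1, target = c("A", "B")),
               "target size")
})

test_that("heptad trimming reproduces the 49/63/77 chain lengths", {
  b <- c3Bundle(len = 77)
  trimmed <- trimChains(b, c(A = 4, B = 2))
  expect_equal(chainLengths(trimmed), c(A = 49L, B = 63L, C = 77L))
  expect_equal(chainLengths(trimChains(b, c(A = 0, B = 0, C = 0))),
               chainLengths(b))
  expect_error(trimChains(b, c(A = 11)), "remove all")
})

test_that("trimming composes additively and preserves register letters", {
  b <- c3Bundle(len = 77)
  withReg <- setRegister(b, assignRegister(b))
  once <- trimChains(withReg, c(A = 3))
  twice <- trimChains(once, c(A = 1))
  direct <- trimChains(withReg, c(A = 4))
  expect_equal(chainLengths(twice), chainLengths(direct))
  expect_equal(atoms(twice), atoms(direct), ignore_attr = TRUE)
  regA <- registerTable(direct)
  regA <- regA[regA$chain == "A", ]
  full <- registerTable(withReg)
  expect_equal(regA$letter, full$letter[full$chain == "A"][1:49])
})

test_that("N-terminal trims renumber from 1", {
  b <- c3Bundle(len = 77)
  t2 <- trimChains(b, c(B = 2), end = "N")
  resB <- sort(unique(atoms(t2)$resi[atoms(t2)$chain == "B"]))
  expect_equal(resB, 1:63)
})

test_that("hairpin pairing conventions are the two printed matchings", {
  cw <- hairpinPairings("clockwise")
  expect_equal(cw$pairs, list(c("A", "D"), c("B", "E"), c("C", "F")))
  ccw <- hairpinPairings("counterclockwise")
  expect_equal(ccw$pairs, list(c("A", "F"), c("B", "E"), c("C", "D")))
  for (scheme in list(cw, ccw)) {
    touched <- unlist(scheme$pairs)
    expect_setequal(touched, LETTERS[1:6])
    expect_equal(anyDuplicated(touched), 0L)
  }
  expect_error(hairpinPairings("widdershins"))
})

test_that("loop feasibility follows the per-residue span rule", {
  # two short parallel helices whose termini sit ~8 A apart at one end
  h1 <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 14), chain = "A")
  h2 <- applyTransform(
    buildHelix(CrickParams(R = 0, omega0 = 0, length = 14, inverted = TRUE),
               chain = "D"),
    Transform(diag(3), c(8, 0, 0)))
  m <- new("BackboneModel", atoms = rbind(atoms(h1), atoms(h2)))
  scheme <- list(pairs = list(c("A", "D")), direction = "clockwise",
                 loopSide = "same-side")
  rep1 <- loopFeasibility(m, scheme)
  expect_equal(nrow(rep1), 2)   # both join directions reported
  expect_true(any(rep1$feasible))

  # an antiparallel pair with staggered lengths is joinable at one end only
  short <- applyTransform(
    buildHelix(CrickParams(R = 0, omega0 = 0, length = 7, inverted = TRUE),
               chain = "D"),
    Transform(diag(3), c(8, 0, 30)))
  h21 <- buildHelix(CrickParams(R = 0, omega0 = 0, length = 21), chain = "A")
  mStag <- new("BackboneModel", atoms = rbind(atoms(h21), atoms(short)))
  repStag <- loopFeasibility(mStag, scheme)
  expect_true(repStag$feasible[repStag$from == "A"])
  expect_false(repStag$feasible[repStag$from == "D"])

  far <- applyTransform(h2, Transform(diag(3), c(0, 0, 120)))
  mFar <- new("BackboneModel", atoms = rbind(atoms(h1), atoms(far)))
  repFar <- loopFeasibility(mFar, scheme)
  expect_false(any(repFar$feasible))

  # d_max rule: an 8 A gap needs no more than a 2-residue loop
  expect_true(all(rep1$minLoopLen[rep1$feasible] <= 2 |
                    rep1$distance[rep1$feasible] > 3.3 * 3))
})
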