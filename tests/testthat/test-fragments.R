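test_that("single-cut fragment masses of small molecules", {
  ethane <- parseSmiles("CC")[[1]]
  p <- enumerateFragments(ethane, maxBonds = 1)
  # the single C-C cut yields two identical CH3 fragments, deduplicated
  expect_equal(as.numeric(p), c(15.0235, 30.0470), tolerance = 1e-3)

  ethanol <- parseSmiles("CCO")[[1]]
  p <- enumerateFragments(ethanol, maxBonds = 1)
  expect_equal(as.numeric(p),
               c(15.0235, 17.0027, 29.0391, 31.0184, 46.0419),
               tolerance = 1e-3)
})

test_that("ring bonds only fragment when the graph disconnects", {
  benzene <- parseSmiles("c1ccccc1")[[1]]
  p1 <- enumerateFragments(benzene, maxBonds = 1)
  expect_length(p1, 1L)                         # parent only
  expect_equal(as.numeric(p1), 78.0470, tolerance = 1e-3)
  p2 <- enumerateFragments(benzene, maxBonds = 2)
  # two ring cuts split the cycle into CkHk arcs, k = 1..5, plus parent
  chMass <- 12 + 1.007825
  expect_equal(as.numeric(p2), chMass * 1:6, tolerance = 1e-3)
})

test_that("pattern invariants: parent present, sorted, bounded", {
  mols <- makeCompoundSet(15, seed = 3)
  for (m in mols) {
    p <- enumerateFragments(m, maxBonds = 2)
    expect_true(all(diff(p) > 0))
    expect_equal(max(p), attr(p, "parent_mass"), tolerance = 1e-9)
    expect_true(all(p <= attr(p, "parent_mass") + 1e-4))
    # monotonicity in maxBonds: k-bond pattern nests in the (k+1)-bond one
    p1 <- enumerateFragments(m, maxBonds = 1)
    expect_true(all(vapply(p1, function(x) min(abs(p - x)) < 1e-9,
                           logical(1))))
  }
})

test_that("fragment enumeration matches the brute-force oracle", {
  mols <- makeCompoundSet(12, seed = 11)
  small <- Filter(function(m) sum(m$elements != "H") <= 12, mols)
  expect_gte(length(small), 5L)
  for (m in small) {
    for (k in 0:2) {
      got <- as.numeric(enumerateFragments(m, maxBonds = k))
      want <- bruteForceFragments(m, maxBonds = k)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("single-bond cuts conserve mass", {
  mols <- makeCompoundSet(10, seed = 5)
  for (m in mols) {
    parent <- m$exact_mass + m$charge * metaboMatch:::.ELECTRON
    for (pair in singleCutMassPairs(m))
      expect_equal(sum(pair), parent, tolerance = 1e-6)
  }
})

test_that("explicit-hydrogen cleavage is opt-in", {
  ethanol <- parseSmiles("CCO")[[1]]
  pNoH <- enumerateFragments(ethanol, maxBonds = 2)
  pH <- enumerateFragments(ethanol, maxBonds = 2, cleaveH = TRUE)
  expect_gt(length(pH), length(pNoH))
  # OH fragment (17.0027) appears in both; bare O (15.9949) needs C-O
  # plus O-H cuts, so it only appears with explicit-H cleavage
  expect_false(any(abs(pNoH - 15.9949) < 1e-3))
  expect_true(any(abs(pH - 15.9949) < 1e-3))
})

test_that("disconnected structures are rejected", {
  salt <- parseSmiles("[Na+].[Cl-]")[[1]]
  expect_error(enumerateFragments(salt), "disconnected")
})
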