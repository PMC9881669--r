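test_that("toy compound sets are deterministic and distinct", {
  a <- makeCompoundSet(10, seed = 1)
  b <- makeCompoundSet(10, seed = 1)
  expect_identical(vapply(a, `[[`, character(1), "inchi"),
                   vapply(b, `[[`, character(1), "inchi"))
  big <- makeCompoundSet(100, seed = 2)
  keys <- vapply(big, `[[`, character(1), "inchikey")
  expect_equal(length(unique(keys)), 100L)
  expect_error(makeCompoundSet(10000, seed = 1), "between 1 and")
})

test_that("simulated spectra respect the noise specification", {
  mol <- parseSmiles("NC(CC(=O)O)C(=O)O")[[1]]   # aspartic acid
  pat <- enumerateFragments(mol, maxBonds = 2)
  clean <- simulateSpectrum(pat, kPeaks = 5, jitterSigma = 0, decoys = 0,
                            seed = 8)
  expect_s4_class(clean, "MergedSpectrum")
  expect_equal(sum(clean@peaks[, 2]), 1.0, tolerance = 1e-12)
  expect_equal(fragScore(clean, pat)$score, 1.0)
  # decoys only: nothing to match unless a decoy lands on a fragment
  noise <- simulateSpectrum(pat, kPeaks = 0, decoys = 6, seed = 9)
  expect_lte(fragScore(noise, pat, hCorrection = FALSE)$score, 0.35)
  # same seed, same spectrum
  s1 <- simulateSpectrum(pat, seed = 10)
  s2 <- simulateSpectrum(pat, seed = 10)
  expect_identical(s1@peaks, s2@peaks)
  expect_error(simulateSpectrum(pat, kPeaks = 0, decoys = 0), "zero")
})

test_that("toy sets regenerate byte-identically from one seed", {
  s1 <- makeToySet(n = 6, seed = 33)
  s2 <- makeToySet(n = 6, seed = 33)
  expect_identical(s1$truth, s2$truth)
  for (i in seq_along(s1$spectra))
    expect_identical(s1$spectra[[i]]@peaks, s2$spectra[[i]]@peaks)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeToySet(s1, d1); writeToySet(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # the MGF round-trips through the reader
  sp <- readSpectra(file.path(d1, "queries.mgf"))
  expect_length(sp, 6L)
  expect_equal(sp[[1]]@precursorMz, s1$spectra[[1]]@precursorMz,
               tolerance = 1e-6)
})

test_that("confusable benchmark pairs targets with nominal-mass decoys", {
  bm <- makeConfusableBenchmark(n = 30, nConfusable = 6, seed = 7)
  expect_equal(bm$params$nConfusable, 6L)
  expect_equal(sum(bm$truth$confusable), 6L)
  storeKeys <- vapply(bm$compounds, `[[`, character(1), "inchikey")
  expect_true(all(bm$truth$inchikey %in% storeKeys))
  # every confusable query has a same-nominal-mass store mate with a
  # different formula
  mass <- vapply(bm$compounds, `[[`, numeric(1), "exact_mass")
  form <- vapply(bm$compounds, `[[`, character(1), "formula")
  for (i in which(bm$truth$confusable)) {
    self <- match(bm$truth$inchikey[i], storeKeys)
    mates <- which(round(mass) == round(mass[self]) &
                     form != form[self])
    expect_gte(length(mates), 1L)
  }
})
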