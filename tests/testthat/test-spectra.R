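mgfText <- c(
  "BEGIN IONS", "TITLE=first", "PEPMASS=181.0707", "CHARGE=1+",
  "COLLISION_ENERGY=20",
  "100.0 5", "200.0 15", "END IONS", "",
  "BEGIN IONS", "TITLE=second", "PEPMASS=179.0561", "CHARGE=1-",
  "90.0 1", "END IONS")

test_that("MGF parsing captures precursor, polarity and peaks", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(mgfText, f)
  sp <- readSpectra(f, format = "mgf")
  expect_length(sp, 2L)
  expect_equal(sp[[1]]@precursorMz, 181.0707)
  expect_equal(sp[[1]]@polarity, "+")
  expect_equal(sp[[2]]@polarity, "-")
  expect_equal(sp[[1]]@collisionEnergy, 20)
  expect_equal(unname(sp[[1]]@peaks),
               cbind(c(100, 200), c(5, 15)), ignore_attr = TRUE)
  expect_equal(sp[[1]]@id, "first")
})

test_that("TSV peak lists read with supplied precursor", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("100.0\t5", "200.0\t15"), f)
  sp <- readSpectra(f, format = "tsv", precursorMz = 181.07)
  expect_length(sp, 1L)
  expect_equal(nrow(sp[[1]]@peaks), 2L)
})

test_that("merging combines close peaks by intensity-weighted mean", {
  s1 <- rawSpectrum(100.0, cbind(100.000, 1))
  s2 <- rawSpectrum(100.0, cbind(100.0005, 3))
  m <- mergeSpectra(list(s1, s2), mzMergeTol = 0.002)
  expect_equal(nrow(m@peaks), 1L)
  expect_equal(m@peaks[1, 1], (1 * 100.000 + 3 * 100.0005) / 4)
  expect_equal(m@peaks[1, 2], 1.0)
})

test_that("normalization sums to one and is idempotent", {
  s <- rawSpectrum(300, cbind(c(100, 150, 200), c(2, 3, 5)))
  m <- mergeSpectra(s)
  expect_equal(unname(m@peaks[, 2]), c(0.2, 0.3, 0.5))
  m2 <- mergeSpectra(rawSpectrum(m@precursorMz, m@peaks))
  expect_equal(m2@peaks, m@peaks, tolerance = 1e-12)
})

test_that("merging is permutation-invariant and polarity-strict", {
  set.seed(1)
  specs <- lapply(1:3, function(i)
    rawSpectrum(250, cbind(sort(runif(6, 50, 250)), runif(6))))
  a <- mergeSpectra(specs)
  b <- mergeSpectra(rev(specs))
  expect_equal(a@peaks, b@peaks, tolerance = 1e-12)
  neg <- rawSpectrum(250, cbind(100, 1), polarity = "-")
  expect_error(mergeSpectra(c(specs, neg)), "polarity")
})

test_that("adduct arithmetic matches known ion masses", {
  expect_equal(fragmentMz(180.0634, "[M+H]+"), 181.0707, tolerance = 1e-4)
  expect_equal(fragmentMz(180.0634, "[M-H]-"), 179.0561, tolerance = 1e-4)
  expect_equal(neutralMassFromPrecursor(181.0707, "[M+H]+"), 180.0634,
               tolerance = 1e-4)
  # mutual inverses for all shipped adducts
  for (a in names(metaboMatch:::.ADDUCTS)) {
    M <- 345.6789
    expect_equal(neutralMassFromPrecursor(fragmentMz(M, a), a), M,
                 tolerance = 1e-10)
  }
  # 13C isotopologue shift
  expect_equal(fragmentMz(100, "[M+H]+", n13C = 1) -
                 fragmentMz(100, "[M+H]+"), 1.003355)
  expect_error(adductSpec("[M+Xx]+"), "unknown adduct")
})
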