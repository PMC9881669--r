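mkSpec <- function(mz, inten, precursor = 300, adduct = "[M+H]+") {
  new("MergedSpectrum", precursorMz = precursor,
      polarity = if (grepl("\\+$", adduct)) "+" else "-", adduct = adduct,
      peaks = cbind(mz, inten / sum(inten)), id = "t")
}

test_that("frag score sums intensities of matched peaks", {
  # fragments at neutral 99 and 199; query peaks at their [M+H]+ ions
  sp <- mkSpec(c(100.007276, 250.0), c(0.6, 0.4))
  r <- fragScore(sp, c(99.0, 199.0), hCorrection = FALSE)
  expect_equal(r$score, 0.6)
  expect_equal(nrow(r$matched_peaks), 1L)
  expect_equal(r$matched_peaks$correction, 0L)
  # all peaks matched -> 1; none -> 0
  all <- fragScore(mkSpec(fragmentMz(c(99, 199), "[M+H]+"), c(1, 1)),
                   c(99, 199))
  expect_equal(all$score, 1.0)
  none <- fragScore(mkSpec(c(50, 60), c(1, 1)), c(99, 199))
  expect_equal(none$score, 0.0)
})

test_that("the hydrogen correction matches +/- 1 H shifted ions", {
  # predicted neutral fragment 100; query peak at the [M+H]+ ion of 101.0078
  sp <- mkSpec(102.015101, 1)
  off <- fragScore(sp, 100.0, hCorrection = FALSE)
  on <- fragScore(sp, 100.0, hCorrection = TRUE)
  expect_equal(off$score, 0)
  expect_equal(on$score, 1)
  expect_equal(on$matched_peaks$correction, 1L)
})

test_that("frag score is monotone in tolerance and correction", {
  set.seed(12)
  pat <- sort(runif(10, 50, 280))
  for (i in 1:20) {
    mz <- sort(runif(8, 50, 290))
    sp <- mkSpec(mz, runif(8))
    s1 <- fragScore(sp, pat, da = 0.005, hCorrection = FALSE)$score
    s2 <- fragScore(sp, pat, da = 0.05, hCorrection = FALSE)$score
    s3 <- fragScore(sp, pat, da = 0.05, hCorrection = TRUE)$score
    expect_lte(s1, s2); expect_lte(s2, s3)
    expect_gte(s1, 0); expect_lte(s3, 1)
  }
})

test_that("self-retrieval from a compound's own pattern scores 1", {
  mol <- parseSmiles("CC(O)C(N)C(=O)O")[[1]]   # threonine
  pat <- enumerateFragments(mol, maxBonds = 2)
  sp <- simulateSpectrum(pat, kPeaks = 6, jitterSigma = 0, decoys = 0,
                         seed = 4)
  expect_equal(fragScore(sp, pat)$score, 1.0)
})

test_that("spectrum featurization bins peaks deterministically", {
  fs <- featureSpec(binWidth = 1, mzMax = 100, neutralLoss = FALSE)
  sp <- mkSpec(50.5, 1, precursor = 80)
  v <- spectrumFeatures(sp, fs)
  expect_length(v, 100L)
  expect_equal(which(v > 0), 51L)                 # one-hot
  expect_equal(sum(v), 1.0)
  expect_identical(v, spectrumFeatures(sp, fs))
  # neutral-loss block doubles the length and also sums to 1 in range
  fs2 <- featureSpec(binWidth = 1, mzMax = 100, neutralLoss = TRUE)
  v2 <- spectrumFeatures(sp, fs2)
  expect_length(v2, 200L)
  expect_equal(sum(v2[1:100]), 1.0)
  expect_equal(which(v2[101:200] > 0), 30L)       # loss 80 - 50.5 = 29.5
})

test_that("Jaccard similarity handles the documented edge cases", {
  expect_equal(jaccardBits(c(1, 1, 0), c(1, 1, 0)), 1.0)
  expect_equal(jaccardBits(c(1, 0, 0), c(0, 1, 1)), 0.0)
  expect_equal(jaccardBits(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_equal(jaccardBits(c(0, 0), c(0, 0)), 1.0)   # both empty
  expect_equal(jaccardBits(c(1, 0, 1), c(1, 1, 1), positions = 1:2), 1 / 2)
})

test_that("TotalScore is the product of enabled scorers", {
  df <- data.frame(inchikey = c("B", "A"), delta_mass = c(0.001, -0.002))
  r <- combineAndRank(df, list(frag = c(0.5, 0.5), finger = c(0.8, 0.9)))
  expect_equal(sort(r$total_score, decreasing = TRUE), c(0.45, 0.40))
  expect_equal(r$rank, 1:2)
  expect_equal(r$inchikey[1], "A")
  expect_equal(r$relative_score[1], 1.0)
  # single scorer passes through unchanged
  one <- combineAndRank(df, list(frag = c(0.7, 0.2)))
  expect_equal(one$total_score, c(0.7, 0.2))
  expect_error(combineAndRank(df, list(frag = c(0.5, NA))), "missing")
  expect_error(combineAndRank(df, list(frag = c(1.5, 0.2))), "0, 1")
})

test_that("ties break deterministically by frag, mass delta, inchikey", {
  df <- data.frame(inchikey = c("C", "A", "B"),
                   delta_mass = c(0.002, 0.002, 0.001))
  r <- combineAndRank(df, list(frag = c(0.5, 0.5, 0.5),
                               finger = c(0.6, 0.6, 0.6)))
  expect_equal(r$inchikey, c("B", "A", "C"))
  # permutation property: ranks are 1..n whatever the input order
  r2 <- combineAndRank(df[c(3, 1, 2), ], list(
    frag = c(0.5, 0.5, 0.5)[c(3, 1, 2)],
    finger = c(0.6, 0.6, 0.6)[c(3, 1, 2)]))
  expect_equal(r2$inchikey, r$inchikey)
  expect_equal(sort(r2$rank), 1:3)
})

# --- finger models on wired marker-peak data -----------------------------

test_that("per-bit SVMs recover a constructed bit-to-peak wiring", {
  nBits <- 12; nTrain <- 60
  markers <- 60.5 + 10 * seq_len(nBits)   # bin centers at width 1
  set.seed(31)
  fps <- matrix(rbinom(nTrain * nBits, 1, 0.5), nTrain, nBits)
  fps[1, ] <- 1L  # guard against degenerate all-zero rows
  attr(fps, "layout_id") <- "wired"
  mkWired <- function(bits, seed) {
    set.seed(seed)
    mz <- markers[bits == 1L] + rnorm(sum(bits), 0, 0.002)
    mz <- c(mz, runif(2, 200, 280))          # noise peaks
    inten <- rexp(length(mz))
    o <- order(mz)
    new("MergedSpectrum", precursorMz = 300, polarity = "+",
        adduct = "[M+H]+",
        peaks = cbind(mz[o], (inten / sum(inten))[o]), id = "w")
  }
  spectra <- lapply(seq_len(nTrain), function(i) mkWired(fps[i, ], 100 + i))
  fspec <- featureSpec(binWidth = 1, mzMax = 310, neutralLoss = FALSE)
  mods <- trainFingerModels(spectra, fps, folds = 3, innerFolds = 2,
                            costs = c(1, 10), fspec = fspec, seed = 9)
  expect_s4_class(mods, "FingerModelSet")
  expect_gte(mean(mods@cvAccuracy), 0.95)
  # prediction on a fresh spectrum reproduces the fingerprint
  pred <- predictFingerprintBits(mods, mkWired(fps[5, ], 999))
  expect_equal(pred[mods@selectedBits], fps[5, mods@selectedBits])
  expect_equal(fingerScore(mkWired(fps[5, ], 999), fps[5, ], mods), 1.0)
})
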