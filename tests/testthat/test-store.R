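# A small store shared across tests in this file.
storeDir <- withr::local_tempdir(.local_envir = teardown_env())

smiFile <- file.path(storeDir, "three.smi")
writeLines(c("O\twater", "CC\tethane", "CCO\tethanol"), smiFile)
threeStore <- buildStore(smiFile, file.path(storeDir, "three.h5"),
                         layout = "toy", sourceDb = "toy")

test_that("building a store from SMILES records exact masses", {
  expect_equal(length(threeStore), 3L)
  expect_equal(threeStore@masses, c(18.0106, 30.0470, 46.0419),
               tolerance = 1e-3)
  man <- storeManifest(threeStore)
  expect_equal(man$compound_count, 3L)
  expect_equal(sum(man$fingerprint_layout$bits), 256L)
  expect_true(file.exists(paste0(threeStore@path, ".json")))
})

test_that("duplicate InChIs collapse to one record, first wins", {
  f <- file.path(storeDir, "dup.smi")
  # same ethanol twice as different SMILES spellings of one InChI
  writeLines(c("CCO\ta", "OCC\tb", "C\tc"), f)
  st <- suppressMessages(buildStore(f, file.path(storeDir, "dup.h5"),
                                    layout = "toy"))
  expect_equal(length(st), 2L)
  eth <- queryByMass(st, 46.0419, tol = 0.005, mode = "da")
  expect_equal(nrow(eth), 1L)
  expect_equal(eth$id, "a")
})

test_that("unparseable records are skipped with a count", {
  f <- file.path(storeDir, "bad.smi")
  writeLines(c("CCO\tok", "xx(yy\tbroken"), f)
  st <- suppressMessages(buildStore(f, file.path(storeDir, "bad.h5"),
                                    layout = "toy"))
  expect_equal(length(st), 1L)
  expect_equal(attr(st, "skipped"), 1L)
  empty <- file.path(storeDir, "empty.smi")
  writeLines(character(0), empty)
  expect_error(buildStore(empty, file.path(storeDir, "e.h5")),
               "no compounds")
})

test_that("mass-window retrieval honours ppm and Da semantics", {
  # 20 ppm around 400 Da is a +/- 0.008 Da window
  expect_equal(400 * 20e-6, 0.008)
  hits <- queryByMass(threeStore, 46.0419, tol = 0.005, mode = "da")
  expect_equal(hits$formula, "C2H6O")             # exactly ethanol
  none <- queryByMass(threeStore, 46.10, tol = 20, mode = "ppm")
  expect_equal(nrow(none), 0L)
  # degenerate window returns everything, ordered by |delta mass|
  all <- queryByMass(threeStore, 30.0, tol = 1e9, mode = "ppm")
  expect_equal(nrow(all), 3L)
  expect_equal(all$formula[1], "C2H6")
  expect_true(!is.unsorted(abs(all$delta_mass)))
})

test_that("window retrieval equals a linear scan (oracle equivalence)", {
  set <- makeCompoundSet(40, seed = 21)
  f <- file.path(storeDir, "forty.smi")
  writeLines(vapply(set, function(m) paste(m$smiles, m$id, sep = "\t"),
                    character(1)), f)
  st <- suppressMessages(buildStore(f, file.path(storeDir, "forty.h5"),
                                    layout = "toy"))
  masses <- vapply(set, function(m) m$exact_mass, numeric(1))
  for (target in c(120.05, 146.07, masses[7], 500)) {
    for (tolSpec in list(c(20, NA), c(0.3, NA), c(NA, 0.5))) {
      if (is.na(tolSpec[2])) {
        hits <- queryByMass(st, target, tol = tolSpec[1], mode = "ppm")
        half <- target * tolSpec[1] * 1e-6
      } else {
        hits <- queryByMass(st, target, tol = tolSpec[2], mode = "da")
        half <- tolSpec[2]
      }
      want <- sort(unique(
        vapply(set[abs(masses - target) <= half], `[[`, character(1),
               "inchikey")))
      expect_equal(sort(hits$inchikey), want)
    }
  }
})

test_that("get_record round-trips every stored field", {
  mols <- parseSmiles(c("O", "CC", "CCO"),
                      ids = c("water", "ethane", "ethanol"))
  fps <- computeFingerprints(mols, layout = "toy")
  for (i in seq_along(mols)) {
    r <- getRecord(threeStore, mols[[i]]$inchikey)
    expect_equal(r$inchi, mols[[i]]$inchi)
    expect_equal(r$formula, mols[[i]]$formula)
    expect_equal(r$exact_mass, mols[[i]]$exact_mass)
    expect_equal(r$charge, mols[[i]]$charge)
    # fingerprint compress/decompress is lossless
    expect_identical(r$fingerprint[[1]], unname(fps[i, ]))
    expect_equal(r$frag_pattern[[1]],
                 as.numeric(enumerateFragments(mols[[i]], maxBonds = 2)))
  }
  expect_error(getRecord(threeStore, "AAAAAAAAAAAAAA-BBBBBBBBBB-C"),
               "not found")
})

test_that("store builds are deterministic", {
  st2 <- buildStore(smiFile, file.path(storeDir, "three2.h5"),
                    layout = "toy", sourceDb = "toy")
  expect_identical(readLines(paste0(threeStore@path, ".json")),
                   readLines(paste0(st2@path, ".json")))
  expect_identical(threeStore@masses, st2@masses)
  k1 <- as.character(rhdf5::h5read(threeStore@path, "inchikey"))
  k2 <- as.character(rhdf5::h5read(st2@path, "inchikey"))
  rhdf5::h5closeAll()
  expect_identical(k1, k2)
})
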