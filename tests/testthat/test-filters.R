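cands <- data.frame(
  inchikey = c("K1", "K2", "K3"),
  formula = c("C6H12O6", "C7H16O5", "C6H13NO2"),
  stringsAsFactors = FALSE
)

test_that("formula filter is exact after Hill normalization", {
  expect_equal(filterFormula(cands, "C6H12O6")$inchikey, "K1")
  expect_equal(filterFormula(cands, "H12C6O6")$inchikey, "K1")
  expect_equal(nrow(filterFormula(cands[0, ], "C6H12O6")), 0L)
  expect_error(filterFormula(cands, "NotAFormula!"), "parse")
})

test_that("element filter keeps subsets of the allowed element set", {
  expect_equal(filterElements(cands, c("C", "H", "O"))$inchikey,
               c("K1", "K2"))
  expect_equal(nrow(filterElements(cands, names(metaboMatch:::.MONOISO))),
               3L)
  se <- data.frame(inchikey = "K4", formula = "C3H7NO2Se")
  expect_equal(nrow(filterElements(se, c("C","H","N","O","P","S"))), 0L)
})

test_that("filters are pure and order-independent", {
  a <- filterElements(filterFormula(cands, "C6H12O6"), c("C", "H", "O"))
  b <- filterFormula(filterElements(cands, c("C", "H", "O")), "C6H12O6")
  expect_equal(a, b)
  # removal only: surviving rows are untouched rows of the input
  expect_true(all(a$inchikey %in% cands$inchikey))
})

# --- metabolite-likeness classifier -------------------------------------

# synthetic, linearly separable fingerprints: metabolites use bits 1..20,
# non-metabolites bits 21..40, plus shared noise bits
makeClassFps <- function(n, block, seed) {
  set.seed(seed)
  fps <- matrix(0L, n, 64)
  fps[, block] <- matrix(rbinom(n * length(block), 1, 0.7), n)
  fps[, 41:64] <- matrix(rbinom(n * 24, 1, 0.3), n)
  fps
}

test_that("separable classes give near-perfect CV accuracy", {
  pos <- makeClassFps(200, 1:20, seed = 1)
  neg <- makeClassFps(200, 21:40, seed = 2)
  clf <- trainMetaboliteClassifier(pos, neg, folds = 5, seed = 3)
  expect_gte(clf$cv_accuracy, 0.99)
  p <- predictMetaboliteLikeness(clf, rbind(pos[1:5, ], neg[1:5, ]))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(p[1:5] > 0.5) && all(p[6:10] < 0.5))
})

test_that("identical class distributions give chance-level accuracy", {
  pos <- makeClassFps(150, 1:40, seed = 4)
  neg <- makeClassFps(150, 1:40, seed = 5)
  clf <- trainMetaboliteClassifier(pos, neg, folds = 5, seed = 6)
  expect_gt(clf$cv_accuracy, 0.4)
  expect_lt(clf$cv_accuracy, 0.6)
})

test_that("single-class input is rejected", {
  pos <- makeClassFps(50, 1:20, seed = 7)
  expect_error(trainMetaboliteClassifier(pos, pos[0, ]), "non-empty")
})

test_that("likeness filter thresholds behave at the extremes", {
  pos <- makeClassFps(100, 1:20, seed = 8)
  neg <- makeClassFps(100, 21:40, seed = 9)
  clf <- trainMetaboliteClassifier(pos, neg, folds = 3, seed = 10)
  df <- data.frame(inchikey = paste0("K", 1:10))
  df$fingerprint <- lapply(1:10, function(i)
    if (i <= 5) pos[i, ] else neg[i, ])
  expect_equal(nrow(filterMetaboliteLikeness(df, clf, threshold = 0)),
               10L)
  # separable set at the default threshold: the metabolite block survives
  kept <- filterMetaboliteLikeness(df, clf, threshold = 0.5)
  expect_equal(kept$inchikey, paste0("K", 1:5))
  expect_true(all(kept$metabolite_likeness >= 0.5))
  expect_error(
    filterMetaboliteLikeness(df, clf, layoutId = "other-layout"),
    "layout mismatch")
})
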