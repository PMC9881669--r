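## The two scorers and score fusion.
##
## FragScorer: intensity-weighted match of the query spectrum against a
## candidate's pre-computed neutral fragment masses, transformed to m/z at
## match time by the query's adduct, with an optional +/- 1 hydrogen-mass
## correction on the predicted fragments (absorbs tautomerism / H mobility).
##
## FingerScorer: per-bit SVMs predict the compound fingerprint from a
## binned-spectrum feature vector; candidates are ranked by Jaccard
## similarity between predicted and stored fingerprints over the
## occupancy-selected bits.
##
## TotalScore: the product of the enabled scorers' values.

.H_MASS <- 1.00782503207

#' Match tolerance at a given m/z
#'
#' The effective tolerance is the larger of the relative (ppm) and absolute
#' (Da) components, mirroring a "<20 ppm or <0.005 Da" accuracy cut.
#'
#' @param mz Query m/z.
#' @param ppm Relative component (default 20).
#' @param da Absolute component in Da (default 0.005).
#' @return Tolerance in Da at each \code{mz}.
#' @export
matchTolerance <- function(mz, ppm = 20, da = 0.005) {
  pmax(mz * ppm * 1e-6, da)
}

#' FragScorer: intensity-weighted fragmentation-pattern match
#'
#' Each predicted neutral fragment mass f yields candidate ion m/z values
#' \code{fragmentMz(f)} and, with the hydrogen correction enabled, also
#' \code{fragmentMz(f +/- 1.007825)}. A query peak is matched if it lies
#' within the match tolerance of any candidate m/z; the score is the sum of
#' the intensities of the matched peaks (each peak counted once). On a
#' normalized spectrum the score is in [0, 1].
#'
#' @param spectrum A \linkS4class{MergedSpectrum} (normalized by
#'   construction).
#' @param pattern Fragment-mass vector from [enumerateFragments()] or a
#'   store record's \code{frag_pattern}.
#' @param adduct Adduct name or spec; defaults to the spectrum's adduct.
#' @param ppm,da Match tolerance components (see [matchTolerance()]).
#' @param hCorrection Enable the +/- 1 H correction (default \code{TRUE}).
#' @param n13C Isotopologue shift passed to [fragmentMz()].
#' @return List: \code{score}, \code{matched_peaks} data frame
#'   (\code{query_mz}, \code{intensity}, \code{fragment_mass},
#'   \code{correction} in -1/0/+1 hydrogens).
#' @export
fragScore <- function(spectrum, pattern, adduct = NULL, ppm = 20,
                      da = 0.005, hCorrection = TRUE, n13C = 0L) {
  stopifnot(methods::is(spectrum, "MergedSpectrum"))
  methods::validObject(spectrum)
  if (is.null(adduct)) adduct <- spectrum@adduct
  pattern <- as.numeric(pattern)
  corr <- if (hCorrection) c(0, -1, 1) else 0
  cand <- expand.grid(fragment_mass = pattern, correction = corr)
  cand$mz <- fragmentMz(cand$fragment_mass + cand$correction * .H_MASS,
                        adduct, n13C = n13C)
  ord <- order(cand$mz)
  cand <- cand[ord, , drop = FALSE]
  pk <- spectrum@peaks
  tol <- matchTolerance(pk[, 1], ppm, da)
  nearest <- findInterval(pk[, 1], cand$mz)
  lo <- pmax(nearest, 1L); hi <- pmin(nearest + 1L, nrow(cand))
  dLo <- abs(pk[, 1] - cand$mz[lo]); dHi <- abs(pk[, 1] - cand$mz[hi])
  best <- ifelse(dLo <= dHi, lo, hi)
  dist <- pmin(dLo, dHi)
  hit <- dist <= tol
  matched <- data.frame(
    query_mz = pk[hit, 1], intensity = pk[hit, 2],
    fragment_mass = cand$fragment_mass[best[hit]],
    correction = as.integer(cand$correction[best[hit]])
  )
  list(score = sum(pk[hit, 2]), matched_peaks = matched)
}

## ---------------------------------------------------------------------------
## Spectral featurization for fingerprint prediction

#' Feature specification for spectral featurization
#'
#' The feature vector is the binned peak intensity histogram over
#' \code{[0, mzMax]} at \code{binWidth}, optionally concatenated with the
#' equally binned neutral-loss (precursor m/z minus peak m/z) intensities.
#'
#' @param binWidth Bin width in Da (default 0.01).
#' @param mzMax Upper m/z bound of the binning (default 500).
#' @param neutralLoss Include the neutral-loss block (default \code{TRUE}).
#' @return List of class \code{featureSpec}.
#' @export
featureSpec <- function(binWidth = 0.01, mzMax = 500, neutralLoss = TRUE) {
  stopifnot(binWidth > 0, mzMax > binWidth)
  structure(list(binWidth = binWidth, mzMax = mzMax,
                 neutralLoss = isTRUE(neutralLoss),
                 nBins = as.integer(ceiling(mzMax / binWidth))),
            class = "featureSpec")
}

#' Featurize a merged spectrum
#'
#' @param spectrum A \linkS4class{MergedSpectrum}.
#' @param spec A [featureSpec()].
#' @return Non-negative numeric vector of length \code{nBins} (times two
#'   with the neutral-loss block); the peak block sums to 1 for peaks
#'   inside range.
#' @export
spectrumFeatures <- function(spectrum, spec = featureSpec()) {
  stopifnot(methods::is(spectrum, "MergedSpectrum"),
            inherits(spec, "featureSpec"))
  binOf <- function(v) pmin(pmax(floor(v / spec$binWidth) + 1L, 1L),
                            spec$nBins)
  pk <- spectrum@peaks
  feat <- numeric(spec$nBins)
  inRange <- pk[, 1] >= 0 & pk[, 1] <= spec$mzMax
  b <- binOf(pk[inRange, 1])
  for (j in seq_along(b)) feat[b[j]] <- feat[b[j]] + pk[inRange, 2][j]
  if (spec$neutralLoss) {
    nl <- numeric(spec$nBins)
    loss <- spectrum@precursorMz - pk[, 1]
    ok <- loss >= 0 & loss <= spec$mzMax
    bl <- binOf(loss[ok])
    for (j in seq_along(bl)) nl[bl[j]] <- nl[bl[j]] + pk[ok, 2][j]
    feat <- c(feat, nl)
  }
  feat
}

## ---------------------------------------------------------------------------
## FingerModelSet

#' FingerModelSet: per-bit SVM fingerprint predictor
#'
#' @slot layoutId Fingerprint layout the models target.
#' @slot selectedBits Indices of occupancy-selected bits (one SVM each).
#' @slot majority Full-length integer vector of training majority values,
#'   used verbatim for unselected bits.
#' @slot models List of per-bit models, parallel to \code{selectedBits}.
#' @slot fspec The [featureSpec()] used at train time.
#' @slot cvAccuracy Named numeric: held-out accuracy per selected bit.
#' @slot bounds Occupancy bounds used for selection.
#' @export
setClass("FingerModelSet", representation(
  layoutId = "character", selectedBits = "integer", majority = "integer",
  models = "list", fspec = "list", cvAccuracy = "numeric",
  bounds = "numeric"
))

setMethod("show", "FingerModelSet", function(object) {
  cat("FingerModelSet: ", length(object@selectedBits), " per-bit SVMs over ",
      length(object@majority), "-bit layout '", object@layoutId, "'\n",
      "  mean held-out bit accuracy ",
      sprintf("%.3f", mean(object@cvAccuracy)), "\n", sep = "")
})

## Fit one bit's model; degenerate single-class labels get a constant model.
.fitBit <- function(x, y, cost) {
  if (length(unique(y)) < 2L)
    return(structure(list(value = y[1]), class = "constantBit"))
  e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "linear",
             cost = cost, scale = FALSE)
}

.predictBit <- function(model, x) {
  if (inherits(model, "constantBit"))
    return(rep(model$value, nrow(x)))
  as.integer(as.character(predict(model, x)))
}

#' Train per-bit SVM fingerprint models from reference pairs
#'
#' Computes bit occupancy on the training fingerprints, keeps bits with
#' occupancy inside \code{bounds} (closed interval), and fits one binary SVM
#' per selected bit mapping [spectrumFeatures()] of the merged spectrum to
#' the bit value. The SVM cost is chosen by an inner cross-validation within
#' each training fold (nested CV); the reported per-bit accuracy is the
#' outer held-out accuracy. Unselected bits are predicted as their training
#' majority value.
#'
#' @param spectra List of \linkS4class{MergedSpectrum} (training spectra).
#' @param fps Integer 0/1 fingerprint matrix, one row per spectrum.
#' @param bounds Closed occupancy interval, default \code{c(0.05, 0.95)}.
#' @param folds Outer CV folds (default 5).
#' @param innerFolds Inner folds for cost selection (default 3).
#' @param costs Candidate SVM costs (default \code{c(0.1, 1, 10)}).
#' @param fspec A [featureSpec()].
#' @param seed Seed for fold assignment.
#' @return A \linkS4class{FingerModelSet}.
#' @export
trainFingerModels <- function(spectra, fps, bounds = c(0.05, 0.95),
                              folds = 5L, innerFolds = 3L,
                              costs = c(0.1, 1, 10),
                              fspec = featureSpec(), seed = 1L) {
  stopifnot(length(spectra) >= 2L, nrow(fps) == length(spectra))
  x <- t(vapply(spectra, spectrumFeatures, numeric(
    fspec$nBins * (1L + fspec$neutralLoss)), spec = fspec))
  ## The SVMs see presence/absence per bin: a fragment's diagnostic value
  ## is whether it appears, not its (acquisition-dependent) intensity, and
  ## near-zero intensities would otherwise sit on the decision boundary.
  x <- (x > 0) * 1
  ## drop all-zero feature columns for speed; remember which
  active <- which(colSums(x) > 0)
  xa <- x[, active, drop = FALSE]
  prof <- occupancyProfile(fps, bounds)
  sel <- prof$selected_bits
  majority <- as.integer(prof$occupancy > 0.5)
  set.seed(seed)
  n <- nrow(xa)
  fold <- sample(rep_len(seq_len(folds), n))
  pickCost <- function(xTr, yTr) {
    if (length(costs) == 1L || length(unique(yTr)) < 2L) return(costs[1])
    inner <- sample(rep_len(seq_len(innerFolds), length(yTr)))
    accs <- vapply(costs, function(co) {
      mean(vapply(seq_len(innerFolds), function(k) {
        tr <- inner != k
        if (length(unique(yTr[tr])) < 2L) return(NA_real_)
        m <- .fitBit(xTr[tr, , drop = FALSE], yTr[tr], co)
        mean(.predictBit(m, xTr[!tr, , drop = FALSE]) == yTr[!tr])
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    costs[which.max(accs)]
  }
  models <- vector("list", length(sel))
  cvAcc <- numeric(length(sel))
  for (j in seq_along(sel)) {
    y <- fps[, sel[j]]
    acc <- vapply(seq_len(folds), function(k) {
      tr <- fold != k
      co <- pickCost(xa[tr, , drop = FALSE], y[tr])
      m <- .fitBit(xa[tr, , drop = FALSE], y[tr], co)
      mean(.predictBit(m, xa[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    cvAcc[j] <- mean(acc)
    models[[j]] <- .fitBit(xa, y, pickCost(xa, y))
  }
  methods::new("FingerModelSet",
               layoutId = as.character(attr(fps, "layout_id") %||% "custom"),
               selectedBits = as.integer(sel), majority = majority,
               models = models,
               fspec = c(unclass(fspec),
                         list(active = active, binarize = TRUE)),
               cvAccuracy = stats::setNames(cvAcc, sel),
               bounds = as.numeric(bounds))
}

#' Predict fingerprint bits from a spectrum
#'
#' @param models A \linkS4class{FingerModelSet}.
#' @param spectrum A \linkS4class{MergedSpectrum}.
#' @return Full-length integer 0/1 vector (selected bits from the SVMs,
#'   the rest filled with training majority values).
#' @export
predictFingerprintBits <- function(models, spectrum) {
  fs <- models@fspec
  spec <- featureSpec(fs$binWidth, fs$mzMax, fs$neutralLoss)
  v <- spectrumFeatures(spectrum, spec)
  if (isTRUE(fs$binarize)) v <- (v > 0) * 1
  x <- matrix(v[fs$active], nrow = 1L)
  bits <- models@majority
  bits[models@selectedBits] <- vapply(seq_along(models@models), function(j)
    .predictBit(models@models[[j]], x)[1], integer(1))
  bits
}

#' Jaccard similarity between binary fingerprints
#'
#' \code{|A intersect B| / |A union B|} over the given bit positions; when
#' both vectors are all-zero over those positions the similarity is defined
#' as 1 (identical emptiness).
#'
#' @param a,b Integer 0/1 vectors of equal length.
#' @param positions Bit positions to compare (default: all).
#' @return Numeric in [0, 1].
#' @export
jaccardBits <- function(a, b, positions = seq_along(a)) {
  stopifnot(length(a) == length(b))
  a <- a[positions] > 0; b <- b[positions] > 0
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}

#' FingerScorer: predicted-vs-stored fingerprint Jaccard similarity
#'
#' Predicts the query's fingerprint from its spectrum and compares it to the
#' candidate's stored fingerprint over the occupancy-selected bits (the
#' unselected bits are majority-constant and would inflate similarity
#' uniformly).
#'
#' @param spectrum A \linkS4class{MergedSpectrum}, or a pre-computed
#'   prediction from [predictFingerprintBits()] (integer vector) to avoid
#'   re-predicting per candidate.
#' @param candidateFp Stored candidate fingerprint (0/1 vector).
#' @param models A \linkS4class{FingerModelSet}.
#' @param layoutId Candidate fingerprint layout, checked against the model
#'   set when both are known.
#' @return Score in [0, 1].
#' @export
fingerScore <- function(spectrum, candidateFp, models, layoutId = NULL) {
  if (!is.null(layoutId) && nzchar(models@layoutId) &&
      !identical(as.character(layoutId), models@layoutId))
    stop("layout mismatch: models for '", models@layoutId,
         "', candidate from '", layoutId, "'")
  pred <- if (methods::is(spectrum, "MergedSpectrum"))
    predictFingerprintBits(models, spectrum) else as.integer(spectrum)
  if (length(pred) != length(candidateFp))
    stop("layout mismatch: predicted ", length(pred),
         " bits, candidate has ", length(candidateFp))
  jaccardBits(pred, candidateFp, models@selectedBits)
}

#' Save / load a finger model set
#' @param models A \linkS4class{FingerModelSet}.
#' @param path File path.
#' @export
saveFingerModels <- function(models, path) {
  saveRDS(models, path)
  invisible(path)
}

#' @rdname saveFingerModels
#' @export
readFingerModels <- function(path) {
  m <- readRDS(path)
  stopifnot(methods::is(m, "FingerModelSet"))
  m
}

## ---------------------------------------------------------------------------
## Fusion and ranking

#' Fuse scorer outputs into TotalScore and rank candidates
#'
#' The TotalScore of a candidate is the product of its enabled scorers'
#' values (a single enabled scorer passes through unchanged). Candidates
#' are sorted by descending TotalScore; ties are broken by descending
#' fragmentation score, then ascending absolute mass deviation, then InChI
#' key. Ranks are 1-based.
#'
#' @param candidates Record data frame (needs \code{inchikey}; uses
#'   \code{delta_mass} for tie-breaks when present).
#' @param scores Named list or data frame of per-scorer numeric vectors in
#'   [0, 1] (e.g. \code{list(frag = ..., finger = ...)}), each of
#'   \code{nrow(candidates)} values; every enabled scorer must score every
#'   candidate.
#' @return \code{candidates} with per-scorer columns
#'   (\code{<name>_score}), \code{total_score}, \code{rank} and
#'   \code{relative_score} (fraction of the maximum TotalScore in the set),
#'   ordered by rank.
#' @export
combineAndRank <- function(candidates, scores) {
  scores <- as.data.frame(scores)
  if (!nrow(candidates)) {
    out <- candidates
    out$total_score <- numeric(0); out$rank <- integer(0)
    out$relative_score <- numeric(0)
    return(out)
  }
  if (nrow(scores) != nrow(candidates) || !ncol(scores))
    stop("every enabled scorer must provide one value per candidate")
  if (anyNA(scores))
    stop("missing scorer value(s): NA in ", paste(
      names(scores)[colSums(is.na(scores)) > 0], collapse = ", "))
  if (any(scores < -1e-12 | scores > 1 + 1e-12))
    stop("scorer values must lie in [0, 1]")
  out <- candidates
  for (nm in names(scores)) out[[paste0(nm, "_score")]] <- scores[[nm]]
  total <- Reduce(`*`, scores)
  out$total_score <- pmin(pmax(total, 0), 1)
  fragTie <- if ("frag" %in% names(scores)) scores[["frag"]] else
    rep(0, nrow(out))
  dTie <- if (!is.null(out$delta_mass)) abs(out$delta_mass) else
    rep(0, nrow(out))
  ord <- order(-out$total_score, -fragTie, dTie, out$inchikey)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  mx <- max(out$total_score)
  out$relative_score <- if (mx > 0) out$total_score / mx else
    rep(0, nrow(out))
  rownames(out) <- NULL
  out
}
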