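## Candidate filters applied between mass-window retrieval and scoring:
## exact molecular formula, elemental composition, and an optional
## metabolite-likeness SVM over compound fingerprints. All filters are pure
## (only remove rows, never mutate) and commute with one another.

#' Keep candidates whose formula equals a known formula
#'
#' Exact match after normalization of both sides to Hill order, for use when
#' the formula has been fully determined upstream (e.g. by an isotope-based
#' formula engine).
#'
#' @param candidates Record data frame from [queryByMass()].
#' @param knownFormula Formula string in any element order.
#' @return The surviving subset of \code{candidates}.
#' @examples
#' df <- data.frame(formula = c("C6H12O6", "C7H16O5"))
#' filterFormula(df, "H12C6O6")$formula   # "C6H12O6"
#' @export
filterFormula <- function(candidates, knownFormula) {
  target <- hillFormula(parseFormula(knownFormula))
  keep <- vapply(candidates$formula, function(f)
    hillFormula(parseFormula(f)) == target, logical(1), USE.NAMES = FALSE)
  candidates[keep, , drop = FALSE]
}

#' Keep candidates composed only of allowed elements
#'
#' @param candidates Record data frame.
#' @param allowedElements Character vector of element symbols (e.g.
#'   \code{c("C","H","N","O","P","S")}).
#' @return The surviving subset.
#' @export
filterElements <- function(candidates, allowedElements) {
  stopifnot(length(allowedElements) >= 1L)
  bad <- setdiff(allowedElements, names(.MONOISO))
  if (length(bad))
    warning("unknown element symbol(s) ignored: ", paste(bad, collapse = ", "))
  keep <- vapply(candidates$formula, function(f)
    all(names(parseFormula(f)) %in% allowedElements), logical(1),
    USE.NAMES = FALSE)
  candidates[keep, , drop = FALSE]
}

#' Train a two-class metabolite-likeness SVM on compound fingerprints
#'
#' Fits a binary SVM (radial kernel) on the full fingerprint bits of
#' compounds labelled metabolite / non-metabolite and reports mean k-fold
#' cross-validated accuracy. Predictions are class probabilities, used by
#' [filterMetaboliteLikeness()].
#'
#' @param positiveFps,negativeFps Integer 0/1 fingerprint matrices of the
#'   metabolite and non-metabolite classes (same layout).
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed controlling fold assignment.
#' @return List of class \code{metaboliteClassifier}: \code{model},
#'   \code{cv_accuracy}, \code{layout_id}, \code{folds}.
#' @export
trainMetaboliteClassifier <- function(positiveFps, negativeFps, folds = 5L,
                                      seed = 1L) {
  if (nrow(positiveFps) == 0L || nrow(negativeFps) == 0L)
    stop("both classes must be non-empty")
  l1 <- attr(positiveFps, "layout_id"); l2 <- attr(negativeFps, "layout_id")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("fingerprint layout mismatch between classes: ", l1, " vs ", l2)
  x <- rbind(positiveFps, negativeFps)
  y <- factor(rep(c(1L, 0L), c(nrow(positiveFps), nrow(negativeFps))),
              levels = c(0L, 1L))
  ## drop constant bits (zero variance breaks svm scaling)
  keep <- which(apply(x, 2, function(v) length(unique(v)) > 1L))
  if (!length(keep)) stop("all fingerprint bits are constant across classes")
  set.seed(seed)
  fold <- .stratifiedFolds(y, folds)
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    fit <- e1071::svm(x[tr, keep, drop = FALSE], y[tr],
                      kernel = "radial", scale = FALSE)
    mean(predict(fit, x[!tr, keep, drop = FALSE]) == y[!tr])
  }, numeric(1))
  model <- e1071::svm(x[, keep, drop = FALSE], y, kernel = "radial",
                      scale = FALSE, probability = TRUE)
  structure(list(model = model, bits_used = keep,
                 cv_accuracy = mean(acc), fold_accuracy = acc,
                 folds = folds, layout_id = l1 %||% l2),
            class = "metaboliteClassifier")
}

## fold labels 1..k, stratified by class
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    ix <- which(y == cl)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

#' Predict metabolite likeness for candidate fingerprints
#'
#' @param classifier A \code{metaboliteClassifier}.
#' @param fps Fingerprint matrix, or the \code{fingerprint} list-column of a
#'   record data frame.
#' @return Numeric vector of metabolite probabilities in [0, 1].
#' @export
predictMetaboliteLikeness <- function(classifier, fps) {
  if (is.list(fps) && !is.matrix(fps)) fps <- do.call(rbind, fps)
  pr <- predict(classifier$model, fps[, classifier$bits_used, drop = FALSE],
                probability = TRUE)
  attr(pr, "probabilities")[, "1"]
}

#' Keep candidates predicted to be metabolite-like
#'
#' Scores each candidate's stored fingerprint with the classifier, caches
#' the probability in a \code{metabolite_likeness} column, and keeps
#' candidates with probability at or above the threshold. Off by default in
#' the pipeline; enable explicitly where the search space should be
#' restricted to biology-like compounds.
#'
#' @param candidates Record data frame with a \code{fingerprint} column.
#' @param classifier From [trainMetaboliteClassifier()].
#' @param threshold Probability cutoff (default 0.5).
#' @param layoutId Layout of the candidates' fingerprints, checked against
#'   the classifier when both are known.
#' @return The surviving subset with \code{metabolite_likeness} filled in.
#' @export
filterMetaboliteLikeness <- function(candidates, classifier,
                                     threshold = 0.5, layoutId = NULL) {
  if (!is.null(layoutId) && !identical(layoutId, classifier$layout_id))
    stop("layout mismatch: classifier trained on '", classifier$layout_id,
         "', candidates use '", layoutId, "'")
  if (!nrow(candidates)) return(candidates)
  p <- predictMetaboliteLikeness(classifier, candidates$fingerprint)
  candidates$metabolite_likeness <- as.numeric(p)
  candidates[p >= threshold, , drop = FALSE]
}
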