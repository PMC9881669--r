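## Synthetic toy compound sets and simulated spectra with known ground
## truth, so every pipeline stage is testable without external databases.
##
## Spectra are simulated from the package's own fragmenter (fragment
## subset + adduct transform + m/z jitter + uniform decoy peaks + Dirichlet
## intensities), which makes self-retrieval a sharp, interpretable test
## surface: with zero jitter and zero decoys the true compound's
## fragmentation score is exactly 1.

.fixtureEnv <- new.env(parent = emptyenv())

#' The curated metabolite fixture table
#'
#' 138 real metabolite structures (name + SMILES) shipped as a plain-text
#' fixture; the source pool for [makeCompoundSet()].
#'
#' @return Data frame with columns \code{name}, \code{smiles}.
#' @export
fixtureCompounds <- function() {
  path <- system.file("extdata", "metabolite_smiles.tsv",
                      package = "metaboMatch", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

## parse the full fixture list once per session
.fixtureMols <- function() {
  if (is.null(.fixtureEnv$mols)) {
    tab <- fixtureCompounds()
    .fixtureEnv$mols <- parseSmiles(tab$smiles, ids = tab$name)
  }
  .fixtureEnv$mols
}

#' Draw a deterministic toy compound set
#'
#' Subsamples \code{n} structurally distinct metabolites from the curated
#' fixture list; the same seed always yields the same set.
#'
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @return List of parsed molecules (as [parseSmiles()]).
#' @export
makeCompoundSet <- function(n, seed = 1L) {
  mols <- .fixtureMols()
  if (n < 1L || n > length(mols))
    stop("n must be between 1 and ", length(mols),
         " (the curated fixture diversity)")
  set.seed(seed)
  mols[sort(sample.int(length(mols), n))]
}

#' Simulate a merged MS2 spectrum from a compound's fragment pattern
#'
#' Selects \code{min(kPeaks, pattern size)} fragment masses, converts them
#' to m/z under the adduct, applies Gaussian m/z jitter, appends uniform
#' random decoy peaks, and assigns Dirichlet(1, ..., 1) intensities
#' normalized to 1.
#'
#' @param pattern Fragment masses from [enumerateFragments()] (or a store
#'   record's \code{frag_pattern}); the largest mass is taken as the parent.
#' @param adduct Adduct name (default \code{"[M+H]+"}).
#' @param kPeaks Number of true fragment peaks (default 8).
#' @param jitterSigma Gaussian m/z jitter s.d. in Da (default 0.001).
#' @param decoys Number of uniform random decoy peaks (default 4).
#' @param seed Integer seed.
#' @param id Query id.
#' @return A \linkS4class{MergedSpectrum} whose precursor m/z is the
#'   adduct-transformed parent mass.
#' @export
simulateSpectrum <- function(pattern, adduct = "[M+H]+", kPeaks = 8L,
                             jitterSigma = 0.001, decoys = 4L, seed = 1L,
                             id = "sim") {
  pattern <- as.numeric(pattern)
  stopifnot(length(pattern) >= 1L)
  a <- adductSpec(adduct)
  parent <- max(pattern)
  precursor <- fragmentMz(parent, a)
  set.seed(seed)
  k <- min(as.integer(kPeaks), length(pattern))
  mz <- numeric(0)
  if (k > 0L) {
    sel <- sample(seq_along(pattern), k)
    mz <- fragmentMz(pattern[sel], a) + stats::rnorm(k, 0, jitterSigma)
  }
  if (decoys > 0L) {
    lo <- min(20, precursor / 2)
    mz <- c(mz, stats::runif(decoys, lo, precursor))
  }
  if (!length(mz)) stop("kPeaks and decoys cannot both be zero")
  inten <- stats::rexp(length(mz))              # Dirichlet(1,...,1)
  inten <- inten / sum(inten)
  ord <- order(mz)
  mz <- mz[ord]; inten <- inten[ord]
  ## collapse exact m/z collisions so the peak list is strictly increasing
  grp <- cumsum(c(1, diff(mz) > 0))
  if (any(duplicated(grp))) {
    inten <- vapply(split(inten, grp), sum, numeric(1))
    mz <- vapply(split(mz, grp), `[`, numeric(1), 1L)
  }
  methods::new("MergedSpectrum", precursorMz = precursor,
               polarity = a$polarity, adduct = a$name,
               peaks = unname(cbind(mz, inten / sum(inten))), id = id)
}

#' Build a full toy benchmark: compound set, store input and query spectra
#'
#' Generates \code{n} toy compounds and one simulated spectrum per compound
#' (seeded per query), giving a self-retrieval benchmark with known ground
#' truth.
#'
#' @inheritParams makeCompoundSet
#' @inheritParams simulateSpectrum
#' @return List of class \code{toySet}: \code{compounds} (molecules),
#'   \code{spectra} (list of \linkS4class{MergedSpectrum}), \code{truth}
#'   (data frame \code{query_id}, \code{inchikey}, \code{formula}),
#'   \code{params}.
#' @export
makeToySet <- function(n = 100L, seed = 42L, adduct = "[M+H]+",
                       kPeaks = 8L, jitterSigma = 0.001, decoys = 4L,
                       maxBonds = 2L) {
  mols <- makeCompoundSet(n, seed)
  pats <- lapply(mols, enumerateFragments, maxBonds = maxBonds)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    spectra[[i]] <- simulateSpectrum(
      pats[[i]], adduct = adduct, kPeaks = kPeaks,
      jitterSigma = jitterSigma, decoys = decoys,
      seed = seed + i, id = paste0("q", i, "_", mols[[i]]$id))
  }
  truth <- data.frame(
    query_id = vapply(spectra, function(s) s@id, character(1)),
    inchikey = vapply(mols, function(m) m$inchikey, character(1)),
    formula = vapply(mols, function(m) m$formula, character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(compounds = mols, spectra = spectra, truth = truth,
                 params = list(n = n, seed = seed, adduct = adduct,
                               kPeaks = kPeaks, jitterSigma = jitterSigma,
                               decoys = decoys, maxBonds = maxBonds)),
            class = "toySet")
}

#' Confusable-candidate benchmark for the formula / element filters
#'
#' Builds a store in which a fraction of the target compounds is paired
#' with a real decoy metabolite of the same nominal mass but different
#' molecular formula (element-set-differing decoys preferred). Queries for
#' the paired targets are chimeric: a minority intensity share from the
#' true compound's fragments plus a majority share at decoy-specific
#' fragment m/z, so the decoy out-scores the truth until the element or
#' formula filter removes it. Retrieval at a wide (unit-resolution) mass
#' window makes the nominal-mass decoys visible.
#'
#' @param n Store size (targets + decoys + fillers).
#' @param nConfusable Number of target/decoy pairs (default \code{0.3 * n}).
#' @param seed Integer seed.
#' @param truthShare Intensity share of the true compound's peaks in
#'   chimeric queries (default 0.3).
#' @param maxBonds Fragmenter depth for patterns and simulation.
#' @return List: \code{compounds}, \code{spectra}, \code{truth} (with
#'   \code{confusable} flag and per-query \code{formula} and
#'   \code{elements}), \code{params}.
#' @export
makeConfusableBenchmark <- function(n = 100L, nConfusable = NULL,
                                    seed = 7L, truthShare = 0.3,
                                    maxBonds = 2L) {
  if (is.null(nConfusable)) nConfusable <- round(0.3 * n)
  all <- .fixtureMols()
  mass <- vapply(all, function(m) m$exact_mass, numeric(1))
  form <- vapply(all, function(m) m$formula, character(1))
  elems <- lapply(form, function(f) names(parseFormula(f)))
  nom <- round(mass)
  ## candidate pairs: same nominal mass, different formula;
  ## element-set-differing pairs first
  pairs <- list()
  for (nv in unique(nom)) {
    ix <- which(nom == nv)
    if (length(ix) < 2L) next
    for (a in ix) for (b in ix)
      if (a < b && form[a] != form[b])
        pairs[[length(pairs) + 1L]] <-
          list(t = a, d = b, ediff = !setequal(elems[[a]], elems[[b]]))
  }
  if (!length(pairs)) stop("fixture list contains no confusable pairs")
  ediff <- vapply(pairs, `[[`, logical(1), "ediff")
  pairs <- pairs[order(!ediff)]
  ## greedily take disjoint pairs whose decoy has fragment ions clear of
  ## the truth's candidate ions (so a chimeric spectrum is constructible)
  patCache <- list()
  pat0 <- function(i) {
    k <- as.character(i)
    if (is.null(patCache[[k]]))
      patCache[[k]] <<- enumerateFragments(all[[i]], maxBonds = maxBonds)
    patCache[[k]]
  }
  used <- integer(0); take <- list()
  for (p in pairs) {
    if (length(take) >= nConfusable) break
    if (p$t %in% used || p$d %in% used) next
    if (length(.clearDecoyMz(pat0(p$t), pat0(p$d))) < 2L) next
    take[[length(take) + 1L]] <- p
    used <- c(used, p$t, p$d)
  }
  nConfusable <- length(take)
  targets <- vapply(take, `[[`, integer(1), "t")
  decoyIx <- vapply(take, `[[`, integer(1), "d")
  set.seed(seed)
  fillers <- setdiff(sample.int(length(all)), used)
  fillers <- fillers[seq_len(max(0L, n - 2L * nConfusable))]
  storeIx <- c(targets, decoyIx, fillers)
  mols <- all[storeIx]
  ## query targets: the confusable targets plus enough fillers to reach n
  qIx <- c(targets, fillers)[seq_len(min(n, length(targets) +
                                           length(fillers)))]
  pat <- pat0
  spectra <- list(); truthRows <- list()
  for (qi in seq_along(qIx)) {
    i <- qIx[qi]
    confus <- qi <= nConfusable
    if (confus) {
      d <- decoyIx[qi]
      sp <- .chimericSpectrum(pat(i), pat(d), truthShare,
                              seed = seed + qi,
                              id = paste0("q", qi, "_", all[[i]]$id))
    } else {
      sp <- simulateSpectrum(pat(i), kPeaks = 8L, jitterSigma = 0.001,
                             decoys = 4L, seed = seed + qi,
                             id = paste0("q", qi, "_", all[[i]]$id))
    }
    spectra[[qi]] <- sp
    truthRows[[qi]] <- data.frame(
      query_id = sp@id, inchikey = all[[i]]$inchikey,
      formula = all[[i]]$formula,
      elements = paste(elems[[i]], collapse = ","),
      confusable = confus, stringsAsFactors = FALSE)
  }
  structure(list(compounds = mols, spectra = spectra,
                 truth = do.call(rbind, truthRows),
                 params = list(n = n, nConfusable = nConfusable,
                               seed = seed, truthShare = truthShare,
                               maxBonds = maxBonds)),
            class = "toySet")
}

## decoy fragment ion m/z far from every truth candidate ion m/z
## (including the +/- 1 H corrections the matcher will try)
.clearDecoyMz <- function(truePat, decoyPat, adduct = "[M+H]+") {
  a <- adductSpec(adduct)
  truthCand <- as.vector(outer(truePat, c(-1, 0, 1) * .H_MASS, `+`))
  truthCandMz <- fragmentMz(truthCand, a)
  dMz <- fragmentMz(decoyPat, a)
  dMz[vapply(dMz, function(z) min(abs(z - truthCandMz)) > 0.05,
             logical(1))]
}

## Chimeric spectrum: kTrue peaks from the true pattern (total intensity
## truthShare) + kDecoy peaks at decoy-only fragment m/z (the rest).
.chimericSpectrum <- function(truePat, decoyPat, truthShare, seed, id,
                              kTrue = 4L, kDecoy = 4L, adduct = "[M+H]+") {
  a <- adductSpec(adduct)
  set.seed(seed)
  trueSel <- sample(seq_along(truePat), min(kTrue, length(truePat)))
  trueMz <- fragmentMz(truePat[trueSel], a)
  dMz <- .clearDecoyMz(truePat, decoyPat, adduct)
  if (!length(dMz))
    stop("decoy pattern fully overlaps the truth pattern")
  decoySel <- sample(seq_along(dMz), min(kDecoy, length(dMz)))
  decoyMz <- dMz[decoySel]
  wT <- stats::rexp(length(trueMz)); wT <- truthShare * wT / sum(wT)
  wD <- stats::rexp(length(decoyMz)); wD <- (1 - truthShare) * wD / sum(wD)
  mz <- c(trueMz, decoyMz) + stats::rnorm(length(trueMz) + length(decoyMz),
                                          0, 0.0005)
  inten <- c(wT, wD)
  ord <- order(mz)
  methods::new("MergedSpectrum",
               precursorMz = fragmentMz(max(truePat), a),
               polarity = a$polarity, adduct = a$name,
               peaks = unname(cbind(mz[ord], inten[ord] / sum(inten))),
               id = id)
}

#' Write a toy set to disk as SMILES + MGF + truth TSV
#'
#' @param set A \code{toySet} from [makeToySet()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (\code{compounds.smi},
#'   \code{queries.mgf}, \code{truth.tsv}).
#' @export
writeToySet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smi <- file.path(dir, "compounds.smi")
  writeLines(vapply(set$compounds, function(m)
    paste(m$smiles, m$id, sep = "\t"), character(1)), smi)
  mgf <- file.path(dir, "queries.mgf")
  con <- file(mgf, "w"); on.exit(close(con))
  for (sp in set$spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp@id),
                 sprintf("PEPMASS=%.6f", sp@precursorMz),
                 paste0("CHARGE=1", sp@polarity),
                 sprintf("%.6f %.8g", sp@peaks[, 1], sp@peaks[, 2]),
                 "END IONS", ""), con)
  }
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(set$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(compounds = smi, queries = mgf, truth = truth))
}
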