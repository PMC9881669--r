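## Query-side spectra: raw MS2 peak lists, merged/normalized query spectra,
## and adduct m/z arithmetic.

#' RawSpectrum: one acquired MS2 peak list
#'
#' @slot precursorMz Precursor m/z (Th).
#' @slot polarity \code{"+"} or \code{"-"}.
#' @slot collisionEnergy Collision energy (eV) or \code{NA}; parsed but not
#'   used by any scorer.
#' @slot peaks Two-column matrix (\code{mz}, \code{intensity}), sorted by mz.
#' @slot id Spectrum identifier (e.g. MGF TITLE).
#' @export
setClass("RawSpectrum", representation(
  precursorMz = "numeric", polarity = "character",
  collisionEnergy = "numeric", peaks = "matrix", id = "character"
))

setValidity("RawSpectrum", function(object) {
  p <- object@peaks
  if (ncol(p) != 2L) return("peaks must have two columns (mz, intensity)")
  if (nrow(p) < 1L) return("spectrum must contain at least one peak")
  if (any(p[, 2] < 0)) return("intensities must be non-negative")
  if (is.unsorted(p[, 1])) return("peaks must be sorted by mz")
  if (!object@polarity %in% c("+", "-")) return("polarity must be '+' or '-'")
  if (!is.finite(object@precursorMz) || object@precursorMz <= 0)
    return("precursorMz must be positive")
  TRUE
})

#' Construct a RawSpectrum
#' @param precursorMz,polarity,peaks,collisionEnergy,id See class slots;
#'   \code{peaks} is a two-column matrix or data frame and is sorted here.
#' @return A \linkS4class{RawSpectrum}.
#' @export
rawSpectrum <- function(precursorMz, peaks, polarity = "+",
                        collisionEnergy = NA_real_, id = "spectrum") {
  peaks <- as.matrix(peaks)
  colnames(peaks) <- c("mz", "intensity")
  peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  methods::new("RawSpectrum", precursorMz = as.numeric(precursorMz),
               polarity = polarity,
               collisionEnergy = as.numeric(collisionEnergy),
               peaks = peaks, id = id)
}

#' MergedSpectrum: the normalized query unit
#'
#' A merged, intensity-normalized MS2 spectrum: peak intensities sum to 1
#' and m/z values are strictly increasing.
#'
#' @slot precursorMz Precursor m/z (Th).
#' @slot polarity \code{"+"} or \code{"-"}.
#' @slot adduct Adduct name (e.g. \code{"[M+H]+"}).
#' @slot peaks Two-column matrix (\code{mz}, \code{intensity}).
#' @slot id Query identifier.
#' @export
setClass("MergedSpectrum", representation(
  precursorMz = "numeric", polarity = "character", adduct = "character",
  peaks = "matrix", id = "character"
))

setValidity("MergedSpectrum", function(object) {
  p <- object@peaks
  if (nrow(p) < 1L) return("merged spectrum has no peaks")
  if (abs(sum(p[, 2]) - 1) > 1e-9)
    return("intensities must sum to 1.0 (+/- 1e-9)")
  if (any(diff(p[, 1]) <= 0)) return("mz must be strictly increasing")
  TRUE
})

setMethod("show", "MergedSpectrum", function(object) {
  cat("MergedSpectrum ", object@id, ": ", nrow(object@peaks), " peaks, ",
      "precursor ", sprintf("%.4f", object@precursorMz), " Th (",
      object@adduct, ", ", object@polarity, ")\n", sep = "")
})

## ---------------------------------------------------------------------------
## Adducts

.ADDUCTS <- list(
  "[M+H]+"   = list(massDelta = .PROTON,                      charge = +1L),
  "[M-H]-"   = list(massDelta = -.PROTON,                     charge = -1L),
  "[M+Na]+"  = list(massDelta = 22.9897692809 - .ELECTRON,    charge = +1L),
  "[M+K]+"   = list(massDelta = 38.96370668 - .ELECTRON,      charge = +1L),
  "[M+NH4]+" = list(massDelta = 14.0030740048 +
                      4 * 1.00782503207 - .ELECTRON,          charge = +1L),
  "[M+Cl]-"  = list(massDelta = 34.96885268 + .ELECTRON,      charge = -1L)
)

#' Adduct specifications
#'
#' Returns the signed mass delta (Da, electron mass included) and charge of
#' a named adduct; the neutral mass M and observed m/z are related by
#' \code{mz = (M + massDelta) / abs(charge)}.
#'
#' @param name Adduct name; see \code{names(adductTable())}.
#' @return List with \code{name}, \code{massDelta}, \code{charge},
#'   \code{polarity}.
#' @examples
#' adductSpec("[M+H]+")$massDelta   # 1.007276
#' @export
adductSpec <- function(name) {
  if (is.list(name) && !is.null(name$massDelta)) return(name)
  a <- .ADDUCTS[[name]]
  if (is.null(a))
    stop("unknown adduct '", name, "'; known: ",
         paste(names(.ADDUCTS), collapse = ", "))
  list(name = name, massDelta = a$massDelta, charge = a$charge,
       polarity = if (a$charge > 0) "+" else "-")
}

#' @rdname adductSpec
#' @export
adductTable <- function() {
  do.call(rbind, lapply(names(.ADDUCTS), function(n)
    data.frame(name = n, massDelta = .ADDUCTS[[n]]$massDelta,
               charge = .ADDUCTS[[n]]$charge)))
}

#' Adduct m/z arithmetic
#'
#' \code{neutralMassFromPrecursor} recovers the neutral (or inherently
#' charged species') mass M from an observed precursor m/z;
#' \code{fragmentMz} predicts the m/z at which a neutral fragment of the
#' candidate appears under the adduct. The two are mutual inverses. An
#' optional isotopologue shift of \code{n13C} times 1.003355 Da is applied
#' to predicted fragment m/z when the query was flagged as an isotope peak.
#'
#' @param precursorMz Observed precursor m/z (Th).
#' @param adduct Adduct name or spec from [adductSpec()].
#' @param fragmentMass Neutral fragment mass (Da).
#' @param n13C Number of 13C substitutions assumed in the query (default 0).
#' @return Mass in Da / m/z in Th.
#' @examples
#' neutralMassFromPrecursor(181.0707, "[M+H]+")  # ~180.0634 (glucose)
#' fragmentMz(180.0634, "[M-H]-")                # ~179.0561
#' @export
neutralMassFromPrecursor <- function(precursorMz, adduct) {
  a <- adductSpec(adduct)
  precursorMz * abs(a$charge) - a$massDelta
}

#' @rdname neutralMassFromPrecursor
#' @export
fragmentMz <- function(fragmentMass, adduct, n13C = 0L) {
  a <- adductSpec(adduct)
  (fragmentMass + n13C * 1.003355 + a$massDelta) / abs(a$charge)
}

## ---------------------------------------------------------------------------
## Reading peak lists

#' Read MS2 spectra from MGF or tab-separated peak lists
#'
#' MGF: one \code{RawSpectrum} per \code{BEGIN IONS}/\code{END IONS} block;
#' \code{PEPMASS}, \code{CHARGE} (sign gives polarity), \code{TITLE} and
#' \code{COLLISION_ENERGY}/\code{CE} headers are captured. TSV: a single
#' two-column (mz, intensity) peak list; precursor and polarity are given
#' as arguments.
#'
#' @param path Input file.
#' @param format \code{"mgf"} or \code{"tsv"}.
#' @param precursorMz,polarity Used for \code{format = "tsv"} only.
#' @return List of \linkS4class{RawSpectrum}. Blocks with zero peaks are
#'   skipped with a warning; an MGF block without a precursor is an error.
#' @export
readSpectra <- function(path, format = c("mgf", "tsv"),
                        precursorMz = NULL, polarity = "+") {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "tsv") {
    if (is.null(precursorMz))
      stop("precursorMz is required for tsv peak lists")
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("mz", "intensity"))
    return(list(rawSpectrum(precursorMz, tab, polarity = polarity,
                            id = basename(path))))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  begins <- grep("^BEGIN IONS$", lines)
  endsAt <- grep("^END IONS$", lines)
  if (length(begins) != length(endsAt))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- list()
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(endsAt[b] - 1L)]
    hdr <- grep("=", block, value = TRUE, fixed = TRUE)
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA
    pep <- getv("PEPMASS")
    if (is.na(pep))
      stop("MGF block ", b, " in ", path, " has no PEPMASS (precursor)")
    prec <- as.numeric(strsplit(pep, "[[:space:]]+")[[1]][1])
    pol <- if (grepl("-", getv("CHARGE") %||% "1+")) "-" else "+"
    ce <- suppressWarnings(as.numeric(getv("COLLISION_ENERGY") %||%
                                        getv("CE")))
    title <- getv("TITLE") %||% paste0("query", b)
    pkLines <- block[!grepl("=", block, fixed = TRUE) & nzchar(block)]
    if (!length(pkLines)) {
      warning("MGF block ", b, " (", title, ") has zero peaks; skipped")
      next
    }
    pk <- do.call(rbind, lapply(strsplit(pkLines, "[[:space:]]+"),
                                function(x) as.numeric(x[1:2])))
    out[[length(out) + 1L]] <-
      rawSpectrum(prec, pk, polarity = pol, collisionEnergy = ce, id = title)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

## ---------------------------------------------------------------------------
## Merging and normalization

#' Merge multi-collision-energy spectra of one precursor and normalize
#'
#' Pools the peaks of all spectra sharing a precursor, combines peaks closer
#' than \code{mzMergeTol} (intensity-summed, m/z = intensity-weighted mean)
#' and rescales intensities to sum to 1 -- roughly equivalent to a spectrum
#' recorded in collision-energy ramp mode. Merging is invariant under
#' permutation of the input spectra.
#'
#' @param spectra List of \linkS4class{RawSpectrum} with equal polarity and
#'   precursors agreeing within \code{mzMergeTol}.
#' @param adduct Adduct name attached to the result (default
#'   \code{"[M+H]+"} / \code{"[M-H]-"} by polarity).
#' @param mzMergeTol Intra-merge m/z tolerance in Da (default 0.002).
#' @param id Query id for the result (default: first spectrum's id).
#' @return A \linkS4class{MergedSpectrum}.
#' @export
mergeSpectra <- function(spectra, adduct = NULL, mzMergeTol = 0.002,
                         id = NULL) {
  if (methods::is(spectra, "RawSpectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L)
  pols <- vapply(spectra, function(s) s@polarity, character(1))
  if (length(unique(pols)) != 1L)
    stop("cannot merge spectra of mixed polarity")
  precs <- vapply(spectra, function(s) s@precursorMz, numeric(1))
  if (diff(range(precs)) > mzMergeTol)
    stop("spectra do not share a precursor within mzMergeTol: ",
         paste(sprintf("%.4f", range(precs)), collapse = " .. "))
  if (is.null(adduct)) adduct <- if (pols[1] == "+") "[M+H]+" else "[M-H]-"
  pk <- do.call(rbind, lapply(spectra, function(s) s@peaks))
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  grp <- cumsum(c(1, diff(pk[, 1]) > mzMergeTol))
  inten <- vapply(split(pk[, 2], grp), sum, numeric(1))
  mz <- vapply(split(seq_len(nrow(pk)), grp), function(ix)
    stats::weighted.mean(pk[ix, 1], pk[ix, 2]), numeric(1))
  ## zero-intensity clusters fall back to the plain mean
  z <- !is.finite(mz)
  if (any(z))
    mz[z] <- vapply(split(pk[, 1], grp)[z], mean, numeric(1))
  total <- sum(inten)
  if (total <= 0) stop("merged spectrum has zero total intensity")
  methods::new("MergedSpectrum",
               precursorMz = stats::weighted.mean(precs, rep(1, length(precs))),
               polarity = pols[1], adduct = adductSpec(adduct)$name,
               peaks = unname(cbind(mz = mz, intensity = inten / total)),
               id = id %||% spectra[[1]]@id)
}
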