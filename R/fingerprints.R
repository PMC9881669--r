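## Fixed-layout binary chemical fingerprints.
##
## A layout is an ordered list of fingerprint families; the compound
## fingerprint is the concatenation of each family's bits in layout order.
## Families are computed by OpenBabel; the total length is whatever the
## layout declares and is recorded in the store manifest -- downstream code
## never assumes a particular length.

.LAYOUTS <- list(
  ## broad layout used for real annotation work: path-based (FP2),
  ## small-ring (FP3), substructure/SMARTS (FP4) and MACCS-style keys
  reference = data.frame(
    family = c("FP2", "FP3", "FP4", "MACCS"),
    bits = c(1024L, 64L, 512L, 256L),
    stringsAsFactors = FALSE
  ),
  ## compact layout for tests and toy stores
  toy = data.frame(
    family = "MACCS",
    bits = 256L,
    stringsAsFactors = FALSE
  )
)

#' Fingerprint layouts
#'
#' A fingerprint layout names the ordered fingerprint families whose bits
#' are concatenated into the compound fingerprint. Two layouts ship with the
#' package: \code{"reference"} (FP2 + FP3 + FP4 + MACCS, 1856 bits) and
#' \code{"toy"} (MACCS only, 256 bits).
#'
#' @param name Layout name, or a data frame with columns \code{family} and
#'   \code{bits} for a custom layout.
#' @return A data frame describing the layout, with attribute
#'   \code{layout_id}.
#' @examples
#' fingerprintLayout("toy")
#' @export
fingerprintLayout <- function(name = "reference") {
  if (is.data.frame(name)) {
    stopifnot(all(c("family", "bits") %in% names(name)))
    lay <- name
    if (is.null(attr(lay, "layout_id")))
      attr(lay, "layout_id") <- paste0("custom-", sum(lay$bits))
    return(lay)
  }
  if (!name %in% names(.LAYOUTS))
    stop("unknown fingerprint layout '", name, "'; available: ",
         paste(names(.LAYOUTS), collapse = ", "))
  lay <- .LAYOUTS[[name]]
  attr(lay, "layout_id") <- name
  lay
}

#' Total bit length of a layout
#' @param layout A layout from [fingerprintLayout()].
#' @return Integer.
#' @export
layoutLength <- function(layout) sum(layout$bits)

#' Compute binary fingerprints for molecules
#'
#' Concatenates the bits of every family in the layout, in layout order.
#' The same structure (same InChI) always yields identical bits.
#'
#' @param mols List of molecules from [parseSmiles()], or a character vector
#'   of SMILES.
#' @param layout Layout name or data frame (see [fingerprintLayout()]).
#' @return Integer 0/1 matrix, one row per molecule, \code{layoutLength()}
#'   columns; attribute \code{layout_id}.
#' @examples
#' fp <- computeFingerprints(c("c1ccccc1", "C"), layout = "toy")
#' sum(fp[1, ]) > sum(fp[2, ])  # benzene sets more feature bits than methane
#' @export
computeFingerprints <- function(mols, layout = "reference") {
  layout <- fingerprintLayout(layout)
  if (is.character(mols)) mols <- parseSmiles(mols)
  smiles <- vapply(mols, function(m) m$smiles, character(1))
  if (anyNA(smiles) || any(!nzchar(smiles)))
    stop("fingerprint error: molecule without a SMILES representation")
  src <- paste(smiles, collapse = "\n")
  blocks <- lapply(seq_len(nrow(layout)), function(i) {
    fam <- layout$family[i]
    obm <- ChemmineOB::forEachMol("SMILES", src, identity)
    bits <- tryCatch(ChemmineOB::fingerprint_OB(obm, fam),
                     error = function(e)
                       stop("fingerprint family '", fam, "' failed: ",
                            conditionMessage(e)))
    if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
    if (nrow(bits) != length(mols))
      stop("fingerprint error: OpenBabel returned ", nrow(bits),
           " fingerprints for ", length(mols), " molecules (family ", fam,
           "); an input failed to sanitize")
    if (ncol(bits) != layout$bits[i])
      stop("family '", fam, "' produced ", ncol(bits),
           " bits, layout declares ", layout$bits[i])
    bits
  })
  fp <- do.call(cbind, blocks)
  storage.mode(fp) <- "integer"
  rownames(fp) <- vapply(mols, function(m) m$id, character(1))
  colnames(fp) <- NULL
  attr(fp, "layout_id") <- attr(layout, "layout_id")
  fp
}

#' Pack a binary fingerprint into bytes; unpack it back
#'
#' Lossless bit-packing used to store fingerprints compactly at rest:
#' 8 bits per byte, little-endian within each byte, zero-padded to a whole
#' byte. \code{unpackBits(packBits(fp), length(fp))} is the identity.
#'
#' @param bits Integer/logical 0-1 vector.
#' @return \code{packFingerprint}: raw vector of \code{ceiling(L/8)} bytes.
#' @examples
#' fp <- c(1L, 0L, 1L, 1L)
#' unpackFingerprint(packFingerprint(fp), 4L)
#' @export
packFingerprint <- function(bits) {
  stopifnot(all(bits %in% c(0L, 1L)))
  L <- length(bits)
  pad <- (8L - L %% 8L) %% 8L
  packBits(as.logical(c(bits, rep(0L, pad))), type = "raw")
}

#' @rdname packFingerprint
#' @param bytes Raw vector from \code{packFingerprint}.
#' @param L Declared fingerprint length.
#' @export
unpackFingerprint <- function(bytes, L) {
  stopifnot(is.raw(bytes))
  if (length(bytes) != ceiling(L / 8))
    stop("fingerprint corruption: ", length(bytes), " bytes cannot hold a ",
         L, "-bit fingerprint")
  bits <- as.integer(rawToBits(bytes))
  if (any(bits[seq.int(L + 1L, length.out = length(bits) - L)] != 0L))
    stop("fingerprint corruption: non-zero padding bits")
  bits[seq_len(L)]
}

#' Per-bit occupancy profile and class-balance bit selection
#'
#' Occupancy of bit i is its mean over the supplied fingerprints. Bits are
#' selected for SVM training when their occupancy lies in the closed
#' interval \code{[bounds[1], bounds[2]]} (default \code{[0.05, 0.95]}),
#' i.e. bits that are nearly always on or nearly always off are dropped for
#' class balance.
#'
#' @param fps Integer 0/1 matrix (rows = compounds) from
#'   [computeFingerprints()].
#' @param bounds Closed occupancy interval, default \code{c(0.05, 0.95)}.
#' @return List with \code{occupancy} (numeric vector), \code{selected_bits}
#'   (integer indices) and \code{layout_id}.
#' @export
occupancyProfile <- function(fps, bounds = c(0.05, 0.95)) {
  stopifnot(is.matrix(fps), nrow(fps) >= 1L,
            length(bounds) == 2L, bounds[1] <= bounds[2])
  occ <- colMeans(fps)
  sel <- which(occ >= bounds[1] & occ <= bounds[2])
  list(occupancy = occ, selected_bits = as.integer(sel),
       bounds = bounds, layout_id = attr(fps, "layout_id"))
}
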