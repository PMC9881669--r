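## Indexed on-disk compound store (HDF5).
##
## Column-oriented layout, records sorted by exact mass so that mass-window
## retrieval is a binary search on the /exact_mass dataset plus a contiguous
## slice read of the other columns. Fingerprints are bit-packed bytes;
## fragment patterns are stored as one concatenated ragged array with
## per-record offsets. A JSON manifest sidecar (store.h5.json) duplicates
## the manifest stored inside the file.

.STORE_VERSION <- "1"

#' CompoundStore: handle to an indexed on-disk compound store
#'
#' @slot path Path to the HDF5 store file.
#' @slot manifest Manifest list (store_version, fingerprint_layout,
#'   compound_count, build_parameters).
#' @slot masses In-memory copy of the sorted exact-mass index.
#' @export
setClass("CompoundStore", representation(
  path = "character", manifest = "list", masses = "numeric"
))

setValidity("CompoundStore", function(object) {
  if (!file.exists(object@path)) return(paste("no such store:", object@path))
  if (object@manifest$compound_count != length(object@masses))
    return("manifest compound_count disagrees with mass index")
  if (is.unsorted(object@masses)) return("mass index is not sorted")
  TRUE
})

setMethod("show", "CompoundStore", function(object) {
  lay <- object@manifest$fingerprint_layout
  cat("CompoundStore: ", object@path, "\n",
      "  ", object@manifest$compound_count, " compounds, ",
      if (length(object@masses))
        sprintf("%.4f-%.4f Da", min(object@masses), max(object@masses))
      else "empty",
      "\n  fingerprint layout '", object@manifest$layout_id, "' (",
      sum(lay$bits), " bits)\n", sep = "")
})

#' Number of compounds in a store
#' @param x A \linkS4class{CompoundStore}.
#' @export
setMethod("length", "CompoundStore",
          function(x) x@manifest$compound_count)

#' Build an indexed compound store from SMILES or SDF input
#'
#' Parses every record, deduplicates by standard InChI (first occurrence
#' wins), computes the fingerprint and the in-silico fragmentation pattern
#' per compound, and writes the store sorted by exact mass together with its
#' manifest. Unparseable records are skipped and counted.
#'
#' @param input Path to a SMILES file (one per line, optional
#'   whitespace-separated id) or an SDF (V2000) file, or a list of parsed
#'   molecules.
#' @param out Output path for the HDF5 store.
#' @param layout Fingerprint layout name (see [fingerprintLayout()]).
#' @param maxBonds Maximum simultaneously broken bonds for the fragment
#'   patterns (default 2).
#' @param dedupTol Fragment-mass deduplication tolerance in Da.
#' @param sourceDb Short label recorded per record (e.g. \code{"toy"}).
#' @param format \code{"auto"} (by extension), \code{"smiles"} or
#'   \code{"sdf"}.
#' @return An open \linkS4class{CompoundStore}; attribute \code{skipped}
#'   gives the number of skipped input records.
#' @export
buildStore <- function(input, out, layout = "reference", maxBonds = 2L,
                       dedupTol = 1e-4, sourceDb = "user",
                       format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (is.list(input) && all(vapply(input, inherits, logical(1), "mmMol"))) {
    mols <- input
    nSkip <- length(attr(input, "skipped") %||% integer(0))
  } else {
    stopifnot(file.exists(input))
    if (format == "auto")
      format <- if (grepl("\\.sdf$", input, ignore.case = TRUE))
        "sdf" else "smiles"
    if (format == "sdf") {
      mols <- parseSdfFile(input)
    } else {
      lines <- readLines(input, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (!length(lines)) stop("no compounds: empty input '", input, "'")
      parts <- strsplit(trimws(lines), "[[:space:]]+")
      smi <- vapply(parts, `[`, character(1), 1L)
      ids <- vapply(seq_along(parts), function(i)
        if (length(parts[[i]]) > 1L) parts[[i]][2] else paste0("rec", i),
        character(1))
      mols <- parseSmiles(smi, ids = ids)
    }
    skipped <- attr(mols, "skipped")
    nSkip <- length(skipped)
    if (nSkip)
      message("skipped ", nSkip, " unparseable record(s): ",
              paste(skipped, collapse = ", "))
  }
  if (!length(mols)) stop("no compounds: nothing parseable in input")

  ## dedup by full standard InChI, first occurrence wins
  inchis <- vapply(mols, function(m) m$inchi, character(1))
  dup <- duplicated(inchis)
  if (any(dup))
    message("dropped ", sum(dup), " duplicate record(s) by InChI: ",
            paste(vapply(mols[dup], function(m) m$id, character(1)),
                  collapse = ", "))
  mols <- mols[!dup]

  lay <- fingerprintLayout(layout)
  fps <- computeFingerprints(mols, layout = lay)
  pats <- lapply(mols, enumerateFragments, maxBonds = maxBonds,
                 dedupTol = dedupTol)

  ord <- order(vapply(mols, function(m) m$exact_mass, numeric(1)),
               vapply(mols, function(m) m$inchikey, character(1)))
  mols <- mols[ord]; fps <- fps[ord, , drop = FALSE]; pats <- pats[ord]

  manifest <- list(
    store_version = .STORE_VERSION,
    layout_id = attr(lay, "layout_id"),
    fingerprint_layout = data.frame(family = lay$family, bits = lay$bits),
    compound_count = length(mols),
    build_parameters = list(max_bonds_broken = as.integer(maxBonds),
                            dedup_tolerance_da = dedupTol,
                            source_db = sourceDb,
                            skipped_records = as.integer(nSkip))
  )
  .writeStore(out, mols, fps, pats, manifest, sourceDb)
  st <- openStore(out)
  attr(st, "skipped") <- nSkip
  st
}

.writeStore <- function(out, mols, fps, pats, manifest, sourceDb) {
  if (file.exists(out)) file.remove(out)
  rhdf5::h5createFile(out)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  getc <- function(f) vapply(mols, function(m) as.character(m[[f]]),
                             character(1))
  rhdf5::h5write(vapply(mols, function(m) m$exact_mass, numeric(1)),
                 out, "exact_mass")
  for (f in c("inchi", "inchikey", "smiles", "formula", "id"))
    rhdf5::h5write(getc(f), out, f)
  rhdf5::h5write(rep(sourceDb, length(mols)), out, "source_db")
  rhdf5::h5write(vapply(mols, function(m) as.integer(m$charge), integer(1)),
                 out, "charge")
  ## bit-packed fingerprints: one column of bytes per compound
  packed <- vapply(seq_len(nrow(fps)),
                   function(i) packFingerprint(fps[i, ]),
                   raw(ceiling(ncol(fps) / 8)))
  rhdf5::h5createDataset(out, "fingerprints", dims = dim(packed),
                         storage.mode = "raw")
  rhdf5::h5write(packed, out, "fingerprints")
  ## ragged fragment patterns
  counts <- vapply(pats, length, integer(1))
  rhdf5::h5write(as.integer(counts), out, "frag_counts")
  rhdf5::h5write(as.numeric(unlist(pats)), out, "frag_masses")
  rhdf5::h5write(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                               digits = NA)),
                 out, "manifest_json")
  jsonlite::write_json(manifest, paste0(out, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' Open an existing compound store
#' @param path Path to a store built by [buildStore()].
#' @return A \linkS4class{CompoundStore}.
#' @export
openStore <- function(path) {
  stopifnot(file.exists(path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  manifest <- jsonlite::fromJSON(rhdf5::h5read(path, "manifest_json"))
  masses <- as.numeric(rhdf5::h5read(path, "exact_mass"))
  methods::new("CompoundStore", path = path, manifest = manifest,
               masses = masses)
}

## Read full records for a set of row indices (1-based, ascending).
.readRecords <- function(store, idx) {
  if (!length(idx)) return(.emptyRecords(store))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  p <- store@path
  L <- sum(store@manifest$fingerprint_layout$bits)
  rd <- function(name) rhdf5::h5read(p, name, index = list(idx))
  packed <- rhdf5::h5read(p, "fingerprints", index = list(NULL, idx))
  counts <- as.integer(rhdf5::h5read(p, "frag_counts"))
  offs <- cumsum(c(0L, counts))
  pats <- lapply(idx, function(i)
    as.numeric(rhdf5::h5read(p, "frag_masses",
                             index = list(seq.int(offs[i] + 1L,
                                                  length.out = counts[i])))))
  fps <- t(vapply(seq_along(idx),
                  function(j) unpackFingerprint(as.raw(packed[, j]), L),
                  integer(L)))
  df <- data.frame(
    id = as.character(rd("id")), source_db = as.character(rd("source_db")),
    inchi = as.character(rd("inchi")),
    inchikey = as.character(rd("inchikey")),
    smiles = as.character(rd("smiles")),
    formula = as.character(rd("formula")),
    exact_mass = as.numeric(rd("exact_mass")),
    charge = as.integer(rd("charge")),
    stringsAsFactors = FALSE
  )
  df$fingerprint <- lapply(seq_len(nrow(fps)), function(i) fps[i, ])
  df$frag_pattern <- pats
  df
}

.emptyRecords <- function(store) {
  df <- data.frame(id = character(0), source_db = character(0),
                   inchi = character(0), inchikey = character(0),
                   smiles = character(0), formula = character(0),
                   exact_mass = numeric(0), charge = integer(0),
                   stringsAsFactors = FALSE)
  df$fingerprint <- list(); df$frag_pattern <- list()
  df
}

#' Retrieve candidate compounds by exact-mass window
#'
#' Returns every record whose exact mass lies within the tolerance window of
#' \code{targetMass} (ppm half-window = mass x tol x 1e-6), ordered by
#' absolute mass deviation, ties broken by InChI key.
#'
#' @param store A \linkS4class{CompoundStore}.
#' @param targetMass Neutral target mass in Da (use
#'   [neutralMassFromPrecursor()] for an observed precursor).
#' @param tol Tolerance value (> 0).
#' @param mode \code{"ppm"} or \code{"da"}.
#' @return Record data frame (possibly 0 rows) with list-columns
#'   \code{fingerprint} and \code{frag_pattern}, plus \code{delta_mass}.
#' @examples \dontrun{
#' hits <- queryByMass(store, 180.0634, tol = 20, mode = "ppm")
#' }
#' @export
queryByMass <- function(store, targetMass, tol, mode = c("ppm", "da")) {
  mode <- match.arg(mode)
  stopifnot(tol > 0)
  half <- if (mode == "ppm") targetMass * tol * 1e-6 else tol
  lo <- findInterval(targetMass - half, store@masses,
                     left.open = TRUE) + 1L
  hi <- findInterval(targetMass + half, store@masses)
  if (hi < lo) return(.emptyRecords(store))
  recs <- .readRecords(store, seq.int(lo, hi))
  recs$delta_mass <- recs$exact_mass - targetMass
  recs <- recs[abs(recs$delta_mass) <= half + 1e-12, , drop = FALSE]
  recs[order(abs(recs$delta_mass), recs$inchikey), , drop = FALSE]
}

#' Fetch one full record by InChI key
#'
#' @param store A \linkS4class{CompoundStore}.
#' @param inchikey 27-character InChI key of a stored compound.
#' @return One-row record data frame (fingerprint decompressed, fragment
#'   pattern attached).
#' @export
getRecord <- function(store, inchikey) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  keys <- as.character(rhdf5::h5read(store@path, "inchikey"))
  i <- match(inchikey, keys)
  if (is.na(i)) stop("not found: no record with InChI key '", inchikey, "'")
  .readRecords(store, i)
}

#' Store manifest
#' @param store A \linkS4class{CompoundStore}.
#' @return Manifest list.
#' @export
storeManifest <- function(store) store@manifest
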