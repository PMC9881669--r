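## Molecule parsing and elemental mass arithmetic.
##
## All structure handling goes through OpenBabel (via ChemmineOB/ChemmineR).
## Molecules are converted with explicit hydrogens before graph extraction so
## that single-heavy-atom species (water, methane) have a non-empty bond block
## and so that fragment masses can be summed directly over atoms.

#' Monoisotopic atomic masses
#'
#' Masses (Da) of the most abundant isotope for the elements commonly found
#' in metabolites. Used for exact-mass and fragment-mass arithmetic.
#'
#' @format Named numeric vector, one entry per element symbol.
#' @keywords internal
.MONOISO <- c(
  H  = 1.00782503207,  C  = 12.0,           N  = 14.0030740048,
  O  = 15.9949146196,  P  = 30.97376163,    S  = 31.97207100,
  F  = 18.99840322,    Cl = 34.96885268,    Br = 78.9183371,
  I  = 126.904473,     Na = 22.9897692809,  K  = 38.96370668,
  Se = 79.9165213,     B  = 11.0093054,     Si = 27.9769265325,
  Mg = 23.9850417,     Ca = 39.96259098,    Fe = 55.9349375,
  Zn = 63.9291422,     Cu = 62.9295975,     Mn = 54.9380451,
  Co = 58.9331950,     As = 74.9215965,     Li = 7.01600455
)

## electron rest mass in Da; exact masses of ions subtract charge * .ELECTRON
.ELECTRON <- 0.00054857990907

## proton mass = H atom mass - electron mass
.PROTON <- 1.00727645216

#' Parse a Hill-order molecular formula into element counts
#'
#' @param formula Character scalar such as \code{"C6H12O6"}.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  f <- gsub("[[:space:]+-]", "", formula)
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (length(toks) == 0L || paste(toks, collapse = "") != f)
    stop("cannot parse formula: '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  n[is.na(n)] <- 1L
  bad <- setdiff(el, names(.MONOISO))
  if (length(bad))
    stop("unknown element(s) in formula '", formula, "': ",
         paste(bad, collapse = ", "))
  counts <- vapply(split(n, el), sum, integer(1))
  counts[order(names(counts))]
}

#' Format element counts in Hill order
#'
#' Hill convention: carbon first, then hydrogen, then all other elements
#' alphabetically; if no carbon, everything alphabetical.
#'
#' @param counts Named integer vector of element counts.
#' @return Character scalar.
#' @export
hillFormula <- function(counts) {
  counts <- counts[counts > 0]
  el <- names(counts)
  if ("C" %in% el) {
    rest <- sort(setdiff(el, c("C", "H")))
    ord <- c("C", intersect("H", el), rest)
  } else {
    ord <- sort(el)
  }
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' @param formula Hill formula string or named count vector.
#' @param charge Net formal charge; the mass of \code{charge} electrons is
#'   subtracted (so cations are lighter than their atom sum).
#' @return Mass in Da.
#' @examples
#' formulaMass("H2O")      # 18.0106
#' formulaMass("C2H6O")    # 46.0419
#' @export
formulaMass <- function(formula, charge = 0L) {
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  sum(.MONOISO[names(counts)] * counts) - charge * .ELECTRON
}

## ---------------------------------------------------------------------------
## OpenBabel conversion helpers (per-record so failures are attributable)

.obConvert <- function(from, to, source) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, source),
    error = function(e) ""
  )
  if (!length(out)) out <- ""
  out
}

## Convert one record to an explicit-hydrogen V2000 SDF text block.
.toExplicitSdf <- function(from, source) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, "SDF", source,
                              options = data.frame(names = "h", args = "")),
    error = function(e) ""
  )
  if (!length(out) || !nzchar(out) || !grepl("V2000", out)) return(NULL)
  out
}

## Net formal charge from the /q and /p layers of a standard InChI.
.chargeFromInchi <- function(inchi) {
  q <- regmatches(inchi, regexpr("/q([+-][0-9]+)", inchi))
  p <- regmatches(inchi, regexpr("/p([+-][0-9]+)", inchi))
  qv <- if (length(q)) as.integer(sub("/q", "", q)) else 0L
  pv <- if (length(p)) as.integer(sub("/p", "", p)) else 0L
  qv + pv
}

#' Parse molecules from SMILES strings
#'
#' Each SMILES is converted (with explicit hydrogens) to a molecular graph,
#' and identifier fields (InChI, InChI key, Hill formula, monoisotopic exact
#' mass, net formal charge) are derived. Records that OpenBabel cannot parse
#' are skipped and reported in the \code{skipped} attribute.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional character vector of identifiers (defaults to
#'   \code{mol1 ... molN}).
#' @return A list of molecule objects (class \code{mmMol}); attribute
#'   \code{skipped} holds the indices of unparseable records.
#' @examples
#' mols <- parseSmiles(c("O", "CCO"))
#' mols[[2]]$formula   # "C2H6O"
#' @export
parseSmiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles))
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  mols <- vector("list", length(smiles))
  skipped <- integer(0)
  for (i in seq_along(smiles)) {
    m <- .parseOne("SMI", smiles[i], ids[i], smiles = smiles[i])
    if (is.null(m)) skipped <- c(skipped, i) else mols[[i]] <- m
  }
  mols <- mols[!vapply(mols, is.null, logical(1))]
  attr(mols, "skipped") <- skipped
  mols
}

#' Parse molecules from an SDF (V2000) file
#'
#' @param path Path to an SDF file; the record title line is used as the id
#'   when present.
#' @return As [parseSmiles()]: list of molecule objects with a
#'   \code{skipped} attribute.
#' @export
parseSdfFile <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("no compounds: empty input file '", path, "'")
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) stop("malformed SDF (no $$$$ record terminator): ", path)
  starts <- c(1L, head(ends, -1L) + 1L)
  mols <- vector("list", length(ends))
  skipped <- integer(0)
  for (i in seq_along(ends)) {
    rec <- lines[starts[i]:ends[i]]
    id <- trimws(rec[1])
    if (!nzchar(id)) id <- paste0("rec", i)
    txt <- paste(c(rec, ""), collapse = "\n")
    smi <- trimws(sub("\t.*", "", .obConvert("SDF", "CAN", txt)))
    m <- .parseOne("SDF", txt, id, smiles = smi)
    if (is.null(m)) skipped <- c(skipped, i) else mols[[i]] <- m
  }
  mols <- mols[!vapply(mols, is.null, logical(1))]
  attr(mols, "skipped") <- skipped
  mols
}

## Build one mmMol from a single-record source in format `from`.
.parseOne <- function(from, source, id, smiles = NA_character_) {
  inchi <- trimws(.obConvert(from, "INCHI", source))
  if (!nzchar(inchi) || !startsWith(inchi, "InChI=")) return(NULL)
  inchikey <- trimws(.obConvert(from, "INCHIKEY", source))
  sdfh <- .toExplicitSdf(from, source)
  if (is.null(sdfh)) return(NULL)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(unlist(strsplit(sdfh, "\n")))),
    error = function(e) NULL
  )
  if (is.null(sdfset) || length(sdfset) != 1L) return(NULL)
  mol <- sdfset[[1]]
  ab <- ChemmineR::atomblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  if (any(!elements %in% names(.MONOISO))) return(NULL)
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(integer(0), ncol = 2L)
  } else {
    unname(cbind(as.integer(bb[, 1]), as.integer(bb[, 2])))
  }
  charge <- .chargeFromInchi(inchi)
  counts <- table(elements)
  counts <- stats::setNames(as.integer(counts), names(counts))
  formula <- hillFormula(counts)
  exactMass <- formulaMass(counts, charge = charge)
  structure(
    list(id = id, smiles = smiles, inchi = inchi, inchikey = inchikey,
         formula = formula, exact_mass = exactMass, charge = charge,
         elements = elements, bonds = bonds),
    class = "mmMol"
  )
}

#' @export
print.mmMol <- function(x, ...) {
  cat("mmMol ", x$id, ": ", x$formula,
      sprintf(" (%.4f Da, charge %+d)\n", x$exact_mass, x$charge), sep = "")
  cat("  ", x$inchikey, "\n", sep = "")
  invisible(x)
}

## Heavy-atom graph view used by the fragmenter: nodes are heavy atoms
## carrying the mass of their attached hydrogens; edges are heavy-heavy bonds.
.heavyGraph <- function(mol) {
  heavy <- which(mol$elements != "H")
  if (!length(heavy))
    heavy <- seq_along(mol$elements)  # H2 and friends: treat all atoms
  idx <- match(seq_along(mol$elements), heavy)
  nodeMass <- .MONOISO[mol$elements[heavy]]
  names(nodeMass) <- NULL
  b <- mol$bonds
  if (nrow(b)) {
    hH <- mol$elements[b[, 1]] == "H" | mol$elements[b[, 2]] == "H"
    for (k in which(hH)) {
      a <- b[k, ]; hv <- a[mol$elements[a] != "H"]
      if (length(hv) == 1L)
        nodeMass[idx[hv]] <- nodeMass[idx[hv]] + .MONOISO[["H"]]
    }
    bh <- b[!hH, , drop = FALSE]
    edges <- cbind(idx[bh[, 1]], idx[bh[, 2]])
  } else {
    edges <- matrix(integer(0), ncol = 2L)
  }
  list(nodeMass = nodeMass, edges = edges)
}

## Explicit-atom graph view (every atom a node) for X-H cleavage mode.
.fullGraph <- function(mol) {
  list(nodeMass = unname(.MONOISO[mol$elements]), edges = mol$bonds)
}
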