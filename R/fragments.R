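## In-silico fragmentation: enumerate neutral fragment masses obtainable by
## deleting up to `maxBonds` bonds from the molecular graph.
##
## Fragment masses are plain atomic-mass sums over the severed subgraph
## (homolytic bookkeeping, no valence repair, no hydrogen transfer at the
## cut); hydrogen mobility is absorbed at match time by the +/- 1 H
## correction in fragScore(). Bond breakage rates are not modelled: the
## pattern is a mass set only.

#' Enumerate the in-silico fragmentation pattern of a molecule
#'
#' Deletes every subset of at most \code{maxBonds} bonds of the molecular
#' graph and collects the neutral monoisotopic masses of the resulting
#' connected components, plus the intact parent mass. By default only bonds
#' between heavy atoms are cleavable (hydrogens stay attached to their heavy
#' atom); \code{cleaveH = TRUE} also allows X-H bond cleavage.
#'
#' @param mol A molecule from [parseSmiles()] / [parseSdfFile()].
#' @param maxBonds Maximum number of bonds broken simultaneously
#'   (default 2).
#' @param dedupTol Masses closer than this (Da) are collapsed, keeping the
#'   smallest of each cluster (default 1e-4).
#' @param cleaveH Also cleave bonds to hydrogen (default \code{FALSE}).
#' @return Numeric vector of strictly increasing fragment masses (Da),
#'   including the parent exact mass, with attributes \code{parent_mass} and
#'   \code{max_bonds}.
#' @examples
#' mol <- parseSmiles("CC")[[1]]
#' enumerateFragments(mol, maxBonds = 1)  # CH3 radical mass + parent
#' @export
enumerateFragments <- function(mol, maxBonds = 2L, dedupTol = 1e-4,
                               cleaveH = FALSE) {
  stopifnot(inherits(mol, "mmMol"), maxBonds >= 0L, dedupTol > 0)
  g <- if (cleaveH) .fullGraph(mol) else .heavyGraph(mol)
  n <- length(g$nodeMass)
  parent <- sum(g$nodeMass)
  if (abs(parent - (mol$exact_mass + mol$charge * .ELECTRON)) > 1e-6)
    stop("internal mass bookkeeping error for ", mol$id)
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  if (igraph::components(ig)$no > 1L)
    stop("disconnected input molecule: ", mol$id,
         " (fragment patterns are per connected structure)")
  nb <- nrow(g$edges)
  masses <- parent
  maxBonds <- min(as.integer(maxBonds), nb)
  if (maxBonds >= 1L && nb > 0L) {
    acc <- vector("list", maxBonds)
    for (k in seq_len(maxBonds)) {
      subs <- utils::combn(nb, k)
      out <- numeric(0)
      for (j in seq_len(ncol(subs))) {
        sg <- igraph::delete_edges(ig, subs[, j])
        memb <- igraph::components(sg)$membership
        out <- c(out, vapply(split(g$nodeMass, memb), sum, numeric(1),
                             USE.NAMES = FALSE))
      }
      acc[[k]] <- out
    }
    masses <- c(masses, unlist(acc))
  }
  res <- .dedupMasses(masses, dedupTol)
  structure(res, parent_mass = parent, max_bonds = maxBonds)
}

## Collapse sorted masses: keep a value only if it exceeds the last kept one
## by more than tol (so the smallest member of each cluster is retained).
.dedupMasses <- function(masses, tol) {
  m <- sort(masses)
  keep <- logical(length(m))
  last <- -Inf
  for (i in seq_along(m)) {
    if (m[i] - last > tol) { keep[i] <- TRUE; last <- m[i] }
  }
  m[keep]
}
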