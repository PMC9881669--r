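# Independent brute-force fragmentation oracle: enumerates every bond
# subset of size <= maxBonds with explicit nested loops and finds connected
# components with union-find (no igraph), summing monoisotopic atom masses.
# Kept deliberately separate from the package's implementation.

bruteForceFragments <- function(mol, maxBonds, dedupTol = 1e-4) {
  g <- metaboMatch:::.heavyGraph(mol)
  n <- length(g$nodeMass)
  edges <- g$edges
  nb <- nrow(edges)
  compMasses <- function(dropIdx) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    keep <- setdiff(seq_len(nb), dropIdx)
    for (e in keep) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
    roots <- vapply(seq_len(n), find, integer(1))
    vapply(split(g$nodeMass, roots), sum, numeric(1), USE.NAMES = FALSE)
  }
  out <- sum(g$nodeMass)
  if (maxBonds >= 1 && nb >= 1)
    for (i in seq_len(nb)) out <- c(out, compMasses(i))
  if (maxBonds >= 2 && nb >= 2)
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb)
      out <- c(out, compMasses(c(i, j)))
  if (maxBonds >= 3) stop("oracle supports maxBonds <= 2")
  sortedUnique <- sort(out)
  kept <- numeric(0); last <- -Inf
  for (m in sortedUnique)
    if (m - last > dedupTol) { kept <- c(kept, m); last <- m }
  kept
}

# All single-bond cuts that disconnect the graph, as pairs of component
# masses (for the mass-conservation check).
singleCutMassPairs <- function(mol) {
  g <- metaboMatch:::.heavyGraph(mol)
  n <- length(g$nodeMass)
  edges <- g$edges
  pairs <- list()
  for (e in seq_len(nrow(edges))) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in setdiff(seq_len(nrow(edges)), e)) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
    roots <- vapply(seq_len(n), find, integer(1))
    ms <- vapply(split(g$nodeMass, roots), sum, numeric(1),
                 USE.NAMES = FALSE)
    if (length(ms) == 2L) pairs[[length(pairs) + 1L]] <- ms
  }
  pairs
}
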