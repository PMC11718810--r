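## Independent oracles kept out of the package code paths they check.

with_seed <- cephaloid:::with_seed

## Edge collapse: the inverse of T1 edge formation. Merges the two endpoints
## of an edge into a single vertex and drops the edge from its two incident
## facets. Collapsing the edge a T1 move created must restore a complex
## isomorphic to the move's input.
collapse_edge <- function(x, u, v, merged = paste0(u, "+", v)) {
  facets <- lapply(x$facets, function(cyc) {
    cyc[cyc %in% c(u, v)] <- merged
    keep <- cyc != c(cyc[-1], cyc[1])  # drop the first of equal neighbours
    cyc[keep]
  })
  polyhedral_complex(facets, labels = x$labels[!is.na(x$labels)])
}

## Exhaustive permutation isomorphism oracle for small labelled graphs.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

brute_force_isomorphic <- function(g1, g2) {
  n <- igraph::vcount(g1)
  if (n != igraph::vcount(g2) ||
      igraph::ecount(g1) != igraph::ecount(g2)) return(FALSE)
  A1 <- as.matrix(igraph::as_adjacency_matrix(g1))
  A2 <- as.matrix(igraph::as_adjacency_matrix(g2))
  perms <- permutations(n)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (all(A1 == A2[p, p])) return(TRUE)
  }
  FALSE
}

## Facet multiset comparison: same cyclic sequences up to rotation (the
## canonical rotation makes cycles directly comparable) regardless of
## facet ids.
same_facet_cycles <- function(a, b) {
  key <- function(x) sort(unname(vapply(x$facets, paste, collapse = "|", "")))
  identical(key(a), key(b))
}
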