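#' Count graphlet orbits for every analysis cell
#'
#' For each analysis node, counts the connected induced subgraphs on 2-5
#' nodes containing it, classified by the automorphism orbit the node
#' occupies (73 orbits).  Enumeration runs over the full graph -- border
#' cells participate as context -- but rows are reported only for analysis
#' nodes.  Column `o0` equals node degree.
#'
#' @param graph a `contact_graph`
#' @param catalogue a [build_catalogue()] object (defaults to the cached one)
#' @return an `orbit_counts` matrix (analysis nodes x 73), rownames = cell
#'   labels, colnames `o0..o72`
#' @export
count_orbits <- function(graph, catalogue = default_catalogue()) {
  stopifnot(inherits(graph, "contact_graph"),
            inherits(catalogue, "graphlet_catalogue"))
  g <- graph$graph
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  m <- cpp_count_orbits(n, el, catalogue$graphlets, catalogue$n_orbits)
  finish_orbit_matrix(m, g, catalogue)
}

finish_orbit_matrix <- function(m, g, catalogue) {
  rownames(m) <- igraph::V(g)$name
  colnames(m) <- paste0("o", seq_len(catalogue$n_orbits) - 1L)
  keep <- igraph::V(g)$analysis
  if (!any(keep)) warning("empty analysis set; returning 0-row matrix")
  m <- m[keep, , drop = FALSE]
  class(m) <- c("orbit_counts", class(m))
  m
}

#' @export
print.orbit_counts <- function(x, ...) {
  cat("orbit_counts:", nrow(x), "cells x", ncol(x), "orbits\n")
  if (nrow(x)) print(utils::head(unclass(x)[, 1:10, drop = FALSE], 3))
  invisible(x)
}

# --- brute-force oracle ------------------------------------------------------

# mask -> per-position global orbit lookup, built by canonicalizing every
# k-node adjacency mask with an explicit permutation search (independent of
# the C++ table construction).
oracle_cache <- new.env(parent = emptyenv())
oracle_lookup <- function(catalogue) {
  key <- "lut"
  if (!is.null(oracle_cache[[key]])) return(oracle_cache[[key]])
  by_mask <- list()
  for (g in catalogue$graphlets)
    by_mask[[paste(g$n, g$mask)]] <- g
  lut <- list()
  for (k in 2:5) {
    pt <- pair_table(k)
    perms <- all_perms(k)
    L <- matrix(0L, 2^nrow(pt), k)
    for (mask in seq_len(2^nrow(pt)) - 1) {
      if (!mask_is_connected(mask, k)) next
      pm <- vapply(seq_len(nrow(perms)),
                   function(p) permute_mask(mask, perms[p, ], pt), 0)
      canon <- min(pm)
      perm <- perms[which.min(pm), ]
      g <- by_mask[[paste(k, canon)]]
      # vertex v of the subset plays role perm[v] in the canonical labeling
      L[mask + 1, ] <- g$orbit[perm] + 1L
    }
    lut[[k]] <- L
  }
  oracle_cache[[key]] <- lut
  lut
}

#' Brute-force orbit counts (verification oracle)
#'
#' Explicitly enumerates all 2-5-node subsets of the vertex set, keeps the
#' connected induced subgraphs, and classifies each member node's orbit by
#' isomorphism lookup.  Same contract as [count_orbits()]; intended for
#' small graphs (<= 60 nodes).
#'
#' @inheritParams count_orbits
#' @return an `orbit_counts` matrix
#' @export
brute_force_orbits <- function(graph, catalogue = default_catalogue()) {
  stopifnot(inherits(graph, "contact_graph"))
  g <- graph$graph
  n <- igraph::vcount(g)
  A <- matrix(0L, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  A[el] <- 1L; A[el[, c(2, 1), drop = FALSE]] <- 1L
  lut <- oracle_lookup(catalogue)
  no <- catalogue$n_orbits
  counts <- matrix(0, n, no)
  for (k in 2:5) {
    if (n < k) next
    pt <- pair_table(k)
    L <- lut[[k]]
    for (v in seq_len(n - k + 1)) {
      rest <- seq(v + 1, n)
      S <- if (k == 2) matrix(rest, nrow = 1)
           else utils::combn(rest, k - 1)
      S <- rbind(v, S)
      mask <- rep(0, ncol(S))
      for (r in seq_len(nrow(pt)))
        mask <- mask + A[cbind(S[pt[r, "i"], ], S[pt[r, "j"], ])] * pt[r, "w"]
      for (p in seq_len(k)) {
        orb <- L[cbind(mask + 1, p)]
        sel <- orb > 0L
        if (!any(sel)) next
        enc <- (S[p, sel] - 1) * no + orb[sel]
        tab <- tabulate(enc, n * no)
        counts <- counts + t(matrix(tab, no, n))
      }
    }
  }
  finish_orbit_matrix(counts, g, catalogue)
}
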