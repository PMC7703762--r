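#' Enumerate the graphlet catalogue (connected graphs on 2-5 nodes)
#'
#' Builds the catalogue of all connected non-isomorphic graphs on 2 to 5
#' nodes (30 graphlets, `G0`..`G29`) together with the automorphism orbits of
#' their vertices, numbered globally `0..72`.  Orbit 0 is the single orbit of
#' the 2-node graphlet (an edge), so a node's orbit-0 count equals its degree.
#'
#' Graphlets are ordered by node count, then edge count, then degree
#' sequence, then canonical form; orbits within a graphlet are ordered by
#' representative degree (ties broken by neighbor-degree profile).  For the
#' 2-4-node graphlets this reproduces the standard graphlet-literature
#' numbering (`G0` edge; `G1` 3-path; `G2` triangle; `G3` 4-path; `G4` claw;
#' `G5` 4-cycle; `G6` paw; `G7` diamond; `G8` K4; orbits 0-14).
#'
#' @return An object of class `graphlet_catalogue`: a list with
#'   `graphlets` (one entry per graphlet: `id`, `n`, `mask`, `edges`,
#'   `orbit` — global orbit id per vertex in canonical labeling),
#'   `n_orbits` (73) and `orbit_table` (data frame mapping global orbit id to
#'   graphlet id and a representative vertex).
#' @examples
#' cat73 <- build_catalogue()
#' cat73$n_orbits            # 73
#' length(cat73$graphlets)   # 30
#' @export
build_catalogue <- function() {
  graphlets <- list()
  for (n in 2:5) {
    pt <- pair_table(n)
    perms <- all_perms(n)
    nmask <- 2^nrow(pt)
    seen <- new.env(hash = TRUE)
    for (mask in seq_len(nmask) - 1) {
      if (!mask_is_connected(mask, n)) next
      canon <- mask
      for (p in seq_len(nrow(perms))) {
        pm <- permute_mask(mask, perms[p, ], pt)
        if (pm < canon) canon <- pm
      }
      key <- as.character(canon)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      edges <- mask_to_edges(canon, n)
      deg <- tabulate(c(edges[, 1L], edges[, 2L]), n)
      graphlets[[length(graphlets) + 1L]] <- list(
        n = n, mask = canon, edges = edges, deg = deg,
        degseq = sort(deg, decreasing = TRUE)
      )
    }
  }
  # deterministic ordering: nodes, edges, degree sequence, canonical mask
  key <- vapply(graphlets, function(g) {
    paste0(g$n, "-", sprintf("%02d", nrow(g$edges)), "-",
           paste(g$degseq, collapse = ""), "-", sprintf("%04d", g$mask))
  }, character(1))
  graphlets <- graphlets[order(key)]

  next_orbit <- 0L
  orbit_table <- NULL
  for (gi in seq_along(graphlets)) {
    g <- graphlets[[gi]]
    g$id <- paste0("G", gi - 1L)
    pt <- pair_table(g$n)
    perms <- all_perms(g$n)
    auto <- perms[apply(perms, 1L, function(p) permute_mask(g$mask, p, pt) == g$mask), ,
                  drop = FALSE]
    # vertex orbits = equivalence classes under the automorphism group
    rep_of <- apply(auto, 2L, min)  # smallest image over all automorphisms
    # order orbits by degree, then sorted neighbor degrees, then index
    adj <- matrix(FALSE, g$n, g$n)
    adj[g$edges] <- TRUE; adj[g$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
    orb_reps <- sort(unique(rep_of))
    okey <- vapply(orb_reps, function(v) {
      nd <- sort(g$deg[adj[v, ]])
      paste0(g$deg[v], "-", paste(nd, collapse = ""), "-", v)
    }, character(1))
    orb_reps <- orb_reps[order(okey)]
    gids <- next_orbit + seq_along(orb_reps) - 1L
    g$orbit <- gids[match(rep_of, orb_reps)]
    orbit_table <- rbind(orbit_table, data.frame(
      orbit = gids, graphlet = g$id, representative = orb_reps,
      degree = g$deg[orb_reps]
    ))
    next_orbit <- next_orbit + length(orb_reps)
    graphlets[[gi]] <- g
  }
  structure(list(graphlets = graphlets, n_orbits = next_orbit,
                 orbit_table = orbit_table),
            class = "graphlet_catalogue")
}

#' @export
print.graphlet_catalogue <- function(x, ...) {
  cat("Graphlet catalogue: ", length(x$graphlets),
      " connected graphs on 2-5 nodes, ", x$n_orbits, " orbits\n", sep = "")
  invisible(x)
}

#' Global orbit ids belonging to a set of graphlet ids
#' @param catalogue a [build_catalogue()] object
#' @param graphlet_ids character vector of ids such as `"G0"`
#' @return sorted integer vector of global orbit ids
#' @export
orbits_of_graphlets <- function(catalogue, graphlet_ids) {
  stopifnot(inherits(catalogue, "graphlet_catalogue"))
  unknown <- setdiff(graphlet_ids, vapply(catalogue$graphlets, `[[`, "", "id"))
  if (length(unknown))
    stop("unknown graphlet id(s): ", paste(unknown, collapse = ", "))
  sort(catalogue$orbit_table$orbit[catalogue$orbit_table$graphlet %in% graphlet_ids])
}

# cached catalogue (built once per session)
catalogue_cache <- new.env(parent = emptyenv())
default_catalogue <- function() {
  if (is.null(catalogue_cache$cat)) catalogue_cache$cat <- build_catalogue()
  catalogue_cache$cat
}
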