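#' Graphlet degree distribution profile
#'
#' For every included orbit j, tallies `d_j(k)` = number of analysis cells
#' that touch orbit j exactly k times (k >= 1), scales by `1/k`
#' (`S_j(k) = d_j(k)/k`, down-weighting high-degree contributions and
#' discarding k = 0), and normalizes to total mass 1
#' (`N_j(k) = S_j(k) / sum_k S_j(k)`).  Orbits never touched by any cell are
#' kept as empty distributions.
#'
#' @param matrix an `orbit_counts` matrix
#' @param motifs optional [load_motif_set()]; when supplied, only that set's
#'   orbits enter the profile
#' @return an object of class `gdd_profile`: list with `N` (per-orbit named
#'   numeric vectors, names = k), `orbit_ids`, `n_nodes`, `motif_set`
#' @export
gdd_profile <- function(matrix, motifs = NULL) {
  if (!is.null(motifs)) matrix <- filter_orbits(matrix, motifs)
  if (nrow(matrix) == 0) stop("orbit-count matrix has no analysis cells")
  orbit_ids <- as.integer(sub("^o", "", colnames(matrix)))
  N <- vector("list", ncol(matrix))
  names(N) <- colnames(matrix)
  for (j in seq_len(ncol(matrix))) {
    k <- matrix[, j]
    k <- k[k >= 1]
    if (!length(k)) { N[[j]] <- numeric(0); next }
    d <- table(k)
    S <- as.numeric(d) / as.numeric(names(d))
    Nj <- S / sum(S)
    names(Nj) <- names(d)
    N[[j]] <- Nj
  }
  structure(list(N = N, orbit_ids = orbit_ids, n_nodes = nrow(matrix),
                 motif_set = attr(matrix, "motif_set") %||% motifs$name %||% "all"),
            class = "gdd_profile")
}

#' @export
print.gdd_profile <- function(x, ...) {
  cat("gdd_profile:", length(x$orbit_ids), "orbits over", x$n_nodes,
      "cells (motif set:", x$motif_set, ")\n")
  invisible(x)
}

orbit_distance <- function(Na, Nb) {
  ea <- length(Na) == 0; eb <- length(Nb) == 0
  if (ea && eb) return(NA_real_)  # undefined in both -> skipped
  ks <- union(names(Na), names(Nb))
  a <- ifelse(ks %in% names(Na), Na[ks], 0)
  b <- ifelse(ks %in% names(Nb), Nb[ks], 0)
  sqrt(sum((a - b)^2)) / sqrt(2)
}

#' Graphlet degree distribution agreement distance (GDD)
#'
#' Per-orbit distance
#' \deqn{D_j = \frac{1}{\sqrt{2}}\Big(\sum_k [N_j^a(k) - N_j^b(k)]^2\Big)^{1/2}
#'   \in [0, 1],}
#' aggregated over orbits into a single GDD value in `[0, 1]`; the higher
#' the value, the more different the two cell arrangements.  Orbits empty in
#' both graphs are skipped; an orbit empty in exactly one graph contributes
#' with the empty side treated as the zero distribution.
#'
#' @param a,b [gdd_profile()] objects over identical orbit sets (profiles
#'   built with different motif sets refuse to compare)
#' @param aggregate `"arithmetic"` (default) mean of the per-orbit distances,
#'   or `"geometric"`: one minus the geometric mean of the per-orbit
#'   agreements `1 - D_j`
#' @return an object of class `gdd_result`: `gdd_value`, `per_orbit`
#'   (named `D_j` vector, `NA` for skipped orbits), `aggregate`,
#'   `motif_set`, `n_nodes` (both graphs)
#' @export
gdd_distance <- function(a, b, aggregate = c("arithmetic", "geometric")) {
  stopifnot(inherits(a, "gdd_profile"), inherits(b, "gdd_profile"))
  aggregate <- match.arg(aggregate)
  if (!identical(a$orbit_ids, b$orbit_ids))
    stop("profiles were built over different orbit sets")
  D <- mapply(orbit_distance, a$N, b$N)
  used <- !is.na(D)
  if (!any(used)) stop("no orbit has a defined distribution in either graph")
  gdd <- if (aggregate == "arithmetic") mean(D[used])
         else 1 - exp(mean(log(pmax(1 - D[used], .Machine$double.eps))))
  structure(list(gdd_value = gdd, per_orbit = D, aggregate = aggregate,
                 motif_set = a$motif_set,
                 n_nodes = c(a = a$n_nodes, b = b$n_nodes)),
            class = "gdd_result")
}

#' @export
print.gdd_result <- function(x, ...) {
  cat("GDD =", format(x$gdd_value, digits = 4),
      sprintf("(%s mean over %d orbits, motif set %s)\n", x$aggregate,
              sum(!is.na(x$per_orbit)), x$motif_set))
  invisible(x)
}

#' Average GDD profiles across replicates
#'
#' Distribution-level average: per orbit, the replicate `N_j(k)` vectors are
#' averaged (empty replicates contribute zero mass) and renormalized.
#'
#' @param profiles list of [gdd_profile()] objects over identical orbit sets
#' @return a `gdd_profile`
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ids <- profiles[[1]]$orbit_ids
  for (p in profiles)
    if (!identical(p$orbit_ids, ids)) stop("profiles have different orbit sets")
  N <- vector("list", length(ids))
  names(N) <- names(profiles[[1]]$N)
  for (j in seq_along(ids)) {
    ks <- sort(unique(unlist(lapply(profiles, function(p) names(p$N[[j]])))))
    if (!length(ks)) { N[[j]] <- numeric(0); next }
    acc <- stats::setNames(numeric(length(ks)), ks)
    for (p in profiles) {
      Nj <- p$N[[j]]
      if (length(Nj)) acc[names(Nj)] <- acc[names(Nj)] + Nj
    }
    # order numerically by k and renormalize
    acc <- acc[order(as.numeric(names(acc)))]
    N[[j]] <- acc / sum(acc)
  }
  structure(list(N = N, orbit_ids = ids,
                 n_nodes = round(mean(vapply(profiles, `[[`, 0, "n_nodes"))),
                 motif_set = profiles[[1]]$motif_set),
            class = "gdd_profile")
}
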