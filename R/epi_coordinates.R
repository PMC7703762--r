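graph_profile <- function(image_or_graph, contact_radius = 2, ring = 0,
                          catalogue = default_catalogue()) {
  g <- if (inherits(image_or_graph, "contact_graph")) image_or_graph
       else build_contact_graph(image_or_graph, contact_radius)
  if (ring > 0) g <- restrict_to_analysis_nodes(g, ring)
  gdd_profile(count_orbits(g, catalogue))
}

#' Build the bank of reference tessellation profiles
#'
#' Assembles the graphlet-degree-distribution profiles of the three
#' reference tessellations against which any tissue is embedded:
#' \describe{
#'   \item{hexagons}{a bounded honeycomb lattice; per-cell analysis is
#'     restricted to cells at graph distance > 4 from the border so that
#'     every counted 2-5-node subgraph lies in untruncated honeycomb (a
#'     graphlet spans at most 4 edges), making the reference an exact point
#'     mass per orbit, as in an infinite lattice.}
#'   \item{random}{random Voronoi tessellations, profile averaged over
#'     `n_replicates` at the distribution level and renormalized.}
#'   \item{voronoi5}{Voronoi diagram 5 of the plain CVT path (5 Lloyd
#'     relaxations from random seeds), averaged the same way.}
#' }
#'
#' @param n_seeds,width,height canvas parameters of the Voronoi references
#' @param n_replicates replicate tessellations averaged per stochastic
#'   reference (default 20)
#' @param hex_rows,hex_cols,hex_diameter honeycomb reference lattice
#' @param contact_radius contact radius passed to [build_contact_graph()]
#' @param rng_seed master seed; the bank is reproducible from its recorded
#'   parameters
#' @param catalogue a [build_catalogue()] object
#' @return an object of class `reference_bank` with elements `hexagons`,
#'   `random`, `voronoi5` ([gdd_profile()]s over all 73 orbits) and `params`
#' @export
build_reference_bank <- function(n_seeds = 500, width = 512, height = 512,
                                 n_replicates = 20, hex_rows = 16,
                                 hex_cols = 16, hex_diameter = 14,
                                 contact_radius = 2, rng_seed = 1,
                                 catalogue = default_catalogue()) {
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max, 2 * n_replicates))
  hex <- graph_profile(
    make_hexagonal_tessellation(hex_rows, hex_cols, hex_diameter),
    contact_radius, ring = 4, catalogue)
  rnd <- lapply(seq_len(n_replicates), function(r) {
    graph_profile(make_random_voronoi(n_seeds, width, height,
                                      rng_seed = seeds[r]),
                  contact_radius, 0, catalogue)
  })
  v5 <- lapply(seq_len(n_replicates), function(r) {
    path <- generate_cvt_path(n_seeds, width, height, max_iter = 5,
                              rng_seed = seeds[n_replicates + r], keep = 5)
    graph_profile(path[[1]]$image, contact_radius, 0, catalogue)
  })
  structure(list(hexagons = hex, random = average_profiles(rnd),
                 voronoi5 = average_profiles(v5),
                 params = list(n_seeds = n_seeds, width = width,
                               height = height, n_replicates = n_replicates,
                               hex_rows = hex_rows, hex_cols = hex_cols,
                               hex_diameter = hex_diameter,
                               contact_radius = contact_radius,
                               rng_seed = rng_seed)),
            class = "reference_bank")
}

#' @export
print.reference_bank <- function(x, ...) {
  cat("reference_bank: hexagons /", "random /", "voronoi5 profiles;",
      x$params$n_seeds, "seeds,", x$params$n_replicates, "replicates\n")
  invisible(x)
}

#' Embed a tessellation as an Epi-coordinate point
#'
#' The three coordinates are the GDD of the tissue to the three reference
#' tessellations: Epi-Hexagons (distance to the regular honeycomb),
#' Epi-Random (distance to a random Voronoi tessellation) and Epi-Voronoi5
#' (distance to Voronoi diagram 5 of the CVT path).  Together they place the
#' tissue's organization as a single point in the unit cube.
#'
#' @param x a `contact_graph`, `label_image`, or precomputed `gdd_profile`
#' @param bank a [build_reference_bank()] object
#' @param motifs a [load_motif_set()] (default the 17-motif set)
#' @param min_cells analysis cells below this emit a warning (default 50)
#' @param ... passed to [build_contact_graph()] when `x` is an image
#' @return an object of class `epi_point` with fields `epi_hexagons`,
#'   `epi_random`, `epi_voronoi5`, `n_cells`, `motif_set`
#' @export
epi_point <- function(x, bank, motifs = load_motif_set("motifs-17"),
                      min_cells = 50, ...) {
  stopifnot(inherits(bank, "reference_bank"), inherits(motifs, "motif_set"))
  prof <- if (inherits(x, "gdd_profile")) x else graph_profile(x, ...)
  if (prof$n_nodes < min_cells)
    warning("only ", prof$n_nodes, " analysis cells; Epi-coordinates may be noisy")
  dist_to <- function(ref)
    gdd_distance(restrict_profile(prof, motifs$orbit_ids),
                 restrict_profile(ref, motifs$orbit_ids))$gdd_value
  structure(list(epi_hexagons = dist_to(bank$hexagons),
                 epi_random = dist_to(bank$random),
                 epi_voronoi5 = dist_to(bank$voronoi5),
                 n_cells = prof$n_nodes, motif_set = motifs$name),
            class = "epi_point")
}

restrict_profile <- function(profile, orbit_ids) {
  sel <- profile$orbit_ids %in% orbit_ids
  if (sum(sel) != length(orbit_ids))
    stop("profile lacks orbits required by the motif set")
  structure(list(N = profile$N[sel], orbit_ids = profile$orbit_ids[sel],
                 n_nodes = profile$n_nodes, motif_set = profile$motif_set),
            class = "gdd_profile")
}

#' @export
print.epi_point <- function(x, ...) {
  cat(sprintf(
    "epi_point (%s, %d cells): Epi-Hexagons = %.4f, Epi-Random = %.4f, Epi-Voronoi5 = %.4f\n",
    x$motif_set, x$n_cells, x$epi_hexagons, x$epi_random, x$epi_voronoi5))
  invisible(x)
}

#' Extract the three coordinates of an `epi_point`
#' @param x an [epi_point()]
#' @return named numeric vector (`epi_hexagons`, `epi_random`,
#'   `epi_voronoi5`)
#' @export
epi_coords <- function(x) {
  stopifnot(inherits(x, "epi_point"))
  c(epi_hexagons = x$epi_hexagons, epi_random = x$epi_random,
    epi_voronoi5 = x$epi_voronoi5)
}

#' Build the CVTn reference scale in Epi-coordinate space
#'
#' Generates CVTn diagrams along an iteration schedule (several independent
#' replicates per scheduled iteration) and embeds each diagram through
#' [epi_point()].  The resulting cloud is the reference scale on which
#' tissues are placed and classified; it is fully reproducible from the
#' recorded parameters and seed.
#'
#' @param bank a [build_reference_bank()] object
#' @param schedule scheduled iterations (default [default_schedule()])
#' @param n_replicates replicates per scheduled iteration (default 20)
#' @param rng_seed master seed
#' @param n_seeds,width,height CVTn canvas (defaults taken from the bank)
#' @param noise_radius_px CVTn noise radius (default 5)
#' @param motifs motif set for the embedding (default the 17-motif set)
#' @return an object of class `cvtn_scale`: data frame `points`
#'   (`iteration`, `replicate`, `epi_hexagons`, `epi_random`,
#'   `epi_voronoi5`, `n_cells`), plus `schedule`, `params`, `bank`
#' @seealso [predict.cvtn_scale()] for classifying a tissue against the scale
#' @export
build_cvtn_scale <- function(bank, schedule = default_schedule(),
                             n_replicates = 20, rng_seed = 1,
                             n_seeds = NULL, width = NULL, height = NULL,
                             noise_radius_px = 5,
                             motifs = load_motif_set("motifs-17")) {
  stopifnot(inherits(bank, "reference_bank"))
  n_seeds <- n_seeds %||% bank$params$n_seeds
  width <- width %||% bank$params$width
  height <- height %||% bank$params$height
  schedule <- check_schedule(schedule)
  diagrams <- generate_cvtn_path(n_seeds, width, height, schedule,
                                 rng_seed = rng_seed,
                                 n_replicates = n_replicates,
                                 noise_radius_px = noise_radius_px)
  rows <- lapply(diagrams, function(d) {
    p <- epi_point(d$image, bank, motifs,
                   contact_radius = bank$params$contact_radius)
    data.frame(iteration = d$iteration, replicate = d$replicate,
               epi_hexagons = p$epi_hexagons, epi_random = p$epi_random,
               epi_voronoi5 = p$epi_voronoi5, n_cells = p$n_cells)
  })
  structure(list(points = do.call(rbind, rows), schedule = schedule,
                 params = list(n_seeds = n_seeds, width = width,
                               height = height, n_replicates = n_replicates,
                               noise_radius_px = noise_radius_px,
                               rng_seed = rng_seed, motif_set = motifs$name),
                 bank = bank),
            class = "cvtn_scale")
}

#' @export
print.cvtn_scale <- function(x, ...) {
  cat("cvtn_scale:", length(x$schedule), "scheduled iterations x",
      x$params$n_replicates, "replicates (", nrow(x$points), "points );",
      "motif set", x$params$motif_set, "\n")
  invisible(x)
}

#' @export
summary.cvtn_scale <- function(object, ...) {
  agg <- stats::aggregate(
    object$points[c("epi_hexagons", "epi_random", "epi_voronoi5")],
    by = list(iteration = object$points$iteration), mean)
  cat("CVTn scale, replicate-mean Epi-coordinates per iteration:\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' Plot a CVTn scale with optional tissue points
#'
#' Pairwise scatter of the three Epi-coordinates, iterations in grayscale
#' (dark = iteration 1) as in the published scale plots.
#'
#' @param x a `cvtn_scale`
#' @param points optional list of [epi_point()]s (or a single one) overlaid
#'   in red
#' @param ... ignored
#' @export
plot.cvtn_scale <- function(x, points = NULL, ...) {
  df <- x$points
  shade <- grDevices::gray(0.8 * (match(df$iteration, x$schedule) - 1) /
                             max(1, length(x$schedule) - 1))
  if (!is.null(points) && inherits(points, "epi_point")) points <- list(points)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  panes <- list(c("epi_hexagons", "epi_random"),
                c("epi_hexagons", "epi_voronoi5"),
                c("epi_random", "epi_voronoi5"))
  for (p in panes) {
    graphics::plot(df[[p[1]]], df[[p[2]]], col = shade, pch = 16,
                   xlab = p[1], ylab = p[2])
    for (tp in points)
      graphics::points(tp[[p[1]]], tp[[p[2]]], col = "red", pch = 17, cex = 1.4)
  }
  invisible(x)
}
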