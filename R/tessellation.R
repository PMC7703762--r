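#' @useDynLib epigraphr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Seed sets for Voronoi-based tessellations
#'
#' A seed set holds continuous 2D seed coordinates in pixel units on a
#' `width` x `height` canvas.  Pixel centers sit at integer coordinates
#' `0..width-1` / `0..height-1`.
#'
#' @param points two-column matrix of (x, y) coordinates in `[0, width)` x
#'   `[0, height)`
#' @param width,height canvas size in pixels
#' @return an object of class `seed_set`
#' @export
seed_set <- function(points, width, height) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 1,
            width >= 1, height >= 1)
  if (any(points[, 1] < 0 | points[, 1] >= width |
          points[, 2] < 0 | points[, 2] >= height))
    stop("all seeds must lie within [0, width) x [0, height)")
  if (anyDuplicated(points))
    stop("seed coordinates must be distinct")
  structure(list(points = unname(points), width = as.integer(width),
                 height = as.integer(height)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("seed_set:", nrow(x$points), "seeds on", x$width, "x", x$height, "canvas\n")
  invisible(x)
}

random_seed_set <- function(n_seeds, width, height, rng_seed = NULL) {
  with_seed(rng_seed, {
    repeat {
      pts <- cbind(stats::runif(n_seeds, 0, width),
                   stats::runif(n_seeds, 0, height))
      if (!anyDuplicated(pts)) break
    }
    seed_set(pts, width, height)
  })
}

label_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("label_image", "matrix", "array"))
}

#' @export
print.label_image <- function(x, ...) {
  cat("label_image:", ncol(x), "x", nrow(x), "px,",
      length(unique(as.vector(x[x > 0]))), "labels\n")
  invisible(x)
}

rasterize_seeds <- function(seeds) {
  label_image(cpp_voronoi_labels(seeds$points[, 1], seeds$points[, 2],
                                 seeds$width, seeds$height))
}

#' Rasterized random Voronoi tessellation
#'
#' Seeds are drawn uniformly on the canvas and every pixel is assigned to its
#' nearest seed, giving one convex region per seed.
#'
#' @param n_seeds number of seeds (>= 10)
#' @param width,height canvas size in pixels
#' @param rng_seed integer seed for reproducibility (optional)
#' @return a `label_image` with labels `1..n_seeds` (no background pixels)
#' @examples
#' img <- make_random_voronoi(50, 128, 128, rng_seed = 1)
#' @export
make_random_voronoi <- function(n_seeds, width = 1024, height = 1024,
                                rng_seed = NULL) {
  stopifnot(n_seeds >= 10)
  rasterize_seeds(random_seed_set(n_seeds, width, height, rng_seed))
}

#' Hexagonal (honeycomb) tessellation as a label image
#'
#' Renders an `n_rows` x `n_cols` honeycomb by rasterizing the Voronoi
#' diagram of a triangular lattice of cell centers.  Cells are numbered
#' row-major; cells of the outer ring extend to the image frame (and are thus
#' flagged border cells downstream), every interior cell is a regular hexagon
#' with exactly 6 contact neighbors.
#'
#' @param n_rows,n_cols lattice size (each >= 3, so at least one interior
#'   cell exists)
#' @param cell_diameter_px center-to-center spacing in pixels (>= 4)
#' @return a `label_image`
#' @export
make_hexagonal_tessellation <- function(n_rows, n_cols, cell_diameter_px) {
  if (n_rows < 3 || n_cols < 3)
    stop("n_rows and n_cols must be >= 3 (no interior cell otherwise)")
  if (cell_diameter_px < 4)
    stop("cell_diameter_px must be >= 4")
  d <- cell_diameter_px
  v <- d * sqrt(3) / 2
  ij <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  # quarter-cell margins: every outer-ring cell strictly reaches the frame
  # (with half-cell margins, offset-row edge cells tie with their diagonal
  # neighbors at the frame and can be shielded from it)
  x <- (ij$col + 0.25 + 0.5 * (ij$row %% 2)) * d
  y <- (ij$row + 0.25) * v
  width <- ceiling(max(x) + 0.25 * d)
  height <- ceiling(max(y) + 0.25 * v)
  rasterize_seeds(seed_set(cbind(x, y), width, height))
}

region_centroids <- function(lab, n) {
  st <- cpp_region_stats(unclass(lab), as.integer(n))
  if (any(st[, 1] == 0))
    stop("degenerate Voronoi region with zero pixels (seed ",
         paste(which(st[, 1] == 0), collapse = ", "), ")")
  cbind(st[, 2] / st[, 1], st[, 3] / st[, 1])
}

#' One Lloyd relaxation step
#'
#' Replaces every seed by the centroid of the pixels of its rasterized
#' Voronoi region.  Iterating this converges to a centroidal Voronoi
#' tessellation (CVT); the CVT energy (sum of squared pixel-to-seed
#' distances) never increases along the iteration.
#'
#' @param seeds a [seed_set()]
#' @param labels optional precomputed rasterization of `seeds` (internal
#'   reuse); when `NULL` it is computed
#' @return the relaxed `seed_set`
#' @export
lloyd_step <- function(seeds, labels = NULL) {
  stopifnot(inherits(seeds, "seed_set"))
  if (is.null(labels)) labels <- rasterize_seeds(seeds)
  cent <- region_centroids(labels, nrow(seeds$points))
  seed_set(cent, seeds$width, seeds$height)
}

#' CVT energy of a seed configuration
#'
#' Sum of squared distances from every pixel center to the seed of its
#' assigned Voronoi region; the Lyapunov function of Lloyd's algorithm.
#'
#' @param seeds a [seed_set()]
#' @return a non-negative number
#' @export
cvt_energy <- function(seeds) {
  stopifnot(inherits(seeds, "seed_set"))
  lab <- rasterize_seeds(seeds)
  cpp_cvt_energy(unclass(lab), seeds$points[, 1], seeds$points[, 2])
}

# jitter each point uniformly within a disc, clamped to the canvas
jitter_in_disc <- function(points, radius, width, height) {
  n <- nrow(points)
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- pmin(pmax(points[, 1] + r * cos(th), 0), width - 1)
  y <- pmin(pmax(points[, 2] + r * sin(th), 0), height - 1)
  cbind(x, y)
}

#' One step of the noisy Lloyd (CVTn) iteration
#'
#' Odd iterations stabilize the system with a plain Lloyd step; even
#' iterations move each seed to a uniformly random position within a disc of
#' `noise_radius_px` around its region centroid (positions falling outside
#' the canvas are clamped to the nearest in-bounds pixel center).  With
#' `noise_radius_px = 0` every iteration degenerates to plain Lloyd.
#'
#' @param seeds a [seed_set()]
#' @param iteration_index 1-based iteration counter (parity selects the
#'   branch; iteration 1 is a plain Lloyd step)
#' @param noise_radius_px disc radius in pixels (default 5)
#' @param labels optional precomputed rasterization of `seeds`
#' @return the updated `seed_set`
#' @export
cvtn_step <- function(seeds, iteration_index, noise_radius_px = 5,
                      labels = NULL) {
  stopifnot(inherits(seeds, "seed_set"), iteration_index >= 1)
  if (is.null(labels)) labels <- rasterize_seeds(seeds)
  cent <- region_centroids(labels, nrow(seeds$points))
  if (iteration_index %% 2 == 0 && noise_radius_px > 0)
    cent <- jitter_in_disc(cent, noise_radius_px, seeds$width, seeds$height)
  # jittered seeds may coincide with vanishing probability; nudge duplicates
  while (anyDuplicated(cent)) {
    dup <- duplicated(cent)
    cent[dup, ] <- jitter_in_disc(cent[dup, , drop = FALSE], 0.5,
                                  seeds$width, seeds$height)
  }
  seed_set(cent, seeds$width, seeds$height)
}

#' Default CVTn iteration schedule
#'
#' Iterations 1-20, then 30-100 in steps of 10, then 200-700 in steps of
#' 100 (38 entries), the schedule used to draw the CVTn reference scale.
#'
#' @return strictly increasing integer vector
#' @export
default_schedule <- function() {
  as.integer(c(1:20, seq(30, 100, 10), seq(200, 700, 100)))
}

check_schedule <- function(schedule) {
  schedule <- as.integer(schedule)
  stopifnot(length(schedule) >= 1, all(schedule >= 1),
            all(diff(schedule) > 0))
  schedule
}

#' Plain Lloyd relaxation path (CVT path)
#'
#' Starting from uniformly random seeds, applies `max_iter` consecutive
#' Lloyd steps; "Voronoi diagram N" is the rasterization after N steps, so
#' the sequence interpolates from a random Voronoi tessellation toward a
#' centroidal one of increasing hexagonal order.
#'
#' @param n_seeds,width,height,rng_seed as in [make_random_voronoi()]
#' @param max_iter number of Lloyd steps (>= 1)
#' @param keep iterations whose rasterization to retain (default all)
#' @return list with one entry per kept iteration: `iteration`, `image`
#'   (`label_image`), `seeds` (`seed_set` after that iteration)
#' @export
generate_cvt_path <- function(n_seeds, width = 1024, height = 1024,
                              max_iter = 5, rng_seed = NULL,
                              keep = seq_len(max_iter)) {
  stopifnot(max_iter >= 1)
  keep <- check_schedule(keep)
  seeds <- random_seed_set(n_seeds, width, height, rng_seed)
  lab <- rasterize_seeds(seeds)
  out <- vector("list", length(keep))
  for (i in seq_len(max_iter)) {
    seeds <- lloyd_step(seeds, labels = lab)
    lab <- rasterize_seeds(seeds)
    if (i %in% keep)
      out[[match(i, keep)]] <- list(iteration = i, image = lab, seeds = seeds)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Noisy Lloyd relaxation path (CVTn path)
#'
#' Runs the CVTn iteration ([cvtn_step()]) from random seeds and emits the
#' rasterized diagram at every scheduled iteration, for each replicate
#' (replicates use distinct RNG substreams derived from `rng_seed`).  The
#' alternation of noise (even iterations) and relaxation (odd iterations)
#' produces tessellations that order progressively but never reach the fully
#' hexagonal CVT limit, which is what makes the path usable as a reference
#' scale for natural packed tissues.
#'
#' @param n_seeds,width,height,rng_seed as in [make_random_voronoi()]
#' @param schedule strictly increasing iterations to emit
#'   (default [default_schedule()])
#' @param n_replicates independent replicate paths (default 1)
#' @param noise_radius_px disc radius for the even (noise) iterations
#' @return list with one entry per (replicate, scheduled iteration):
#'   `iteration`, `replicate`, `image`, `seeds`
#' @export
generate_cvtn_path <- function(n_seeds, width = 1024, height = 1024,
                               schedule = default_schedule(), rng_seed = NULL,
                               n_replicates = 1, noise_radius_px = 5) {
  schedule <- check_schedule(schedule)
  stopifnot(n_replicates >= 1)
  rep_seeds <- with_seed(rng_seed,
                         sample.int(.Machine$integer.max, n_replicates))
  out <- list()
  for (r in seq_len(n_replicates)) {
    res <- with_seed(rep_seeds[r], {
      seeds <- random_seed_set(n_seeds, width, height)
      lab <- rasterize_seeds(seeds)
      run <- vector("list", length(schedule))
      for (i in seq_len(max(schedule))) {
        seeds <- cvtn_step(seeds, i, noise_radius_px, labels = lab)
        lab <- rasterize_seeds(seeds)
        if (i %in% schedule)
          run[[match(i, schedule)]] <- list(iteration = i, replicate = r,
                                            image = lab, seeds = seeds)
      }
      run
    })
    out <- c(out, res)
  }
  out
}
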