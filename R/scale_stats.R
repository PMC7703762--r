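#' Classify a tissue point against the CVTn scale
#'
#' For every scheduled iteration, the tissue's Epi-point is compared with
#' that iteration's replicate cloud through a standardized distance with
#' diagonal covariance: per coordinate, the z-score against the replicate
#' mean and standard deviation (variances floored at `var_floor` to guard
#' against degenerate clouds), combined as the root-mean-square over the
#' three coordinates, so the score reads as "per-coordinate standard
#' deviations away from the cloud".  The tissue is assigned the iteration
#' with the smallest score and is an outlier when even that smallest score
#' exceeds `threshold_sd` -- i.e. its organization does not conform to the
#' CVTn scale.
#'
#' @param point an [epi_point()] (or numeric vector of the 3 coordinates)
#' @param scale a [build_cvtn_scale()] object
#' @param threshold_sd outlier threshold in per-coordinate SD units
#'   (default 2.5)
#' @param var_floor minimum per-coordinate variance (default `1e-4`,
#'   i.e. SD floor 0.01 on coordinates of magnitude <= 1)
#' @return an object of class `epi_report`: `closest_iteration`,
#'   `distance_score`, `is_outlier`, `threshold_sd`, `per_iteration`
#'   (data frame of all per-iteration distances), `point`
#' @export
classify_against_scale <- function(point, scale, threshold_sd = 2.5,
                                   var_floor = 1e-4) {
  stopifnot(inherits(scale, "cvtn_scale"))
  p <- if (inherits(point, "epi_point")) epi_coords(point) else as.numeric(point)
  stopifnot(length(p) == 3)
  df <- scale$points
  coords <- c("epi_hexagons", "epi_random", "epi_voronoi5")
  its <- sort(unique(df$iteration))
  rows <- lapply(its, function(it) {
    cloud <- as.matrix(df[df$iteration == it, coords, drop = FALSE])
    if (nrow(cloud) < 3) return(NULL)  # spread not estimable
    mu <- colMeans(cloud)
    v <- pmax(apply(cloud, 2, stats::var), var_floor)
    data.frame(iteration = it, n_replicates = nrow(cloud),
               distance = sqrt(mean((p - mu)^2 / v)))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop("fewer than 3 replicates at every scheduled iteration; ",
         "cannot estimate the scale's spread")
  per <- do.call(rbind, rows)
  best <- which.min(per$distance)
  structure(list(closest_iteration = per$iteration[best],
                 distance_score = per$distance[best],
                 is_outlier = per$distance[best] > threshold_sd,
                 threshold_sd = threshold_sd, var_floor = var_floor,
                 per_iteration = per,
                 point = stats::setNames(p, coords)),
            class = "epi_report")
}

#' @export
print.epi_report <- function(x, ...) {
  cat(sprintf(
    "epi_report: closest CVTn iteration = %d, distance score = %.2f SD (threshold %.2f)\n%s\n",
    x$closest_iteration, x$distance_score, x$threshold_sd,
    if (x$is_outlier) "-> OUTLIER: organization deviates from the CVTn scale"
    else "-> inlier: organization conforms to the CVTn scale"))
  invisible(x)
}

#' Classify new tissues against a fitted CVTn scale
#'
#' @param object a [build_cvtn_scale()] object
#' @param newdata an [epi_point()], a `contact_graph`, or a `label_image`
#'   (graphs/images are embedded with the scale's bank and motif set first)
#' @param threshold_sd,var_floor see [classify_against_scale()]
#' @param ... passed to [epi_point()] for graph/image inputs
#' @return an `epi_report`
#' @export
predict.cvtn_scale <- function(object, newdata, threshold_sd = 2.5,
                               var_floor = 1e-4, ...) {
  if (!inherits(newdata, "epi_point") && !is.numeric(newdata))
    newdata <- epi_point(newdata, object$bank,
                         load_motif_set(object$params$motif_set), ...)
  classify_against_scale(newdata, object, threshold_sd, var_floor)
}
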