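#' Build the cell-to-cell contact graph of a label image
#'
#' Two cells are in contact when dilating one region by a disc of
#' `contact_radius_px` pixels overlaps the other; with the default radius of
#' 2 px this bridges the thin membrane gap (0-valued pixels) present in
#' segmented real tissues while honeycomb next-nearest cells stay apart.
#' Cells whose region touches the image frame are flagged invalid (border
#' cells): their neighborhoods are truncated by the frame, so they serve as
#' graph context but are excluded from per-cell statistics.
#'
#' @param image a `label_image` (integer matrix; 0 = background/membrane)
#' @param contact_radius_px dilation radius in pixels (>= 1, default 2)
#' @return an object of class `contact_graph`: a list with `graph` (an
#'   undirected simple [igraph][igraph::graph_from_edgelist] graph whose
#'   vertex attributes are `name` = cell label, `x`, `y` = region centroid in
#'   0-based pixel coordinates, `valid`, `analysis`), `width`, `height`,
#'   `contact_radius`.
#' @export
build_contact_graph <- function(image, contact_radius_px = 2) {
  stopifnot(contact_radius_px >= 1)
  img <- unclass(as.matrix(image))
  if (any(img < 0) || any(img != round(img)))
    stop("label image must contain non-negative integers")
  storage.mode(img) <- "integer"
  labels <- sort(unique(as.vector(img[img > 0])))
  if (length(labels) < 2)
    stop("label image must contain at least 2 cells")
  nmax <- max(labels)

  comp <- cpp_region_components(img, nmax)
  split_lab <- labels[comp[labels] > 1]
  if (length(split_lab))
    warning("label(s) ", paste(utils::head(split_lab, 5), collapse = ", "),
            if (length(split_lab) > 5) ", ..." else "",
            " occupy disconnected regions; proceeding with their union")

  h <- nrow(img); w <- ncol(img)
  ep <- cpp_contact_pairs(img, contact_radius_px)

  st <- cpp_region_stats(img, nmax)
  cx <- st[labels, 2] / st[labels, 1]
  cy <- st[labels, 3] / st[labels, 1]
  border <- labels %in% c(img[1, ], img[h, ], img[, 1], img[, w])

  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  igraph::V(g)$name <- as.character(labels)
  igraph::V(g)$x <- cx
  igraph::V(g)$y <- cy
  igraph::V(g)$valid <- !border
  igraph::V(g)$analysis <- !border
  if (nrow(ep))
    g <- igraph::add_edges(g, t(matrix(match(ep, labels), ncol = 2)))
  structure(list(graph = g, width = w, height = h,
                 contact_radius = contact_radius_px, ring = 0L),
            class = "contact_graph")
}

#' Construct a contact graph directly from an edge list
#'
#' Mainly for tests and imported networks; all nodes are valid unless stated.
#'
#' @param edges two-column matrix of endpoints (labels or names)
#' @param n_nodes optional node count (isolated nodes included)
#' @param valid logical vector per node (default all `TRUE`)
#' @return a `contact_graph`
#' @export
contact_graph_from_edges <- function(edges, n_nodes = NULL, valid = NULL) {
  edges <- as.matrix(edges)
  ids <- sort(unique(as.vector(edges)))
  if (!is.null(n_nodes)) ids <- union(ids, seq_len(n_nodes))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- as.character(ids)
  igraph::V(g)$x <- NA_real_
  igraph::V(g)$y <- NA_real_
  valid <- valid %||% rep(TRUE, length(ids))
  igraph::V(g)$valid <- valid
  igraph::V(g)$analysis <- valid
  if (nrow(edges))
    g <- igraph::add_edges(g, t(matrix(match(edges, ids), ncol = 2)))
  g <- igraph::simplify(g)
  structure(list(graph = g, width = NA_integer_, height = NA_integer_,
                 contact_radius = NA_real_, ring = 0L),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  g <- x$graph
  cat("contact_graph:", igraph::vcount(g), "cells,", igraph::ecount(g),
      "contacts;", sum(igraph::V(g)$analysis), "analysis cells\n")
  invisible(x)
}

#' Restrict per-cell analysis to cells far from the border
#'
#' Cells within graph distance `ring` of any invalid (border) cell are
#' dropped from the analysis set but kept in the graph, so their edges still
#' shape the orbit counts of retained cells (no truncation bias at the
#' analysis boundary).
#'
#' @param graph a `contact_graph`
#' @param ring non-negative integer; `ring = 0` keeps all valid cells
#' @return the annotated `contact_graph`
#' @export
restrict_to_analysis_nodes <- function(graph, ring = 0) {
  stopifnot(inherits(graph, "contact_graph"), ring >= 0)
  g <- graph$graph
  keep <- igraph::V(g)$valid
  if (ring > 0 && any(!igraph::V(g)$valid)) {
    d <- igraph::distances(g, v = igraph::V(g)[!igraph::V(g)$valid])
    keep <- keep & (apply(d, 2, min) > ring)
  }
  if (!any(keep))
    stop("no analysis cells remain at ring = ", ring)
  igraph::V(g)$analysis <- keep
  graph$graph <- g
  graph$ring <- as.integer(ring)
  graph
}

#' Per-cell degree / polygon class table
#'
#' For interior cells of a packed tissue, contact degree equals the number
#' of polygon sides of the cell's apical surface.
#'
#' @param graph a `contact_graph`
#' @param analysis_only restrict to analysis cells (default `TRUE`)
#' @return data frame with `label`, `degree`, `valid`, `analysis`
#' @export
polygon_classes <- function(graph, analysis_only = TRUE) {
  g <- graph$graph
  df <- data.frame(label = igraph::V(g)$name,
                   degree = igraph::degree(g),
                   valid = igraph::V(g)$valid,
                   analysis = igraph::V(g)$analysis,
                   row.names = NULL)
  if (analysis_only) df <- df[df$analysis, , drop = FALSE]
  df
}
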