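#' Read / write label images
#'
#' Label images travel as single-channel TIFF (16-bit, labels up to 65535)
#' or PNG (8-bit, labels up to 255); pixel values are the integer cell
#' labels (0 = background/membrane).  Round-trips are lossless within those
#' ranges.  Multi-channel (e.g. RGB photograph) input is rejected.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`
#' @return [read_label_image()]: a `label_image`
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (is.matrix(img)) img <- round(img * 255)
  } else stop("unsupported image format: .", ext)
  if (length(dim(img)) != 2)
    stop("format error: expected a single-channel integer label image")
  if (any(img != round(img)) || any(img < 0))
    stop("format error: image does not contain non-negative integer labels")
  label_image(img)
}

#' @rdname read_label_image
#' @param image a `label_image`
#' @export
write_label_image <- function(image, path) {
  img <- unclass(as.matrix(image))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(img) > 65535) stop("labels exceed the 16-bit TIFF range")
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16)
  } else if (ext == "png") {
    if (max(img) > 255)
      stop("labels exceed the 8-bit PNG range; write a 16-bit TIFF instead")
    png::writePNG(img / 255, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Export / import contact graphs
#'
#' GraphML keeps the full attribute set (centroids, validity flags); the CSV
#' exports are an edge list (`source,target`) and a node table
#' (`label,x,y,valid,degree`).
#'
#' @param graph a `contact_graph`
#' @param path output path; format chosen by extension (`.graphml` or `.csv`)
#' @param what for CSV: `"edges"` or `"nodes"`
#' @export
write_contact_graph <- function(graph, path, what = c("edges", "nodes")) {
  stopifnot(inherits(graph, "contact_graph"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    igraph::write_graph(graph$graph, path, format = "graphml")
  } else if (ext == "csv") {
    what <- match.arg(what)
    if (what == "edges") {
      el <- igraph::as_edgelist(graph$graph)
      utils::write.csv(data.frame(source = el[, 1], target = el[, 2]),
                       path, row.names = FALSE)
    } else {
      utils::write.csv(polygon_classes(graph, analysis_only = FALSE)[
        c("label", "degree", "valid", "analysis")], path, row.names = FALSE)
    }
  } else stop("unsupported graph format: .", ext)
  invisible(path)
}

#' @rdname write_contact_graph
#' @export
read_contact_graph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext != "graphml") stop("only GraphML import is supported")
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::V(g)$valid)) igraph::V(g)$valid <- TRUE
  igraph::V(g)$valid <- as.logical(igraph::V(g)$valid)
  if (is.null(igraph::V(g)$analysis)) igraph::V(g)$analysis <- igraph::V(g)$valid
  igraph::V(g)$analysis <- as.logical(igraph::V(g)$analysis)
  structure(list(graph = g, width = NA_integer_, height = NA_integer_,
                 contact_radius = NA_real_, ring = 0L),
            class = "contact_graph")
}

#' Write an orbit-count matrix as CSV
#'
#' Header `label,o0,...`; one row per analysis cell.
#' @param matrix an `orbit_counts` matrix
#' @param path output CSV path
#' @export
write_orbit_counts <- function(matrix, path) {
  df <- data.frame(label = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a CVTn scale
#'
#' JSON round-trip of the scale's point table and generation parameters (the
#' bank is re-recorded by its parameters; `read_cvtn_scale` restores the
#' point cloud and parameters, rebuilding the bank lazily only when needed
#' for embedding new tissues).
#'
#' @param scale a `cvtn_scale`
#' @param path output path: `.json` for the full round-trippable form,
#'   `.csv` for the plain point table
#'   (`iteration,replicate,epi_hexagons,epi_random,epi_voronoi5,n_cells`)
#' @export
write_cvtn_scale <- function(scale, path) {
  stopifnot(inherits(scale, "cvtn_scale"))
  if (tolower(tools::file_ext(path)) == "csv") {
    utils::write.csv(scale$points, path, row.names = FALSE)
    return(invisible(path))
  }
  jsonlite::write_json(list(points = scale$points,
                            schedule = scale$schedule,
                            params = scale$params,
                            bank_params = scale$bank$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cvtn_scale
#' @param rebuild_bank rebuild the reference bank from its recorded
#'   parameters (needed to embed new images; default `FALSE`)
#' @export
read_cvtn_scale <- function(path, rebuild_bank = FALSE) {
  x <- jsonlite::fromJSON(path)
  bank <- if (rebuild_bank) do.call(build_reference_bank, x$bank_params)
          else structure(list(params = x$bank_params), class = "reference_bank")
  structure(list(points = as.data.frame(x$points),
                 schedule = as.integer(x$schedule),
                 params = x$params, bank = bank),
            class = "cvtn_scale")
}
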