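#' Run the full quantification pipeline
#'
#' Orchestrates generate/load -> contact graph -> orbit counts ->
#' Epi-coordinates -> classification from a single config list, writing every
#' intermediate artifact (with provenance metadata) when `out_dir` is set.
#' The config mirrors the individual functions' arguments:
#' \describe{
#'   \item{input}{either `image` (path to a label image) or `tessellation`
#'     (one of `"hexagons"`, `"voronoi"`, `"cvt"`, `"cvtn"`) with its
#'     generator parameters (`n_seeds`, `width`, `height`, `n_rows`,
#'     `n_cols`, `cell_diameter`, `iterations`, `noise_radius`)}
#'   \item{graph}{`contact_radius` (default 2), `ring` (default 0)}
#'   \item{analysis}{`motifs` (default `"motifs-17"`), `threshold_sd`
#'     (default 2.5), `rng_seed`}
#'   \item{scale}{either a prebuilt [build_cvtn_scale()] object / JSON path
#'     (`scale`), or parameters for building one (`schedule`,
#'     `n_replicates`, plus bank parameters under `bank`)}
#' }
#'
#' @param config nested list as above
#' @param out_dir optional output directory for artifacts
#' @return list with `image`, `graph`, `orbits`, `point`, `report`, `config`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- config
  seed <- cfg$rng_seed %||% 1L
  radius <- cfg$contact_radius %||% 2
  ring <- cfg$ring %||% 0L

  image <-
    if (!is.null(cfg$image)) read_label_image(cfg$image)
    else switch(cfg$tessellation %||% stop("config needs 'image' or 'tessellation'"),
      hexagons = make_hexagonal_tessellation(cfg$n_rows %||% 16,
                                             cfg$n_cols %||% 16,
                                             cfg$cell_diameter %||% 14),
      voronoi = make_random_voronoi(cfg$n_seeds %||% 500,
                                    cfg$width %||% 1024,
                                    cfg$height %||% 1024, rng_seed = seed),
      cvt = {
        p <- generate_cvt_path(cfg$n_seeds %||% 500, cfg$width %||% 1024,
                               cfg$height %||% 1024,
                               max_iter = cfg$iterations %||% 5,
                               rng_seed = seed,
                               keep = cfg$iterations %||% 5)
        p[[length(p)]]$image
      },
      cvtn = {
        p <- generate_cvtn_path(cfg$n_seeds %||% 500, cfg$width %||% 1024,
                                cfg$height %||% 1024,
                                schedule = cfg$iterations %||% 4,
                                rng_seed = seed,
                                noise_radius_px = cfg$noise_radius %||% 5)
        p[[length(p)]]$image
      },
      stop("unknown tessellation kind: ", cfg$tessellation))

  graph <- build_contact_graph(image, radius)
  if (ring > 0) graph <- restrict_to_analysis_nodes(graph, ring)
  catalogue <- default_catalogue()
  orbits <- count_orbits(graph, catalogue)
  motifs <- load_motif_set(cfg$motifs %||% "motifs-17", catalogue)

  scale <- cfg[["scale"]]   # exact match: cfg may also carry scale_params
  if (is.character(scale)) scale <- read_cvtn_scale(scale, rebuild_bank = TRUE)
  if (is.null(scale)) {
    bank <- do.call(build_reference_bank,
                    c(cfg[["bank"]] %||% list(), list(catalogue = catalogue)))
    scale <- do.call(build_cvtn_scale,
                     c(list(bank = bank, motifs = motifs),
                       cfg[["scale_params"]] %||% list()))
  }

  point <- epi_point(gdd_profile(orbits), scale$bank, motifs)
  report <- classify_against_scale(point, scale,
                                   threshold_sd = cfg$threshold_sd %||% 2.5)

  res <- list(image = image, graph = graph, orbits = orbits, point = point,
              report = report, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_label_image(image, file.path(out_dir, "tissue.tif"))
    write_contact_graph(graph, file.path(out_dir, "graph.graphml"))
    write_orbit_counts(orbits, file.path(out_dir, "orbits.csv"))
    prov <- list(package = "epigraphr",
                 version = as.character(utils::packageVersion("epigraphr")),
                 config = cfg, config_hash = config_hash(cfg))
    jsonlite::write_json(c(unclass(point), prov),
                         file.path(out_dir, "point.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(c(list(closest_iteration = report$closest_iteration,
                                distance_score = report$distance_score,
                                is_outlier = report$is_outlier,
                                threshold_sd = report$threshold_sd,
                                per_iteration = report$per_iteration), prov),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Write the canonical small fixtures used in tests and documentation
#'
#' Regenerates, bit-identically from packaged seeds: a 5x5 hexagonal
#' lattice, a 128x128 random Voronoi tessellation, a CVTn mini-path
#' (schedule 1..5), and the K3 / P3 / K5 reference graphs, plus an inventory
#' CSV with MD5 checksums.
#'
#' @param out_dir output directory (created if missing)
#' @return invisibly, the inventory data frame
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_label_image(make_hexagonal_tessellation(5, 5, 20),
                    file.path(out_dir, "hexagonal_5x5.tif"))
  write_label_image(make_random_voronoi(20, 128, 128, rng_seed = 7),
                    file.path(out_dir, "voronoi_128.tif"))
  mini <- generate_cvtn_path(20, 128, 128, schedule = 1:5, rng_seed = 11)
  for (d in mini)
    write_label_image(d$image,
                      file.path(out_dir, sprintf("cvtn_mini_iter%02d.tif",
                                                 d$iteration)))
  combos <- list(K3 = t(utils::combn(3, 2)), P3 = cbind(1:2, 2:3),
                 K5 = t(utils::combn(5, 2)))
  for (nm in names(combos))
    write_contact_graph(contact_graph_from_edges(combos[[nm]]),
                        file.path(out_dir, paste0(nm, ".graphml")))
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!grepl("inventory[.]csv$", files)]
  inv <- data.frame(file = basename(files), md5 = unname(tools::md5sum(files)))
  utils::write.csv(inv, file.path(out_dir, "inventory.csv"), row.names = FALSE)
  invisible(inv)
}
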