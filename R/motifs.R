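#' Load a cellular-motif set
#'
#' A motif set restricts the orbit space to graphlets that occur as cellular
#' motifs in planar packed tissues.  Two sets ship with the package:
#' `"full-29"` (29 motifs over 26 distinct graphlets; graphlets G8, G23 and
#' G26 each realize two geometrically distinct motifs) and `"motifs-17"`
#' (the default 17-motif reduced set).  Membership is shipped as data
#' (`inst/extdata/motif_sets.json`); note that the packaged partition is a
#' synthetic transcription built to the published cardinalities, flagged as
#' such in the file, since the original figure-color partition is not
#' machine-readable.  A path to a user JSON file with fields `name` and
#' `graphlets` (list of `{id, multiplicity}`) is also accepted.
#'
#' @param name_or_path `"full-29"`, `"motifs-17"`, or a file path
#' @param catalogue a [build_catalogue()] object
#' @return an object of class `motif_set`: `name`, `graphlet_ids`,
#'   `multiplicity` (named), `n_motifs`, `orbit_ids` (global orbit ids of the
#'   included graphlets)
#' @export
load_motif_set <- function(name_or_path, catalogue = default_catalogue()) {
  builtin <- c("full-29", "motifs-17")
  if (name_or_path %in% builtin) {
    path <- system.file("extdata", "motif_sets.json", package = "epigraphr")
    cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    entry <- NULL
    for (s in cfg$sets) if (s$name == name_or_path) entry <- s
  } else {
    if (!file.exists(name_or_path))
      stop("unknown motif set or missing file: ", name_or_path)
    entry <- tryCatch(jsonlite::fromJSON(name_or_path, simplifyVector = FALSE),
                      error = function(e) stop("malformed motif-set file: ",
                                               conditionMessage(e)))
  }
  if (is.null(entry$name) || is.null(entry$graphlets))
    stop("motif-set definition needs 'name' and 'graphlets' fields")
  ids <- vapply(entry$graphlets, function(g) as.character(g$id), "")
  mult <- vapply(entry$graphlets,
                 function(g) as.integer(g$multiplicity %||% 1L), 0L)
  if (anyDuplicated(ids)) stop("duplicate graphlet ids in motif set")
  names(mult) <- ids
  ms <- structure(list(name = entry$name, graphlet_ids = ids,
                       multiplicity = mult, n_motifs = sum(mult),
                       orbit_ids = orbits_of_graphlets(catalogue, ids)),
                  class = "motif_set")
  # the published cardinalities are enforced on the shipped sets
  if (ms$name == "full-29" &&
      (length(ms$graphlet_ids) != 26L || ms$n_motifs != 29L))
    stop("packaged 'full-29' set fails validation (26 graphlets / 29 motifs)")
  if (ms$name == "motifs-17" && ms$n_motifs != 17L)
    stop("packaged 'motifs-17' set fails validation (17 motifs)")
  ms
}

#' @export
print.motif_set <- function(x, ...) {
  cat("motif_set '", x$name, "': ", x$n_motifs, " motifs, ",
      length(x$graphlet_ids), " graphlets, ", length(x$orbit_ids),
      " orbits\n", sep = "")
  invisible(x)
}

#' Restrict an orbit-count matrix to a motif set
#'
#' Drops orbit columns outside the motif set; row order is preserved and the
#' operation is idempotent.
#'
#' @param matrix an `orbit_counts` matrix with the full 73 columns (or an
#'   already-filtered superset of the target columns)
#' @param motifs a [load_motif_set()] object
#' @return the filtered `orbit_counts` matrix
#' @export
filter_orbits <- function(matrix, motifs) {
  stopifnot(inherits(motifs, "motif_set"))
  want <- paste0("o", motifs$orbit_ids)
  missing <- setdiff(want, colnames(matrix))
  if (length(missing))
    stop("orbit columns absent from matrix: ", paste(missing, collapse = ", "))
  out <- matrix[, want, drop = FALSE]
  attr(out, "motif_set") <- motifs$name
  class(out) <- unique(c("orbit_counts", class(out)))
  out
}
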