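test_that("two abutting rectangles yield a single contact", {
  img <- matrix(1L, 20, 20)
  img[, 11:20] <- 2L
  g <- build_contact_graph(img)
  expect_equal(igraph::ecount(g$graph), 1L)
  expect_equal(sort(igraph::V(g$graph)$name), c("1", "2"))
  # both touch the frame -> no valid cell, but the graph itself is intact
  expect_false(any(igraph::V(g$graph)$valid))
  expect_error(build_contact_graph(matrix(1L, 10, 10)), "at least 2")
})

test_that("a membrane gap within the contact radius still connects", {
  img <- matrix(0L, 20, 21)
  img[, 1:10] <- 1L
  img[, 12:21] <- 2L   # 1-px 0-valued membrane: nearest pixels 2 px apart
  g <- build_contact_graph(img, contact_radius_px = 2)
  expect_equal(igraph::ecount(g$graph), 1L)
  g1 <- build_contact_graph(img, contact_radius_px = 1)
  expect_equal(igraph::ecount(g1$graph), 0L)
})

test_that("ring restriction peels analysis cells from the border inward", {
  g <- build_contact_graph(make_hexagonal_tessellation(5, 5, 20))
  expect_equal(sum(igraph::V(g$graph)$analysis), 9L)      # ring 0
  g1 <- restrict_to_analysis_nodes(g, 1)
  expect_equal(sum(igraph::V(g1$graph)$analysis), 1L)     # central cell only
  expect_error(restrict_to_analysis_nodes(g, 5), "no analysis cells")
  # ring 0 on an all-valid graph keeps every node
  t6 <- torus_triangular_graph(4)
  expect_equal(sum(igraph::V(restrict_to_analysis_nodes(t6, 0)$graph)$analysis),
               16L)
})

test_that("contact relation is symmetric, planar-bounded, degree = sides", {
  img <- make_random_voronoi(120, 256, 256, rng_seed = 11)
  g <- suppressWarnings(build_contact_graph(img))
  expect_false(igraph::any_multiple(g$graph))
  expect_equal(sum(igraph::which_loop(g$graph)), 0L)
  expect_lte(igraph::ecount(g$graph), 3 * igraph::vcount(g$graph) - 6)
  # Euler relation: interior degrees average ~6 and never drop below 3
  pc <- polygon_classes(g)
  expect_lt(abs(mean(pc$degree) - 6), 0.3)
  expect_gte(min(pc$degree), 3)
})

test_that("Voronoi contact graph matches the Delaunay relation of the seeds", {
  skip_if_not(nzchar(Sys.which("python")), "python oracle unavailable")
  set.seed(42)
  pts <- cbind(runif(40, 0, 256), runif(40, 0, 256))
  img <- epigraphr:::rasterize_seeds(seed_set(pts, 256, 256))
  # radius 1: the natural adjacency when there is no membrane gap (larger
  # radii deliberately add contacts across near-degenerate junctions)
  g <- suppressWarnings(build_contact_graph(img, contact_radius_px = 1))
  f <- tempfile(fileext = ".csv")
  utils::write.table(pts, f, row.names = FALSE, col.names = FALSE, sep = ",")
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from scipy.spatial import Delaunay;",
    "p=np.loadtxt('", f, "',delimiter=',');",
    "t=Delaunay(p); e=set();\n",
    "for s in t.simplices:\n",
    "    for i in range(3):\n",
    "        for j in range(i+1,3):\n",
    "            e.add((min(s[i],s[j])+1,max(s[i],s[j])+1))\n",
    "print('\\n'.join(f'{a},{b}' for a,b in sorted(e)))"))),
    stdout = TRUE)
  del <- do.call(rbind, lapply(strsplit(out, ","), as.integer))
  el <- apply(igraph::as_edgelist(g$graph), 2, as.integer)
  valid <- as.integer(igraph::V(g$graph)$name[igraph::V(g$graph)$valid])
  keep_int <- function(e) e[e[, 1] %in% valid & e[, 2] %in% valid, , drop = FALSE]
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  a <- key(keep_int(el)); b <- key(keep_int(del))
  jac <- length(intersect(a, b)) / length(union(a, b))
  expect_gt(jac, 0.96)  # identical up to degenerate junctions and
                        # sub-pixel Voronoi facets
})

test_that("split regions are unioned with a warning", {
  img <- matrix(2L, 15, 15)
  img[3:5, 3:5] <- 1L
  img[10:12, 10:12] <- 1L  # label 1 in two disconnected patches
  expect_warning(g <- build_contact_graph(img), "disconnected")
  expect_equal(igraph::vcount(g$graph), 2L)
})
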