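test_that("hexagonal lattices have the forced honeycomb structure", {
  g <- build_contact_graph(make_hexagonal_tessellation(5, 5, 20))
  pc <- polygon_classes(g)
  expect_equal(nrow(pc), 9L)                 # 3x3 interior cells
  expect_true(all(pc$degree == 6L))
  # 3x3 lattice: only the center cell is interior
  g3 <- build_contact_graph(make_hexagonal_tessellation(3, 3, 20))
  expect_equal(nrow(polygon_classes(g3)), 1L)
  # 6x6 at a different diameter: interior polygon distribution is all hexagons
  g6 <- build_contact_graph(make_hexagonal_tessellation(6, 6, 16))
  expect_equal(unique(polygon_classes(g6)$degree), 6L)
  expect_error(make_hexagonal_tessellation(2, 5, 20), "n_rows")
  expect_error(make_hexagonal_tessellation(5, 5, 3), "cell_diameter")
})

test_that("random Voronoi rasters partition the frame, one region per seed", {
  img <- make_random_voronoi(60, 192, 192, rng_seed = 1)
  expect_equal(sort(unique(as.vector(unclass(img)))), 1:60)  # no 0 pixels
  # determinism: bit-identical under a fixed seed
  img2 <- make_random_voronoi(60, 192, 192, rng_seed = 1)
  expect_identical(unclass(img), unclass(img2))
  # convex cells rasterize into a single connected region each
  img3 <- make_random_voronoi(10, 128, 128, rng_seed = 7)
  comp <- epigraphr:::cpp_region_components(unclass(img3), 10L)
  expect_true(all(comp == 1L))
  expect_error(make_random_voronoi(5, 128, 128), "n_seeds")
})

test_that("interior mean contact number is near 6 (Euler relation)", {
  img <- make_random_voronoi(500, 512, 512, rng_seed = 1)
  pc <- polygon_classes(suppressWarnings(build_contact_graph(img)))
  expect_gt(nrow(pc), 300)
  expect_lt(abs(mean(pc$degree) - 6), 0.15)
})

test_that("Lloyd steps relocate seeds to centroids and never raise CVT energy", {
  # single seed moves to the canvas centroid
  one <- seed_set(cbind(10, 10), 100, 100)
  expect_equal(as.vector(lloyd_step(one)$points), c(49.5, 49.5),
               tolerance = 0.5)
  # a honeycomb seed lattice is (nearly) a fixed point
  d <- 16; v <- d * sqrt(3) / 2
  ij <- expand.grid(col = 0:5, row = 0:5)
  pts <- cbind((ij$col + 0.25 + 0.5 * (ij$row %% 2)) * d, (ij$row + 0.25) * v)
  s <- seed_set(pts, ceiling(max(pts[, 1]) + 0.25 * d),
                ceiling(max(pts[, 2]) + 0.25 * v))
  moved <- sqrt(rowSums((lloyd_step(s)$points - s$points)^2))
  expect_lt(max(moved[c(8:11, 14:17, 20:23, 26:29)]), 1.0)  # interior seeds
  # energy is non-increasing on random configurations
  for (i in 1:15) {
    s <- epigraphr:::random_seed_set(40, 128, 128, rng_seed = 300 + i)
    e0 <- cvt_energy(s)
    s1 <- lloyd_step(s)
    expect_lte(cvt_energy(s1), e0 + 1e-9)
    expect_lte(cvt_energy(lloyd_step(s1)), cvt_energy(s1) + 1e-9)
  }
})

test_that("CVTn steps follow the odd/even noise convention", {
  s <- epigraphr:::random_seed_set(30, 128, 128, rng_seed = 4)
  # odd iteration: identical to plain Lloyd
  expect_equal(cvtn_step(s, 1)$points, lloyd_step(s)$points)
  # even iteration with zero radius degenerates to Lloyd
  expect_equal(cvtn_step(s, 2, noise_radius_px = 0)$points,
               lloyd_step(s)$points)
  # even iteration: every seed within the noise disc of its centroid
  set.seed(99)
  cent <- lloyd_step(s)$points
  noisy <- cvtn_step(s, 2, noise_radius_px = 5)$points
  expect_true(all(sqrt(rowSums((noisy - cent)^2)) <= 5 + 1e-9))
})

test_that("the default iteration schedule matches the published grid", {
  sch <- default_schedule()
  expect_identical(sch, as.integer(c(1:20, seq(30, 100, 10),
                                     seq(200, 700, 100))))
  expect_true(all(diff(sch) > 0))
})

test_that("CVT path relaxes toward order; CVTn paths are reproducible", {
  # iteration-1 entry equals one plain Lloyd relaxation from the same seeds
  p <- generate_cvt_path(30, 128, 128, max_iter = 2, rng_seed = 21)
  s0 <- epigraphr:::random_seed_set(30, 128, 128, rng_seed = 21)
  expect_equal(p[[1]]$seeds$points, lloyd_step(s0)$points)
  # near-convergence: displacement per step shrinks below half a pixel
  pc <- generate_cvt_path(25, 128, 128, max_iter = 60, rng_seed = 3,
                          keep = c(59, 60))
  disp <- sqrt(rowSums((pc[[2]]$seeds$points - pc[[1]]$seeds$points)^2))
  expect_lt(max(disp), 0.5)
  # hexagon enrichment along the path (replicate-averaged)
  hexfrac <- function(img) {
    pc <- polygon_classes(suppressWarnings(build_contact_graph(img)))
    mean(pc$degree == 6)
  }
  f1 <- f8 <- numeric(0)
  for (i in 1:10) {
    pp <- generate_cvt_path(80, 192, 192, max_iter = 8, rng_seed = 400 + i,
                            keep = c(1, 8))
    f1 <- c(f1, hexfrac(pp[[1]]$image))
    f8 <- c(f8, hexfrac(pp[[2]]$image))
  }
  expect_gt(mean(f8), mean(f1))
  # CVTn: deterministic under a fixed seed, schedule respected
  a <- generate_cvtn_path(30, 128, 128, schedule = c(1, 3), rng_seed = 8,
                          n_replicates = 2)
  b <- generate_cvtn_path(30, 128, 128, schedule = c(1, 3), rng_seed = 8,
                          n_replicates = 2)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  expect_equal(vapply(a, `[[`, 0L, "iteration"), c(1L, 3L, 1L, 3L))
  # schedule = {1}: a single plain Lloyd step
  s1 <- generate_cvtn_path(30, 128, 128, schedule = 1, rng_seed = 8)
  expect_equal(s1[[1]]$iteration, 1L)
})

test_that("noise keeps late CVTn diagrams less hexagonal than plain CVT", {
  hexfrac <- function(img) {
    pc <- polygon_classes(suppressWarnings(build_contact_graph(img)))
    mean(pc$degree == 6)
  }
  fc <- fn <- numeric(0)
  for (i in 1:6) {
    cvt <- generate_cvt_path(80, 192, 192, max_iter = 30, rng_seed = 500 + i,
                             keep = 30)
    cvtn <- generate_cvtn_path(80, 192, 192, schedule = 30,
                               rng_seed = 500 + i)
    fc <- c(fc, hexfrac(cvt[[1]]$image))
    fn <- c(fn, hexfrac(cvtn[[1]]$image))
  }
  expect_gt(mean(fc), mean(fn))
})
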