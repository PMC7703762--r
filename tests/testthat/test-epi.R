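test_that("reference bank is reproducible and hexagon profile is point-mass", {
  b1 <- suppressWarnings(build_reference_bank(
    n_seeds = 60, width = 160, height = 160, n_replicates = 3, rng_seed = 5))
  b2 <- suppressWarnings(build_reference_bank(
    n_seeds = 60, width = 160, height = 160, n_replicates = 3, rng_seed = 5))
  expect_identical(b1$hexagons, b2$hexagons)
  expect_identical(b1$random, b2$random)
  expect_identical(b1$voronoi5, b2$voronoi5)
  # an ideal honeycomb interior is vertex-transitive: every touched orbit is
  # a point mass
  for (Nj in b1$hexagons$N)
    if (length(Nj)) expect_equal(unname(sum(Nj == 1)), 1L)
})

test_that("Epi-coordinates live in the unit cube with exact self-identity", {
  bank <- test_bank()
  hexg <- build_contact_graph(make_hexagonal_tessellation(16, 16, 14))
  hexg <- restrict_to_analysis_nodes(hexg, 4)
  p <- suppressWarnings(epi_point(hexg, bank))
  expect_identical(p$epi_hexagons, 0)       # same profile as the reference
  expect_true(all(epi_coords(p) >= 0 & epi_coords(p) <= 1))
  # a fresh random Voronoi tessellation sits near the random reference and
  # far from the hexagon reference
  v <- make_random_voronoi(150, 256, 256, rng_seed = 77)
  pv <- suppressWarnings(epi_point(v, bank))
  expect_lt(pv$epi_random, pv$epi_hexagons)
  expect_true(all(epi_coords(pv) >= 0 & epi_coords(pv) <= 1))
})

test_that("Voronoi-5 reference is intermediate in hexagon content", {
  hexfrac <- function(img) {
    pc <- polygon_classes(suppressWarnings(build_contact_graph(img)))
    mean(pc$degree == 6)
  }
  f1 <- f5 <- f40 <- numeric(0)
  for (i in 1:5) {
    p <- generate_cvt_path(100, 224, 224, max_iter = 40, rng_seed = 600 + i,
                           keep = c(1, 5, 40))
    f1 <- c(f1, hexfrac(p[[1]]$image))
    f5 <- c(f5, hexfrac(p[[2]]$image))
    f40 <- c(f40, hexfrac(p[[3]]$image))
  }
  expect_lt(mean(f1), mean(f5))
  expect_lt(mean(f5), mean(f40))
})

test_that("CVTn scale has the scheduled layout and is deterministic", {
  bank <- test_bank()
  s1 <- suppressWarnings(build_cvtn_scale(bank, schedule = c(1, 3, 5),
                                          n_replicates = 3, rng_seed = 9,
                                          n_seeds = 60, width = 160,
                                          height = 160))
  expect_equal(nrow(s1$points), 9L)          # |schedule| x replicates
  expect_setequal(unique(s1$points$iteration), c(1L, 3L, 5L))
  s2 <- suppressWarnings(build_cvtn_scale(bank, schedule = c(1, 3, 5),
                                          n_replicates = 3, rng_seed = 9,
                                          n_seeds = 60, width = 160,
                                          height = 160))
  expect_identical(s1$points, s2$points)
  co <- as.matrix(s1$points[c("epi_hexagons", "epi_random", "epi_voronoi5")])
  expect_true(all(co >= 0 & co <= 1))
})

test_that("scale serialization round-trips points and parameters", {
  bank <- test_bank()
  s <- suppressWarnings(build_cvtn_scale(bank, schedule = c(1, 2),
                                         n_replicates = 3, rng_seed = 4,
                                         n_seeds = 60, width = 160,
                                         height = 160))
  f <- tempfile(fileext = ".json")
  write_cvtn_scale(s, f)
  s2 <- read_cvtn_scale(f)
  expect_equal(s2$points, s$points)
  expect_equal(s2$schedule, s$schedule)
  expect_equal(s2$params$rng_seed, s$params$rng_seed)
  expect_equal(s2$bank$params$n_seeds, bank$params$n_seeds)
  # CSV table export and the scale plot render without error
  fc <- tempfile(fileext = ".csv")
  write_cvtn_scale(s, fc)
  expect_equal(nrow(utils::read.csv(fc)), nrow(s$points))
  pdf(NULL)
  expect_silent(plot(s, points = suppressWarnings(
    epi_point(make_random_voronoi(60, 160, 160, rng_seed = 1), bank))))
  dev.off()
})
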