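# Shared fixtures, all generated in code under fixed seeds.

# random planar-ish test graphs: contact graphs of small rasterized Voronoi
# tessellations (guaranteed planar up to rasterization artifacts)
random_planar_graph <- function(n_seeds, rng_seed, side = 96) {
  img <- make_random_voronoi(max(10, n_seeds), side, side, rng_seed = rng_seed)
  suppressWarnings(build_contact_graph(img))
}

# sparse random graph (not necessarily planar) as a contact_graph
random_gnm_graph <- function(n, m, rng_seed) {
  set.seed(rng_seed)
  all_pairs <- t(utils::combn(n, 2))
  el <- all_pairs[sample(nrow(all_pairs), min(m, nrow(all_pairs))), , drop = FALSE]
  contact_graph_from_edges(el, n_nodes = n)
}

# 6-regular triangular lattice on a torus: vertex-transitive, every cell
# looks like a honeycomb interior
torus_triangular_graph <- function(k = 6) {
  idx <- function(i, j) ((i %% k) * k + (j %% k)) + 1
  el <- NULL
  for (i in 0:(k - 1)) for (j in 0:(k - 1)) {
    el <- rbind(el,
                c(idx(i, j), idx(i + 1, j)),
                c(idx(i, j), idx(i, j + 1)),
                c(idx(i, j), idx(i + 1, j + 1)))
  }
  contact_graph_from_edges(el, n_nodes = k * k)
}

# chain of three K4 blocks sharing single cut vertices (10 nodes)
k4_chain_graph <- function() {
  blocks <- list(1:4, 4:7, 7:10)
  el <- do.call(rbind, lapply(blocks, function(b) t(utils::combn(b, 2))))
  contact_graph_from_edges(el, n_nodes = 10)
}

# --- shared expensive fixtures (built on first use, then cached) ------------
.fixture_env <- new.env(parent = emptyenv())

test_bank <- function() {
  if (is.null(.fixture_env$bank))
    .fixture_env$bank <- suppressWarnings(build_reference_bank(
      n_seeds = 150, width = 256, height = 256, n_replicates = 10,
      rng_seed = 101))
  .fixture_env$bank
}

# study-size scale shared by the acceptance checks: 500-seed diagrams
# (~420 interior cells, stable orbit statistics), schedule truncated at 100
acc_bank <- function() {
  if (is.null(.fixture_env$acc_bank))
    .fixture_env$acc_bank <- suppressWarnings(build_reference_bank(
      n_seeds = 500, width = 512, height = 512, n_replicates = 10,
      rng_seed = 1))
  .fixture_env$acc_bank
}

acc_scale <- function() {
  if (is.null(.fixture_env$acc_scale))
    .fixture_env$acc_scale <- suppressWarnings(build_cvtn_scale(
      acc_bank(), schedule = c(1:20, seq(30, 100, 10)), n_replicates = 15,
      rng_seed = 2, n_seeds = 500))
  .fixture_env$acc_scale
}
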