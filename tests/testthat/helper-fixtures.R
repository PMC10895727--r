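# Shared fixtures, built in code. The "small" simulation keeps unit and
# property tests fast; the full reference simulation (5 types x 200 cells,
# 3 markers/type, 200 noise genes) is built once per test run and cached.

# Simulation thresholds here are matched to the simulated depth (a few
# hundred genes), not to genome-wide data.
sim_preprocess_config <- function(seed = 1L, min_genes_per_cell = 10L, ...) {
  preprocess_config(min_genes_per_cell = min_genes_per_cell, hvg = FALSE,
                    regress = FALSE, seed = seed, ...)
}

small_sim <- function(seed = 1L, ...) {
  simulate_panel_data(synthetic_spec(n_types = 3L, cells_per_type = 80L,
                                     n_markers_per_type = 2L,
                                     n_noise_genes = 40L, marker_effect = 8,
                                     seed = seed, ...))
}

small_processed <- function(seed = 1L, ...) {
  sim <- small_sim(seed = seed, ...)
  pp <- preprocess_pipeline(sim$counts, sim$labels,
                            sim_preprocess_config(seed = seed))
  list(x = pp$x, labels = pp$labels, truth = sim$truth, log = pp$log)
}

.fixture_cache <- new.env(parent = emptyenv())

reference_processed <- function() {
  if (is.null(.fixture_cache$ref)) {
    sim <- simulate_panel_data(synthetic_spec(seed = 1L))
    pp <- preprocess_pipeline(sim$counts, sim$labels,
                              sim_preprocess_config(seed = 1L,
                                                    min_genes_per_cell = 50L))
    .fixture_cache$ref <- list(x = pp$x, labels = pp$labels,
                               truth = sim$truth)
  }
  .fixture_cache$ref
}

# Brute-force regularizer oracle: scalar loops, written independently of the
# vectorized implementation.
oracle_regularizer <- function(w, d, alpha, beta, gamma, p, pairs,
                               exceed_only = FALSE) {
  spars <- 0
  for (wi in w) spars <- spars + abs(wi) * abs(wi - 1)
  s <- 0
  for (wi in w) s <- s + abs(wi)
  size <- if (exceed_only) alpha * max(s - d, 0) else alpha * abs(s - d)
  prio <- 0
  for (i in seq_along(w)) prio <- prio + p[i] * (1 - min(abs(w[i]), 1))
  prio <- beta * prio
  cx <- 0
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      cx <- cx + abs(abs(w[pairs[r, 1]]) - abs(w[pairs[r, 2]]))
    }
  }
  cx <- gamma * cx
  spars + size + prio + cx
}
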