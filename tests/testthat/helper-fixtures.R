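# Shared in-code fixtures. Simulations are cached per test file so several
# tests can reuse one seeded dataset without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_sim <- function(seed = 1) {
  cached(paste0("default_sim_", seed),
         simulate_counts(simulation_config(seed = seed)))
}

# Small deterministic count matrix: 10 genes x 6 samples, 3 per group.
tiny_cm <- function() {
  set.seed(42)
  counts <- matrix(rnbinom(60, mu = 50, size = 5), nrow = 10,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("s%d", 1:6)))
  count_matrix(counts, rep(c("normal", "cancer"), each = 3))
}

# Module-recovery setting: 5 planted modules of 100 genes at r = 0.6 among
# 1,000 genes, 50 samples in one group.
module_sim <- function(seed) {
  simulate_counts(simulation_config(
    n_genes = 1000, n_normal = 50, n_cancer = 0, seed = seed,
    de_fraction = 0,
    module_spec = replicate(5, module_spec(100, 0.6), simplify = FALSE),
    n_outlier_samples = 0, planted_reversal_drug = FALSE))
}

truth_signature <- function(truth, universe) {
  de <- truth$de_genes
  disease_signature(names(de)[de > 0], names(de)[de < 0], universe)
}
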