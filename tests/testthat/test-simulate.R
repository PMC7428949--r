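test_that("identical config and seed give byte-identical output", {
  cfg <- simulation_config(seed = 7, n_genes = 300, n_normal = 10,
                           n_cancer = 10, module_spec = list(),
                           de_fraction = 0.1, n_outlier_samples = 1,
                           drug_signature_size = 10)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$cm$counts, b$cm$counts)
  expect_identical(a$truth, b$truth)
  la <- simulate_drug_library(cfg, a$truth)
  lb <- simulate_drug_library(cfg, b$truth)
  expect_identical(la$entries, lb$entries)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(de_fraction = 1), "de_fraction")
  expect_error(simulation_config(n_genes = 500), "exceed")
  expect_error(simulation_config(n_genes = 0, module_spec = list(),
                                 de_fraction = 0), "n_genes")
  expect_error(simulation_config(library_size_range = c(2, 1)),
               "library_size_range")
  expect_error(simulation_config(n_outlier_samples = 500),
               "n_outlier_samples")
  expect_error(module_spec(100, 1.2), "r")
})

test_that("with no planted effect the group log-ratio concentrates at 0", {
  cfg <- simulation_config(n_genes = 1000, n_normal = 50, n_cancer = 50,
                           seed = 2, de_fraction = 0, module_spec = list(),
                           n_outlier_samples = 0,
                           library_size_range = c(1, 1),
                           planted_reversal_drug = FALSE)
  sim <- simulate_counts(cfg)
  grp <- sim$cm$groups
  m1 <- rowMeans(log2(sim$cm$counts[, grp == "normal"] + 1))
  m2 <- rowMeans(log2(sim$cm$counts[, grp == "cancer"] + 1))
  expect_lt(mean(abs(m2 - m1)), 0.1)
})

test_that("planted module correlation hits its target in both groups", {
  sim <- default_sim(1)
  expr <- normalized_log2(sim$cm)
  keep <- setdiff(names(sim$cm$groups), sim$truth$outlier_sample_ids)
  mm <- sim$truth$module_membership
  for (g in c("normal", "cancer")) {
    idx <- intersect(keep, names(sim$cm$groups)[sim$cm$groups == g])
    cc <- cor(t(expr[names(mm)[mm == "M1"], idx]))
    expect_gt(mean(cc[upper.tri(cc)]), 0.5)
    expect_lt(mean(cc[upper.tri(cc)]), 0.7)
  }
  ## disrupted module: coexpression collapses in the cancer group only
  gi <- names(mm)[mm %in% sim$truth$disrupted_modules]
  idxN <- intersect(keep, names(sim$cm$groups)[sim$cm$groups == "normal"])
  idxC <- intersect(keep, names(sim$cm$groups)[sim$cm$groups == "cancer"])
  ccN <- cor(t(expr[gi, idxN])); ccC <- cor(t(expr[gi, idxC]))
  expect_gt(mean(ccN[upper.tri(ccN)]), 0.5)
  expect_lt(abs(mean(ccC[upper.tri(ccC)])), 0.1)
})

test_that("per-gene mean/variance follows the planted NB relationship", {
  cfg <- simulation_config(n_genes = 1000, n_normal = 200, n_cancer = 0,
                           seed = 4, de_fraction = 0, module_spec = list(),
                           n_outlier_samples = 0,
                           library_size_range = c(1, 1),
                           planted_reversal_drug = FALSE)
  sim <- simulate_counts(cfg)
  m <- rowMeans(sim$cm$counts)
  v <- apply(sim$cm$counts, 1, var)
  use <- m > 20
  alpha_emp <- (v[use] - m[use]) / m[use]^2
  alpha_true <- sim$truth$true_dispersion[use]
  slope <- sum(alpha_emp * alpha_true) / sum(alpha_true^2)
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("the planted drug reverses the planted disease signature", {
  cfg <- simulation_config(seed = 1)
  sim <- default_sim(1)
  lib <- simulate_drug_library(cfg, sim$truth)
  de <- sim$truth$de_genes
  planted <- lib$entries[[sim$truth$reversal_drug_id]]
  expect_length(planted$down, 50)
  expect_true(all(planted$down %in% names(de)[de > 0]))
  expect_true(all(planted$up %in% names(de)[de < 0]))
  ## without planting, no drug is built from the truth beyond chance
  cfg0 <- simulation_config(seed = 1, planted_reversal_drug = FALSE)
  lib0 <- simulate_drug_library(cfg0, sim$truth)
  expect_false("drug_planted" %in% names(lib0$entries))
  fracs <- vapply(lib0$entries, function(e)
    length(intersect(e$down, names(de)[de > 0])) / length(e$down), 1)
  expect_lt(max(fracs), 0.5)
  ## oversized planted signature is rejected
  cfg_big <- simulation_config(seed = 1, drug_signature_size = 150)
  expect_error(simulate_drug_library(cfg_big, sim$truth),
               "exceeds available")
})

test_that("written simulations are re-readable with truth intact", {
  cfg <- simulation_config(seed = 9, n_genes = 200, n_normal = 6,
                           n_cancer = 6, module_spec = list(),
                           de_fraction = 0.1, n_outlier_samples = 1,
                           n_drug_signatures = 5, drug_signature_size = 5)
  sim <- simulate_counts(cfg)
  lib <- simulate_drug_library(cfg, sim$truth)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, lib, d)
  back <- read_counts(paths[["counts"]], paths[["metadata"]])
  expect_identical(back$counts, sim$cm$counts)
  tr <- utils::read.table(paths[["truth_de"]], header = TRUE, sep = "\t")
  expect_setequal(tr$gene_id, names(sim$truth$de_genes))
})
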