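test_that("connectivity at beta 1 equals row sums of |cor| minus one", {
  set.seed(21)
  expr <- matrix(rnorm(10 * 15), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:15)))
  tab <- pick_soft_threshold(expr, candidate_powers = 1)
  k_direct <- rowSums(abs(cor(t(expr)))) - 1
  expect_equal(tab$mean_connectivity, mean(k_direct), tolerance = 1e-12)
})

test_that("mean connectivity of independent genes decays with beta", {
  set.seed(22)
  expr <- matrix(rnorm(50 * 30), nrow = 50,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:30)))
  tab <- pick_soft_threshold(expr, candidate_powers = c(1, 4, 8, 12))
  expect_true(all(diff(tab$mean_connectivity) < 0))
  expect_lt(tab$mean_connectivity[4], 0.05 * tab$mean_connectivity[1])
})

test_that("scale-free fit improves at the working power on module data", {
  sim <- cached("module_sim_1", module_sim(1))
  expr <- normalized_log2(sim$cm)
  tab <- pick_soft_threshold(expr, candidate_powers = c(1, 6))
  expect_gte(tab$scale_free_R2[tab$power == 6],
             tab$scale_free_R2[tab$power == 1])
})

test_that("TOM analytic cases hold", {
  a0 <- diag(4)
  dimnames(a0) <- list(paste0("g", 1:4), paste0("g", 1:4))
  t0 <- tom_similarity(a0)
  expect_equal(t0, a0)
  a1 <- matrix(1, 4, 4)
  expect_true(all(abs(tom_similarity(a1) - 1) < 1e-12))
})

test_that("TOM rejects invalid adjacencies", {
  a <- random_adjacency(5)
  bad <- a; bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(tom_similarity(bad), "symmetric")
  bad2 <- a; bad2[1, 2] <- bad2[2, 1] <- 1.5
  expect_error(tom_similarity(bad2), "\\[0, 1\\]")
  bad3 <- a; diag(bad3) <- 0.5
  expect_error(tom_similarity(bad3), "diagonal")
})

test_that("TOM equals the triple-loop reference on random matrices", {
  set.seed(23)
  for (i in 1:5) {
    a <- random_adjacency(8)
    expect_equal(tom_similarity(a), tom_oracle(a), tolerance = 1e-12)
  }
})

test_that("module detection recovers planted modules and is order-invariant", {
  sim <- cached("module_sim_1", module_sim(1))
  expr <- normalized_log2(sim$cm)
  ma <- cached("ma_1", detect_modules(expr, group = "normal"))
  truth <- sim$truth$module_membership
  lab <- ma$modules
  non_grey <- names(lab)[lab != "grey"]
  planted <- ifelse(names(lab) %in% names(truth),
                    truth[names(lab)], "background")
  names(planted) <- names(lab)
  expect_gte(mclust::adjustedRandIndex(lab[non_grey], planted[non_grey]),
             0.8)
  ## permuted gene order gives the same partition
  set.seed(24)
  perm <- sample(nrow(expr))
  ma2 <- detect_modules(expr[perm, ], group = "normal")
  common <- names(lab)
  expect_equal(mclust::adjustedRandIndex(lab[common], ma2$modules[common]),
               1)
})

test_that("independent genes are left almost entirely grey", {
  cfg <- simulation_config(n_genes = 500, n_normal = 40, n_cancer = 0,
                           seed = 31, de_fraction = 0, module_spec = list(),
                           n_outlier_samples = 0,
                           planted_reversal_drug = FALSE)
  expr <- normalized_log2(simulate_counts(cfg)$cm)
  ma <- detect_modules(expr, group = "normal")
  expect_gte(mean(ma$modules == "grey"), 0.95)
})

test_that("eigengenes are unit-norm and aligned with module expression", {
  sim <- cached("module_sim_1", module_sim(1))
  expr <- normalized_log2(sim$cm)
  ma <- cached("ma_1", detect_modules(expr, group = "normal"))
  for (m in colnames(ma$eigengenes)) {
    eg <- ma$eigengenes[, m]
    expect_equal(sum(eg^2), 1, tolerance = 1e-8)
    avg <- colMeans(expr[names(ma$modules)[ma$modules == m], ])
    expect_gte(cor(eg, avg), 0)
  }
})

test_that("module overlap table cross-tabulates and flags dissolution", {
  genes <- paste0("g", 1:120)
  lab <- setNames(rep(c("M1", "M2", "grey"), each = 40), genes)
  a <- structure(list(group = "normal", modules = lab, eigengenes = NULL),
                 class = "module_assignment")
  b <- a; b$group <- "cancer"
  tab <- module_overlap_table(a, b)
  self <- tab[tab$module_normal == tab$module_cancer, ]
  expect_true(all(self$n_shared == 40))
  expect_true(all(tab$n_shared[tab$module_normal != tab$module_cancer] == 0))
  ## dissolve M2 into grey in the cancer assignment
  b2 <- b; b2$modules[b2$modules == "M2"] <- "grey"
  tab2 <- module_overlap_table(a, b2)
  row <- tab2[tab2$module_normal == "M2" & tab2$module_cancer == "grey", ]
  expect_equal(row$n_shared, 40)
  expect_lt(row$p_overlap, 1e-6)
  ## disjoint universes are an error
  c2 <- a; names(c2$modules) <- paste0("x", 1:120)
  expect_error(module_overlap_table(a, c2), "no genes")
})

test_that("a disrupted planted module dissolves in the cancer network", {
  sim <- default_sim(1)
  cm <- apply_qc(sim$cm, pca_outliers(sim$cm))
  mods <- list()
  for (g in c("normal", "cancer")) {
    cm_g <- subset_counts(cm, samples = names(cm$groups)[cm$groups == g])
    mods[[g]] <- detect_modules(normalized_log2(cm_g), group = g)
  }
  mm <- sim$truth$module_membership
  gi <- names(mm)[mm %in% sim$truth$disrupted_modules]
  lab_n <- mods$normal$modules[gi]
  lab_c <- mods$cancer$modules[gi]
  ## present as one module in the normal network
  expect_gte(max(table(lab_n[lab_n != "grey"])) / length(gi), 0.8)
  ## majority grey or fragmented in the cancer network
  frac_largest_c <- if (all(lab_c == "grey")) 0 else
    max(table(lab_c[lab_c != "grey"])) / length(gi)
  expect_lt(frac_largest_c, 0.5)
})
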