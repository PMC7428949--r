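test_that("reversal overlap counts only the reversed pairings", {
  dis <- disease_signature(up = c("g1", "g2", "g3"), down = c("g4", "g5"),
                           universe = paste0("g", 1:10))
  ov <- reversal_overlap(dis, drug_up = c("g4", "g6"),
                         drug_down = c("g1", "g7"))
  expect_equal(unname(ov), c(1, 1))
  ## exact identity match
  ov2 <- reversal_overlap(dis, drug_up = c("g4", "g5"),
                          drug_down = c("g1", "g2", "g3"))
  expect_equal(unname(ov2), c(3, 2))
  ## disjoint sets
  ov3 <- reversal_overlap(dis, drug_up = "g8", drug_down = "g9")
  expect_equal(unname(ov3), c(0, 0))
  ## concordant overlap is not counted
  ov4 <- reversal_overlap(dis, drug_up = c("g1", "g2"), drug_down = "g4")
  expect_equal(unname(ov4), c(0, 0))
})

test_that("reversal Fisher p covers degenerate and oracle cases", {
  expect_equal(fisher_reversal_p(0, 100, 50, 1000), 1)
  expect_equal(fisher_reversal_p(10, 10, 10, 10), 1)
  expect_equal(fisher_reversal_p(20, 100, 50, 1000),
               hyper_tail_oracle(20, 50, 100, 1000), tolerance = 1e-12)
  expect_error(fisher_reversal_p(60, 100, 50, 1000), "margin")
  expect_error(fisher_reversal_p(1, 600, 500, 1000), "negative")
})

test_that("p is non-increasing in universe size with counts fixed", {
  ps <- vapply(seq(200, 2000, by = 200), function(U)
    fisher_reversal_p(20, 100, 50, U), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("a planted perfect reverser ranks first and passes filters", {
  u <- paste0("g", 1:2000)
  dis <- disease_signature(u[1:100], u[101:200], u)
  entries <- list(planted = list(up = u[101:200], down = u[1:100]),
                  random = list(up = u[301:350], down = u[401:450]))
  lib <- signature_library(entries)
  rk <- rank_drugs(dis, lib)
  expect_equal(rk$drug_id[1], "planted")
  expect_equal(rk$coverage[1], 1)
  expect_equal(rk$rank[1], 1L)
  expect_true(rk$passes_p[1] && rk$passes_coverage[1])
  expect_true(is.na(rk$rank[rk$drug_id == "random"]))
})

test_that("equal coverage ties break by smaller fisher p", {
  u <- paste0("g", 1:500)
  dis <- disease_signature(u[1:50], u[51:100], u)
  ## both drugs fully reversed (coverage 1) but different signature sizes,
  ## so the larger overlap has the smaller p
  entries <- list(big = list(up = u[51:90], down = u[1:40]),
                  small = list(up = u[51:60], down = u[1:10]))
  lib <- signature_library(entries)
  rk <- rank_drugs(dis, lib, p_max = 0.05, cov_min = 0.5)
  expect_equal(rk$coverage, c(1, 1))
  expect_equal(rk$drug_id, c("big", "small"))
  expect_equal(rk$rank, c(1L, 2L))
})

test_that("random libraries produce no passing drugs", {
  cfg <- simulation_config(seed = 11, planted_reversal_drug = FALSE)
  sim <- default_sim(11)
  lib <- simulate_drug_library(cfg, sim$truth)
  dis <- truth_signature(sim$truth, rownames(sim$cm$counts))
  rk <- rank_drugs(dis, lib)
  expect_equal(sum(rk$passes_coverage), 0)
  expect_true(all(is.na(rk$rank)))
})

test_that("drugs emptied by universe restriction are flagged, not ranked", {
  u <- paste0("g", 1:100)
  dis <- disease_signature(u[1:10], u[11:20], u)
  lib <- signature_library(list(ghost = list(up = "x1", down = "x2"),
                                ok = list(up = u[11:15], down = u[1:5])))
  expect_warning(rk <- rank_drugs(dis, lib, p_max = 0.05, cov_min = 0.5),
                 "ghost")
  expect_true(is.na(rk$coverage[rk$drug_id == "ghost"]))
  expect_true(is.na(rk$rank[rk$drug_id == "ghost"]))
  expect_equal(rk$rank[rk$drug_id == "ok"], 1L)
})

test_that("disease signatures reject malformed sets", {
  u <- paste0("g", 1:10)
  expect_error(disease_signature(c("g1", "g2"), c("g2"), u), "overlap")
  expect_error(disease_signature("g1", "g2", u[3:10]), "outside")
})
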