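test_that("size factors match analytic and brute-force references", {
  counts <- matrix(c(10L, 20L, 40L, 10L, 20L, 40L), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  cm <- count_matrix(counts, c("normal", "cancer"))
  expect_equal(unname(size_factors(cm)), c(1, 1))

  cm2 <- count_matrix(cbind(a = c(10L, 20L, 40L), b = c(20L, 40L, 80L)) |>
                        `rownames<-`(paste0("g", 1:3)),
                      c("normal", "cancer"))
  expect_equal(unname(size_factors(cm2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  cm3 <- tiny_cm()
  sf <- size_factors(cm3)
  geo <- exp(rowMeans(log(cm3$counts)))
  ok <- is.finite(geo) & geo > 0
  ## log-scale median of ratios, recomputed directly
  brute <- apply(cm3$counts, 2,
                 function(x) exp(median(log(x[ok] / geo[ok]))))
  expect_equal(sf, brute, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  cm <- tiny_cm()
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  expect_equal(size_factors(cm), ref, tolerance = 1e-10)
})

test_that("size factors error when no gene is positive everywhere", {
  counts <- matrix(c(0L, 5L, 7L, 0L), 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
  cm <- count_matrix(counts, c("normal", "cancer"))
  expect_error(size_factors(cm), "no gene")
})

test_that("BH adjustment matches its analytic cases and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("genes identical across groups have zero LFC and p of 1", {
  ## every sample carries the same profile, so library sizes are equal and
  ## each gene is exactly balanced between the groups
  profile <- c(12L, 57L, 80L, 150L, 31L, 9L, 400L, 66L)
  counts <- matrix(rep(profile, 6), ncol = 6,
                   dimnames = list(sprintf("g%02d", 1:8),
                                   sprintf("s%d", 1:6)))
  cm <- count_matrix(counts, rep(c("normal", "cancer"), each = 3))
  de <- de_test(cm)
  expect_equal(unname(attr(de, "size_factors")), rep(1, 6))
  expect_equal(de$log2FoldChange, rep(0, 8), tolerance = 1e-8)
  expect_equal(de$pvalue, rep(1, 8), tolerance = 1e-8)
})

test_that("scaling one sample scales its relative size factor, not the LFCs", {
  cm <- tiny_cm()
  de1 <- de_test(cm)
  counts2 <- cm$counts
  counts2[, "s1"] <- counts2[, "s1"] * 3L
  cm2 <- count_matrix(counts2, cm$groups)
  de2 <- de_test(cm2)
  sf1 <- attr(de1, "size_factors"); sf2 <- attr(de2, "size_factors")
  ## factors are not renormalised, so the invariant is on the ratio scale:
  ## s1 grows threefold relative to every other sample
  expect_equal(unname(sf2[["s1"]] / sf2[["s2"]]),
               unname(3 * sf1[["s1"]] / sf1[["s2"]]), tolerance = 1e-10)
  ## LFCs are invariant up to the (small) change the rescaling induces in
  ## the moment-based dispersion estimates
  expect_lt(max(abs(de2$log2FoldChange - de1$log2FoldChange)), 0.02)
})

test_that("DE results are invariant to gene and sample order", {
  cm <- tiny_cm()
  de1 <- de_test(cm)
  set.seed(3)
  gp <- sample(nrow(cm$counts)); sp <- sample(ncol(cm$counts))
  cm2 <- count_matrix(cm$counts[gp, sp], cm$groups[sp])
  de2 <- de_test(cm2)
  de2 <- de2[match(de1$gene_id, de2$gene_id), ]
  expect_equal(de2$pvalue, de1$pvalue, tolerance = 1e-9)
  expect_equal(de2$log2FoldChange, de1$log2FoldChange, tolerance = 1e-9)
})

test_that("de_test requires two samples per group and drops all-zero genes", {
  cm <- tiny_cm()
  expect_error(de_test(subset_counts(cm, samples = c("s1", "s4", "s5"))),
               "at least 2")
  counts <- rbind(cm$counts, gz = rep(0L, 6))
  cmz <- count_matrix(counts, cm$groups)
  expect_false("gz" %in% de_test(cmz)$gene_id)
})

test_that("planted DE genes get the planted fold change back", {
  sim <- default_sim(1)
  cm <- apply_qc(sim$cm, pca_outliers(sim$cm))
  de <- cached("de_default_1", de_test(cm))
  truth <- sim$truth$de_genes
  est <- de$log2FoldChange[match(names(truth), de$gene_id)]
  expect_gt(cor(est, truth), 0.95)
  expect_lt(median(abs(est - truth), na.rm = TRUE), 0.3)
})

test_that("threshold tiers apply their rules and nest", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    baseMean = c(150, 50, 200, 120),
                    log2FoldChange = c(1.5, 1.5, -2, 0.5),
                    lfcSE = 0.1,
                    pvalue = c(1e-5, 1e-5, 1e-6, 0.2),
                    padj = c(5e-4, 5e-4, 1e-5, 0.4))
  th <- de_thresholds()
  strict <- apply_thresholds(res, th, "strict")
  loose <- apply_thresholds(res, th, "loose")
  expect_setequal(strict$up, "a")       # b fails baseMean, d fails padj
  expect_setequal(strict$down, "c")
  expect_true(all(c("a", "b") %in% loose$up))
  expect_true(all(strict$up %in% loose$up))
  expect_true(all(strict$down %in% loose$down))
  expect_error(de_thresholds(padj_max = 1e-4), "strict_padj_max")
})
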