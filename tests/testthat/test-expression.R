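# Normalization, gland combining, variance analysis, correlation network.

toy_counts <- function() {
  matrix(c(10L, 0L, 5L, 7L), 2, 2,
         dimnames = list(c("gA", "gB"), c("ind1_L", "ind1_R")))
}

toy_meta <- function() {
  tibble::tibble(sample_id = c("ind1_L", "ind1_R"),
                 individual = "ind1",
                 gland_side = c("left", "right"))
}

test_that("gland combining sums raw counts per individual", {
  out <- combine_glands(toy_counts(), toy_meta())
  expect_identical(out[, "ind1"], c(gA = 15L, gB = 7L))
})

test_that("single-gland individuals pass through; duplicates error", {
  counts <- toy_counts()[, 1, drop = FALSE]
  meta <- toy_meta()[1, ]
  out <- combine_glands(counts, meta)
  expect_identical(unname(out[, "ind1"]), unname(counts[, 1]))

  meta_dup <- toy_meta()
  meta_dup$gland_side <- c("left", "left")
  expect_error(combine_glands(toy_counts(), meta_dup), "same gland side")
  expect_error(combine_glands(toy_counts(), toy_meta()[1, ]),
               "without metadata")
})

test_that("median-of-ratios factors match the hand-computed example", {
  counts <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- size_factors_median_of_ratios(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  same <- cbind(A = c(5L, 8L), B = c(5L, 8L))
  rownames(same) <- c("g1", "g2")
  expect_equal(unname(size_factors_median_of_ratios(same)), c(1, 1))

  single <- matrix(c(3L, 4L), 2, 1, dimnames = list(c("g1", "g2"), "A"))
  expect_equal(unname(size_factors_median_of_ratios(single)), 1)

  zeros <- matrix(c(0L, 3L, 2L, 0L), 2, 2,
                  dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(size_factors_median_of_ratios(zeros), "positive counts")
})

test_that("size factors agree with the reference library-size estimator", {
  skip_if_not_installed("DESeq2")
  b <- shared_bundle()
  counts <- b$counts_combined
  mine <- size_factors_median_of_ratios(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(mine), unname(ref[names(mine)]), tolerance = 1e-8)
})

test_that("library scaling is recovered up to a common constant", {
  set.seed(31)
  base <- matrix(rpois(400, 60) + 1L, 40, 10)
  rownames(base) <- paste0("g", 1:40)
  scales <- runif(10, 0.5, 2)
  scaled <- round(sweep(base, 2, scales, "*"))
  colnames(scaled) <- paste0("s", 1:10)
  sf <- size_factors_median_of_ratios(scaled)
  ratio <- sf / scales
  # rounding the scaled counts perturbs each factor slightly
  expect_lt(diff(range(ratio)) / mean(ratio), 0.15)
  expect_gt(stats::cor(sf, scales), 0.99)
})

test_that("per-gene variance behaves on closed forms and permutations", {
  norm <- matrix(c(0, 2, 1, 1, 5, 5), 3, 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  attr(norm, "transform") <- "log2p1"
  v <- expression_variance(norm)
  expect_equal(v$variance[v$gene == "g1"], 2)
  expect_equal(v$variance[v$gene == "g2"], 0)
  expect_equal(v$variance[v$gene == "g3"], 0)
  expect_error(expression_variance(norm, samples = "s1"), "2 samples")

  b <- shared_bundle()
  norm_b <- normalize_counts(b$counts_combined)
  v1 <- expression_variance(norm_b)
  v2 <- expression_variance(norm_b[, sample(colnames(norm_b))])
  expect_equal(dplyr::arrange(v1, gene), dplyr::arrange(v2, gene))
  expect_equal(nrow(top_variable_genes(v1, 20)), 20L)
})

test_that("variance group test is a Welch t-test with its symmetries", {
  a <- c(1, 2, 3, 4)
  expect_equal(variance_group_test(a, a)$p_value, 1)
  expect_equal(variance_group_test(a, a)$statistic, 0)

  set.seed(5)
  x <- rnorm(20); y <- rnorm(20) + 50
  res <- variance_group_test(x, y)
  expect_lt(res$p_value, 0.01)
  # independent check through the t CDF
  ref <- stats::t.test(x, y)
  expect_equal(res$p_value,
               unname(2 * stats::pt(abs(ref$statistic), ref$parameter,
                                    lower.tail = FALSE)),
               tolerance = 1e-12)
  swapped <- variance_group_test(y, x)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)
  expect_error(variance_group_test(1, c(1, 2)), "at least 2")
})

test_that("gene-trait significance is |r| with edge cases", {
  norm <- rbind(gX = c(0, 0, 1, 1), gY = c(1, 1, 0, 0),
                gZ = c(2, 2, 2, 2))
  colnames(norm) <- paste0("s", 1:4)
  trait <- c(0, 0, 1, 1)
  gs <- suppressWarnings(gene_trait_significance(norm, trait))
  expect_equal(gs$gene_significance[gs$gene == "gX"], 1)
  expect_equal(gs$gene_significance[gs$gene == "gY"], 1)
  expect_equal(gs$gene_significance[gs$gene == "gZ"], 0)
  expect_warning(gene_trait_significance(norm, trait), "constant")
  expect_error(gene_trait_significance(norm, rep(1, 4)), "both classes")
})

test_that("BH step-up matches hand computation and the stats oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"))
  }
})

test_that("correlation network thresholds and self-correlation behave", {
  b <- shared_bundle()
  norm <- normalize_counts(b$counts_combined)
  res <- tf_venom_correlation(norm, c(b$tf_genes[1], b$venom_genes[1]),
                              b$venom_genes[1:5])
  self <- res[res$tf == b$venom_genes[1] & res$gene == b$venom_genes[1], ]
  expect_equal(self$rho, 1)
  expect_true(self$significant)
  expect_true(all(res$significant == (res$p_value < 0.05 &
                                        res$q_value < 0.1), na.rm = TRUE))
  expect_error(tf_venom_correlation(norm[, 1:2], b$tf_genes[1],
                                    b$venom_genes[1]), "3 samples")
})

test_that("independent-noise correlations stay near the BH bound", {
  set.seed(13)
  fp_counts <- replicate(60, {
    norm <- matrix(rnorm(12 * 30), 30, 12,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
    res <- tf_venom_correlation(norm, paste0("g", 1:10),
                                paste0("g", 11:30))
    sum(res$significant)
  })
  # BH controls FDR at q = 0.1; with all-null pairs the chance of any
  # discovery is at most ~q, so discoveries are rare
  expect_lt(mean(fp_counts > 0), 0.25)
})

test_that("correlation p-values are uniform under independence", {
  set.seed(21)
  p_all <- c()
  for (i in 1:40) {
    norm <- matrix(rnorm(10 * 20), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    res <- tf_venom_correlation(norm, paste0("g", 1:5), paste0("g", 6:20))
    p_all <- c(p_all, res$p_value)
  }
  ks <- suppressWarnings(stats::ks.test(p_all, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("venom genes out-vary their non-venom paralogs in the bundle", {
  b <- shared_bundle()
  norm <- normalize_counts(b$counts_combined)
  v <- expression_variance(norm)
  venom_var <- v$variance[v$gene %in% b$venom_genes]
  nvp_var <- v$variance[v$gene %in% b$nvp_genes]
  res <- variance_group_test(venom_var, nvp_var)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 0.05)
})
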