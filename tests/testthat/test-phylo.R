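# Independent contrasts, feature assembly, per-class PCA, gene regression.

test_that("two-tip contrast matches the closed form", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  cc <- pic_contrasts(tr, c(A = 3, B = 1))
  expect_equal(unname(cc[1, 1]), 2 / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(pic_contrasts(tr, c(A = 5, B = 5))[1, 1]), 0)
})

test_that("contrasts agree with the reference implementation", {
  set.seed(61)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    tr <- ape::rtree(n)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    mine <- sort(pic_contrasts(tr, x)[, 1])
    ref <- sort(unname(ape::pic(x, tr)))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("contrast sum of squares equals the GLS quadratic form", {
  set.seed(62)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    tr <- ape::rtree(n)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    expect_equal(sum(pic_contrasts(tr, x)^2), gls_quadratic_form(tr, x),
                 tolerance = 1e-8)
  }
})

test_that("polytomies are resolved and zero branches regularized", {
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  cc <- pic_contrasts(poly, c(A = 1, B = 2, C = 3))
  expect_equal(nrow(cc), 2L)
  expect_true(all(is.finite(cc)))
  no_len <- ape::read.tree(text = "((A,B),C);")
  expect_error(pic_contrasts(no_len, c(A = 1, B = 2, C = 3)))
})

test_that("standardized contrasts recover the Brownian rate", {
  set.seed(63)
  tr <- simulate_tree(4, 3, seed = 63)
  sigma2 <- 0.7
  vars <- replicate(300, {
    x <- venomreg:::sim_bm(tr, sigma2)
    mean(pic_contrasts(tr, x)^2)
  })
  se <- stats::sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - sigma2), 3 * se)
})

test_that("gene windows pad, clip and reject multi-chromosome arrays", {
  f <- tibble::tibble(chrom = "chr1", start = c(10000L, 15000L),
                      end = c(11000L, 20000L), name = c("a", "b"),
                      element_class = "enhancer", gene = "g")
  w <- build_gene_window(f)
  expect_equal(c(w$start, w$end), c(9000L, 21000L))
  near0 <- build_gene_window(f[1, ] |> dplyr::mutate(start = 500L,
                                                     end = 600L))
  expect_equal(c(near0$start, near0$end), c(0L, 1600L))
  two_chrom <- dplyr::mutate(f, chrom = c("chr1", "chr2"))
  expect_error(build_gene_window(two_chrom), "multiple chromosomes")
})

test_that("top-variance unannotated peaks are selected with tie-breaks", {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(10L, 20L, 30L, 40L, 50L),
                          end = c(15L, 25L, 35L, 45L, 55L),
                          name = paste0("p", 1:5),
                          element_class = c("denovo_peak", "denovo_peak",
                                            "promoter", "denovo_peak",
                                            "denovo_peak"),
                          gene = NA_character_)
  scores <- rbind(p1 = c(0, 1), p2 = c(0, 10), p3 = c(0, 100),
                  p4 = c(0, 10), p5 = c(0, 3))
  colnames(scores) <- c("s1", "s2")
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  sel <- select_denovo_peaks(scores, peaks, w, k = 3)
  # p3 is a promoter and excluded; tie between p2 and p4 resolved by start
  expect_equal(sel, c("p2", "p4", "p5"))
  expect_warning(sel2 <- select_denovo_peaks(scores, peaks, w, k = 5),
                 "eligible")
  expect_length(sel2, 4L)
})

test_that("uncentered PC1 matches an independent eigensolver", {
  set.seed(64)
  for (i in 1:20) {
    block <- matrix(rnorm(11 * sample(2:10, 1)), 11)
    colnames(block) <- paste0("v", seq_len(ncol(block)))
    pc <- class_pca_pc1(block)
    ev <- eigen(crossprod(block))
    ref_load <- ev$vectors[, 1]
    if (ref_load[which.max(abs(ref_load))] < 0) ref_load <- -ref_load
    expect_equal(pc$scores, as.vector(block %*% ref_load),
                 tolerance = 1e-8)
    expect_equal(pc$var_explained, ev$values[1] / sum(ev$values),
                 tolerance = 1e-8)
  }
})

test_that("PC1 edge cases: perfect correlation, symmetry, single column", {
  b <- cbind(v1 = c(1, 2, 3, -1), v2 = c(2, 4, 6, -2))
  expect_equal(class_pca_pc1(b)$var_explained, 1)
  orth <- cbind(v1 = c(1, 0, 0, 0), v2 = c(0, 1, 0, 0))
  expect_equal(class_pca_pc1(orth)$var_explained, 0.5)
  single <- cbind(v1 = c(1, 2, 3))
  expect_equal(class_pca_pc1(single)$scores, c(1, 2, 3))
})

test_that("a response equal to one class is detected with coefficient 1", {
  set.seed(65)
  n <- 20
  preds <- list(cre_accessibility = rnorm(n), tf_expression = rnorm(n),
                cre_genotype = rnorm(n))
  resp <- preds$cre_accessibility + rnorm(n, 0, 1e-4)
  fit <- fit_gene_model(resp, preds, gene = "g")
  row <- fit[fit$class == "cre_accessibility", ]
  expect_lt(row$p_value, 1e-6)
  expect_equal(row$coefficient, 1, tolerance = 1e-2)
  expect_true(row$significant)
  g <- glance(fit)
  expect_gt(g$r_squared, 0.99)
})

test_that("collinear classes are dropped deterministically, later first", {
  set.seed(66)
  x <- rnorm(12)
  preds <- list(cre_accessibility = x, tf_expression = 2 * x,
                cre_genotype = rnorm(12))
  fit <- fit_gene_model(rnorm(12), preds, gene = "g")
  expect_equal(fit$status[fit$class == "tf_expression"],
               "dropped_collinear")
  expect_equal(fit$status[fit$class == "cre_accessibility"], "fit")
})

test_that("too few contrasts for the parameter count errors", {
  preds <- replicate(6, rnorm(5), simplify = FALSE)
  names(preds) <- venomreg:::FEATURE_CLASSES
  expect_error(fit_gene_model(rnorm(5), preds), "more contrasts")
})

test_that("full per-gene modeling is invariant to sample permutation", {
  b <- shared_bundle()
  expr <- normalize_counts(b$counts_combined, transform = "log2p1")
  occ <- shared_occupancy()
  base <- model_gene("SVMP3", b$tree, expr, b$peaks, b$peak_scores, occ,
                     b$tfbs, b$variants, b$tf_genes)
  perm <- sample(colnames(expr))
  perm_fit <- model_gene("SVMP3", b$tree, expr[, perm],
                         b$peaks, b$peak_scores[, perm],
                         structure(list(bound = occ$bound[, perm],
                                        scores = occ$scores[, perm],
                                        thresholds = occ$thresholds[perm]),
                                   class = "venomreg_occupancy"),
                         b$tfbs, b$variants, b$tf_genes)
  expect_equal(tibble::as_tibble(base), tibble::as_tibble(perm_fit),
               tolerance = 1e-9)
})

test_that("strict PCA mode keeps small classes unreduced", {
  b <- shared_bundle()
  tree <- b$tree
  tips <- tree$tip.label
  set.seed(91)
  expr <- rbind(gX = rnorm(12, 100, 10), TFa = rnorm(12, 50, 5),
                TFb = rnorm(12, 50, 5))
  colnames(expr) <- tips
  peaks <- tibble::tibble(
    chrom = "chrT", start = c(100L, 400L, 700L, 900L),
    end = c(200L, 500L, 800L, 1000L),
    name = c("gX_prom", "gX_enh", "gX_ctcf", "gX_peak"),
    element_class = c("promoter", "enhancer", "ctcf", "denovo_peak"),
    gene = c("gX", "gX", NA, NA))
  peak_scores <- matrix(rnorm(4 * 12, 20, 4), 4, 12,
                        dimnames = list(peaks$name, tips))
  tfbs <- tibble::tibble(chrom = "chrT", start = c(120L, 150L),
                         end = c(126L, 156L), name = c("site1", "site2"),
                         tf_name = "TFa", element = "gX_prom", gene = "gX")
  bound <- matrix(rbinom(24, 1, 0.5), 2, 12,
                  dimnames = list(tfbs$name, tips))
  occ <- structure(list(bound = bound, scores = bound,
                        thresholds = stats::setNames(rep(0.5, 12), tips)),
                   class = "venomreg_occupancy")
  gts <- stats::setNames(rep("hom_ref", 12), tips)
  gts[1:4] <- "het"
  variants <- tibble::as_tibble(c(list(chrom = "chrT", pos = 130L,
                                       ref = "A", alt = "T"),
                                  as.list(gts)))
  fit <- model_gene("gX", tree, expr, peaks, peak_scores, occ, tfbs,
                    variants, c("TFa", "TFb"), pca_mode = "n_rule")
  # every class has at most n-sample variables: nothing is reduced to PC1,
  # multi-variable classes appear as their individual columns
  expect_false("cre_accessibility" %in% fit$class)
  expect_true(any(grepl("^cre_accessibility\\.\\.", fit$class)))
  expect_true(any(grepl("^tf_expression\\.\\.", fit$class)))
  # and the default mode reduces the same inputs to one row per class
  fit_pc1 <- model_gene("gX", tree, expr, peaks, peak_scores, occ, tfbs,
                        variants, c("TFa", "TFb"))
  expect_setequal(
    fit_pc1$class[fit_pc1$status == "fit"],
    c("cre_accessibility", "ctcf_accessibility", "denovo_accessibility",
      "tf_footprints", "tf_expression", "cre_genotype"))
})

test_that("genes without context are excluded with a reason", {
  b <- shared_bundle()
  expr <- normalize_counts(b$counts_combined, transform = "log2p1")
  occ <- shared_occupancy()
  res <- run_model_matrix(c("SVMP3", "bg1", "ghost"), b$tree, expr,
                          b$peaks, b$peak_scores, occ, b$tfbs, b$variants,
                          b$tf_genes)
  expect_setequal(unique(res$gene), "SVMP3")
  excl <- attr(res, "excluded")
  expect_setequal(excl$gene, c("bg1", "ghost"))
  expect_match(excl$reason[excl$gene == "bg1"], "CRE")
  empty <- run_model_matrix(character(0), b$tree, expr, b$peaks,
                            b$peak_scores, occ, b$tfbs, b$variants,
                            b$tf_genes)
  expect_equal(nrow(empty), 0L)
})

test_that("planted drivers couple at tip level; null genes stay calibrated", {
  b <- shared_bundle()
  expr <- normalize_counts(b$counts_combined, transform = "log2p1")
  occ <- shared_occupancy()
  planted <- b$truth$planted_effects$gene
  tips <- b$tree$tip.label
  # the planted enhancer score is the gene's expression driver: strong
  # correlation at the tip level, absent for matched null genes
  cor_of <- function(g) {
    enh <- paste0(g, "_enh")
    abs(stats::cor(expr[g, tips], b$peak_scores[enh, tips]))
  }
  null_genes <- setdiff(
    unique(stats::na.omit(
      b$peaks$gene[b$peaks$element_class == "enhancer"])), planted)
  planted_cor <- vapply(planted, cor_of, numeric(1))
  null_cor <- vapply(null_genes, cor_of, numeric(1))
  expect_gt(min(planted_cor), 0.6)
  # null genes correlate with their enhancer only through shared
  # phylogeny; the planted coupling clearly exceeds that baseline
  expect_gt(mean(planted_cor) - mean(null_cor), 0.2)
  # after contrast standardization the per-gene regression stays
  # calibrated on the null genes (per-gene power at 12 tips is limited;
  # see the methods vignette)
  res <- run_model_matrix(null_genes, b$tree, expr, b$peaks,
                          b$peak_scores, occ, b$tfbs, b$variants,
                          b$tf_genes)
  cre <- res[res$class == "cre_accessibility" & res$status == "fit", ]
  expect_lte(sum(cre$p_value < 0.05),
             qbinom(0.995, nrow(cre), 0.05) + 1L)
})
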