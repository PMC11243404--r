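# Expression normalization, gland combining, variance analysis and the
# significance-filtered TF-to-venom-gene correlation network.

#' Combine left and right venom-gland counts per individual
#'
#' Venom is expressed from paired glands; replicate libraries from the two
#' glands of one individual are summed on the raw count scale before
#' normalization (counts are additive; normalization then absorbs depth).
#' Individuals represented by a single gland pass through unchanged.
#'
#' @param counts Integer matrix, genes x samples.
#' @param meta Sample metadata tibble with columns sample_id, individual,
#'   gland_side (one of left/right/combined/NA).
#' @return Integer matrix, genes x individuals (column names are individual
#'   ids).
#' @export
combine_glands <- function(counts, meta) {
  meta <- meta[meta$sample_id %in% colnames(counts), , drop = FALSE]
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing)) {
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  split_ids <- split(meta$sample_id, meta$individual)
  sides <- split(meta$gland_side, meta$individual)
  for (ind in names(sides)) {
    s <- sides[[ind]][!is.na(sides[[ind]])]
    if (anyDuplicated(s[s %in% c("left", "right")])) {
      stop("individual '", ind, "' has two samples of the same gland side")
    }
  }
  out <- vapply(split_ids, function(ids) {
    as.integer(rowSums(counts[, ids, drop = FALSE]))
  }, integer(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Median-of-ratios size factors
#'
#' For counts k (genes i, samples j) the size factor of sample j is
#' s_j = median_i k_ij / g_i, where g_i = (prod_j k_ij)^(1/m) is the
#' geometric mean across the m samples, taken over genes with positive
#' counts in every sample. This is the classical library-size estimator for
#' count matrices; normalized values are k_ij / s_j.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  if (ncol(counts) == 1L) {
    return(stats::setNames(1, colnames(counts)))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; ",
         "consider a pseudo-reference fallback")
  }
  logk <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logk)
  sf <- apply(logk, 2L, function(col) exp(stats::median(col - ref)))
  stats::setNames(sf, colnames(counts))
}

#' Normalize a counts matrix
#'
#' Divides each sample by its median-of-ratios size factor; optionally
#' applies the variance-stabilizing proxy log2(normalized + 1).
#'
#' @param counts Integer matrix, genes x samples.
#' @param transform `"none"` for normalized counts, `"log2p1"` for
#'   log2(normalized + 1).
#' @param size_factors Optional precomputed size factors.
#' @return Numeric matrix of the same shape, with attributes `size_factors`
#'   and `transform`.
#' @export
normalize_counts <- function(counts, transform = c("log2p1", "none"),
                             size_factors = NULL) {
  transform <- match.arg(transform)
  if (is.null(size_factors)) {
    size_factors <- size_factors_median_of_ratios(counts)
  }
  if (any(size_factors <= 0)) stop("size factors must be positive")
  norm <- sweep(counts, 2L, size_factors, "/")
  if (transform == "log2p1") norm <- log2(norm + 1)
  attr(norm, "size_factors") <- size_factors
  attr(norm, "transform") <- transform
  norm
}

#' Per-gene expression variance
#'
#' Unbiased sample variance of each gene over a sample subset, on the
#' transformed (log2) scale.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param samples Optional character vector restricting the samples
#'   (e.g. one species); default all.
#' @return Tibble with columns gene, variance, ranked high to low.
#' @export
expression_variance <- function(norm, samples = NULL) {
  if (is.null(samples)) samples <- colnames(norm)
  if (length(samples) < 2L) stop("need at least 2 samples for a variance")
  sub <- norm[, samples, drop = FALSE]
  v <- apply(sub, 1L, stats::var)
  tibble::tibble(gene = rownames(sub), variance = unname(v)) |>
    dplyr::arrange(dplyr::desc(.data$variance))
}

#' Top-k most variable genes
#' @param variance_table Output of [expression_variance()].
#' @param k Number of genes.
#' @return Tibble of the k highest-variance genes.
#' @export
top_variable_genes <- function(variance_table, k) {
  dplyr::slice_max(variance_table, .data$variance, n = k, with_ties = FALSE)
}

#' Two-sample t-test on per-gene variances
#'
#' Compares expression-variance distributions between two gene groups (e.g.
#' venom genes vs their non-venom paralogs). Welch's unequal-variance test by
#' default; a pooled-variance test is available.
#'
#' @param variances_a,variances_b Numeric vectors of per-gene variances.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return Tibble with statistic, p_value, df, mean_a, mean_b.
#' @export
variance_group_test <- function(variances_a, variances_b, var_equal = FALSE) {
  if (length(variances_a) < 2L || length(variances_b) < 2L) {
    stop("both groups need at least 2 values")
  }
  if (stats::var(variances_a) == 0 && stats::var(variances_b) == 0) {
    if (mean(variances_a) == mean(variances_b)) {
      return(tibble::tibble(statistic = 0, p_value = 1, df = NA_real_,
                            mean_a = mean(variances_a),
                            mean_b = mean(variances_b)))
    }
    warning("zero within-group variance in both groups; p undefined")
    return(tibble::tibble(statistic = NaN, p_value = NaN, df = NA_real_,
                          mean_a = mean(variances_a),
                          mean_b = mean(variances_b)))
  }
  tt <- stats::t.test(variances_a, variances_b, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter),
                 mean_a = mean(variances_a), mean_b = mean(variances_b))
}

#' Gene-trait significance
#'
#' Absolute Pearson correlation between each gene's expression and a binary
#' per-sample trait (e.g. lineage membership), the per-gene significance
#' measure used to screen candidate regulators.
#'
#' @param norm Normalized matrix, genes x samples.
#' @param trait 0/1 vector, one value per sample (in column order).
#' @return Tibble with columns gene, gene_significance (= |r|).
#' @export
gene_trait_significance <- function(norm, trait) {
  if (length(trait) != ncol(norm)) stop("trait length must match samples")
  if (length(unique(trait)) < 2L) stop("trait must have both classes present")
  gs <- apply(norm, 1L, function(x) {
    if (stats::sd(x) == 0) {
      warning("constant gene; significance set to 0")
      return(0)
    }
    abs(stats::cor(x, trait))
  })
  tibble::tibble(gene = rownames(norm), gene_significance = unname(gs))
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' Classical step-up procedure: for ordered p-values p_(1) <= ... <= p_(m),
#' q_(i) = min_{k >= i} ( m * p_(k) / k ), capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  scaled <- m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Significance-filtered TF-to-venom-gene correlation network
#'
#' Pearson correlation between each candidate transcription factor and each
#' venom gene across samples; p-values from the exact t transform
#' t = r * sqrt((n-2) / (1-r^2)) with n-2 degrees of freedom, adjusted
#' jointly across all pairs by Benjamini-Hochberg. A pair is significant when
#' p < `p_thresh` and q < `q_thresh`.
#'
#' @param norm Normalized matrix, genes x samples.
#' @param tf_genes,venom_genes Row names selecting the two gene sets.
#' @param p_thresh,q_thresh Significance thresholds (defaults 0.05 and 0.1).
#' @return A tibble of class `venomreg_cor` with one row per TF-gene pair:
#'   tf, gene, rho, p_value, q_value, significant.
#' @export
tf_venom_correlation <- function(norm, tf_genes, venom_genes,
                                 p_thresh = 0.05, q_thresh = 0.1) {
  n <- ncol(norm)
  if (n < 3L) stop("need at least 3 samples for correlation p-values")
  missing <- setdiff(c(tf_genes, venom_genes), rownames(norm))
  if (length(missing)) stop("genes not in matrix: ",
                            paste(missing, collapse = ", "))
  tf_mat <- t(norm[tf_genes, , drop = FALSE])
  vg_mat <- t(norm[venom_genes, , drop = FALSE])
  rho <- suppressWarnings(stats::cor(tf_mat, vg_mat))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  p[is.na(rho)] <- NA_real_
  out <- tibble::tibble(
    tf = rep(tf_genes, times = length(venom_genes)),
    gene = rep(venom_genes, each = length(tf_genes)),
    rho = as.vector(rho),
    p_value = as.vector(p))
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[ok] <- benjamini_hochberg(out$p_value[ok])
  out$significant <- !is.na(out$p_value) &
    out$p_value < p_thresh & out$q_value < q_thresh
  class(out) <- c("venomreg_cor", class(out))
  attr(out, "n_samples") <- n
  attr(out, "thresholds") <- c(p = p_thresh, q = q_thresh)
  out
}

#' @export
glance.venomreg_cor <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 n_samples = attr(x, "n_samples"),
                 p_threshold = attr(x, "thresholds")[["p"]],
                 q_threshold = attr(x, "thresholds")[["q"]])
}

#' Heatmap of the significance-filtered correlation matrix
#'
#' Non-significant pairs are left blank, mirroring the convention of showing
#' only correlations passing both thresholds.
#'
#' @param object A `venomreg_cor` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venomreg_cor <- function(object, ...) {
  df <- dplyr::mutate(object,
                      rho_shown = ifelse(.data$significant, .data$rho, NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$tf,
                                   fill = .data$rho_shown)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey95",
                                  name = "Pearson's rho") +
    ggplot2::labs(x = "venom gene", y = "transcription factor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
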