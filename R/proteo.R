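# Compositional (CLR) coupling of venom-gland mRNA abundance and venom
# protein abundance.

#' Centered log-ratio transform
#'
#' clr_i = ln(x_i) - mean(ln(x)). The result sums to zero and is invariant
#' to rescaling of the whole composition.
#'
#' @param x Positive numeric vector (one composition).
#' @return Numeric vector of the same length, summing to zero.
#' @export
clr_transform <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("clr requires strictly positive finite entries")
  }
  lx <- log(x)
  lx - mean(lx)
}

#' Pair mRNA and protein abundances for CLR regression
#'
#' Builds the matched per-individual compositions used to quantify
#' transcriptome-proteome coupling. Zeros are handled by adding half of the
#' smallest positive value of each matrix before the transform; the CLR is
#' applied per sample (column) across the shared venom genes.
#'
#' @param mrna Numeric matrix of mRNA abundance (genes x samples), e.g.
#'   normalized counts on the count scale.
#' @param protein Numeric matrix of protein abundance (genes x samples).
#' @return A list of class `venomreg_paired` with clr_mrna, clr_protein
#'   (genes x samples) and the gene/sample labels used.
#' @export
pair_abundances <- function(mrna, protein) {
  genes <- intersect(rownames(mrna), rownames(protein))
  samples <- intersect(colnames(mrna), colnames(protein))
  if (length(genes) < 2L) stop("need at least 2 shared genes for CLR")
  if (length(samples) < 1L) stop("no shared samples")
  m <- mrna[genes, samples, drop = FALSE]
  p <- protein[genes, samples, drop = FALSE]
  offset <- function(x) {
    if (any(x <= 0)) x + min(x[x > 0]) / 2 else x
  }
  m <- offset(m); p <- offset(p)
  structure(list(genes = genes, samples = samples,
                 clr_mrna = apply(m, 2L, clr_transform),
                 clr_protein = apply(p, 2L, clr_transform)),
            class = "venomreg_paired")
}

#' mRNA-protein coupling fit
#'
#' Ordinary least squares of CLR protein abundance on CLR mRNA abundance,
#' pooled over all gene x sample points (one scatter across individuals);
#' per-sample fits are available with `per_sample = TRUE`. R^2 is the squared
#' Pearson correlation of the pooled points.
#'
#' @param paired A `venomreg_paired` object from [pair_abundances()].
#' @param per_sample Also return one fit per individual.
#' @return A list of class `venomreg_fit` with elements `model` (the pooled
#'   `lm`), `points` (tibble gene, sample, clr_mrna, clr_protein) and
#'   optionally `per_sample` (tibble of per-individual slopes and R^2).
#' @export
mrna_protein_fit <- function(paired, per_sample = FALSE) {
  pts <- tibble::tibble(
    gene = rep(paired$genes, times = length(paired$samples)),
    sample = rep(paired$samples, each = length(paired$genes)),
    clr_mrna = as.vector(paired$clr_mrna),
    clr_protein = as.vector(paired$clr_protein))
  if (nrow(pts) < 3L) stop("need at least 3 points for a fit")
  if (stats::sd(pts$clr_mrna) == 0) stop("constant predictor; fit undefined")
  fit <- stats::lm(clr_protein ~ clr_mrna, data = pts)
  out <- list(model = fit, points = pts)
  if (per_sample) {
    out$per_sample <- pts |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(
        slope = stats::coef(stats::lm(clr_protein ~ clr_mrna))[2],
        r_squared = stats::cor(.data$clr_protein, .data$clr_mrna)^2,
        .groups = "drop")
  }
  class(out) <- "venomreg_fit"
  out
}

#' @exportS3Method base::print
print.venomreg_fit <- function(x, ...) {
  g <- glance(x)
  cat("mRNA-protein CLR coupling: slope ", signif(g$slope, 4),
      ", R^2 ", signif(g$r_squared, 4), " over ", g$n_points,
      " gene x sample points\n", sep = "")
  invisible(x)
}

#' @export
tidy.venomreg_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.venomreg_fit <- function(x, ...) {
  tibble::tibble(
    slope = unname(stats::coef(x$model)[2]),
    intercept = unname(stats::coef(x$model)[1]),
    r_squared = summary(x$model)$r.squared,
    n_points = nrow(x$points))
}

#' Scatter of CLR protein vs CLR mRNA with the pooled fit line
#' @param object A `venomreg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venomreg_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$clr_mrna, y = .data$clr_protein)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept,
                         color = "#B2182B") +
    ggplot2::labs(x = "clr(mRNA abundance)", y = "clr(protein abundance)",
                  subtitle = sprintf("R² = %.2f", g$r_squared)) +
    ggplot2::theme_minimal()
}
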