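# Phylogenetically independent contrasts, per-class PCA reduction, and the
# per-gene regulatory-correlate regression.

FEATURE_CLASSES <- c("cre_accessibility", "ctcf_accessibility",
                     "denovo_accessibility", "tf_footprints",
                     "tf_expression", "cre_genotype")

#' Resolve a tree to binary with strictly positive branch lengths
#'
#' Polytomies are resolved deterministically to a binary topology; any
#' zero-length branch so created (or already present) is raised to
#' `epsilon_frac` times the tree height. Contrasts require a binary tree
#' with positive lengths.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param epsilon_frac Fraction of tree height used for the minimal branch
#'   length.
#' @return A binary `ape::phylo` tree.
#' @export
resolve_tree <- function(tree, epsilon_frac = 1e-6) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  height <- max(ape::node.depth.edgelength(tree))
  if (height <= 0) stop("tree height is zero; all branch lengths vanish")
  eps <- epsilon_frac * height
  tree$edge.length[tree$edge.length <= 0] <- eps
  tree
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node whose two child
#' values are x_i, x_j with adjusted branch lengths v_i, v_j, the contrast
#' is (x_i - x_j) / sqrt(v_i + v_j); the node is assigned the
#' precision-weighted value (x_i/v_i + x_j/v_j) / (1/v_i + 1/v_j) and its
#' parent branch is lengthened by v_i v_j / (v_i + v_j). Contrasts are
#' emitted in post-order, one per internal node, and are i.i.d. with
#' variance sigma^2 under Brownian motion with rate sigma^2.
#'
#' Traits may be a vector or a matrix (one column per trait); all columns
#' are pruned in one pass.
#'
#' @param tree An `ape::phylo` tree; polytomies are resolved via
#'   [resolve_tree()].
#' @param traits Named numeric vector (names = tip labels) or a matrix with
#'   tip labels as rownames.
#' @param epsilon_frac Passed to [resolve_tree()].
#' @return A matrix with `n_tips - 1` rows (post-order internal nodes) and
#'   one column per trait; a vector input returns a 1-column matrix.
#' @export
pic_contrasts <- function(tree, traits, epsilon_frac = 1e-6) {
  if (is.vector(traits)) {
    traits <- matrix(traits, ncol = 1L,
                     dimnames = list(names(traits), "trait"))
  }
  tree <- resolve_tree(tree, epsilon_frac)
  if (is.null(rownames(traits)) ||
      !all(tree$tip.label %in% rownames(traits))) {
    stop("every tip needs a trait value (rownames must cover tip labels)")
  }
  traits <- traits[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  n_node <- tree$Nnode
  p <- ncol(traits)
  values <- matrix(NA_real_, n + n_node, p)
  values[seq_len(n), ] <- traits
  v_above <- numeric(n + n_node)          # adjusted length of edge above node
  v_above[tree$edge[, 2]] <- tree$edge.length
  extra <- numeric(n + n_node)
  contrasts <- matrix(NA_real_, n - 1L, p)
  colnames(contrasts) <- colnames(traits)
  parents <- unique(tree$edge[, 1])       # postorder
  children <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = parents))
  for (k in seq_along(parents)) {
    ch <- children[[k]]
    if (length(ch) != 2L) stop("tree must be binary for contrasts")
    i <- ch[1]; j <- ch[2]
    vi <- v_above[i] + extra[i]
    vj <- v_above[j] + extra[j]
    if (vi + vj <= 0) {
      stop("zero-length cherry at node ", parents[k],
           "; raise epsilon_frac to regularize branch lengths")
    }
    contrasts[k, ] <- (values[i, ] - values[j, ]) / sqrt(vi + vj)
    values[parents[k], ] <- (values[i, ] / vi + values[j, ] / vj) /
      (1 / vi + 1 / vj)
    extra[parents[k]] <- vi * vj / (vi + vj)
  }
  contrasts
}

#' Window spanning a venom gene array
#'
#' The furthest-separated features of the array (known CREs and, when
#' supplied, the coding span), extended by `pad` bases on each side and
#' clipped at zero.
#'
#' @param features Interval tibble of the array's features (one chromosome).
#' @param pad Extension in bases (default 1000).
#' @return A one-row interval tibble.
#' @export
build_gene_window <- function(features, pad = 1000L) {
  if (nrow(features) == 0L) stop("no features for window construction")
  if (length(unique(features$chrom)) != 1L) {
    stop("features span multiple chromosomes: ",
         paste(unique(features$chrom), collapse = ", "))
  }
  tibble::tibble(chrom = features$chrom[1],
                 start = max(0L, min(features$start) - as.integer(pad)),
                 end = max(features$end) + as.integer(pad),
                 name = paste0(features$chrom[1], "_window"),
                 element_class = "other", gene = NA_character_)
}

#' Select the most variable unannotated peaks in a window
#'
#' Among accessibility peaks overlapping the window that are not annotated
#' CREs or CTCF sites, returns the `k` with the highest cross-sample score
#' variance. Ties are broken by lower genomic start coordinate.
#'
#' @param peak_scores Numeric matrix, peaks x samples (rownames = peak
#'   names).
#' @param peaks Interval tibble describing the rows of `peak_scores`.
#' @param window One-row interval tibble.
#' @param k Number of peaks to keep (default 3).
#' @return Character vector of selected peak names (possibly fewer than `k`,
#'   with a warning).
#' @export
select_denovo_peaks <- function(peak_scores, peaks, window, k = 3L) {
  eligible <- peaks$chrom == window$chrom[1] &
    peaks$start < window$end[1] & peaks$end > window$start[1] &
    !peaks$element_class %in% c("promoter", "enhancer", "ctcf")
  cand <- peaks[eligible, , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  v <- apply(peak_scores[cand$name, , drop = FALSE], 1L, stats::var)
  ord <- order(-v, cand$start)
  sel <- cand$name[ord][seq_len(min(k, nrow(cand)))]
  if (length(sel) < k) {
    warning("only ", length(sel), " eligible unannotated peak(s) in window")
  }
  sel
}

# Mode of a genotype-dose vector, ties toward the smaller dose.
impute_mode <- function(x) {
  tab <- table(factor(x[!is.na(x)], levels = 0:2))
  as.integer(names(tab)[which.max(tab)])
}

genotype_dose <- function(variants, samples) {
  code <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = NA_integer_)
  if (nrow(variants) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = length(samples),
                  dimnames = list(NULL, samples)))
  }
  m <- vapply(samples, function(s) code[unlist(variants[[s]])],
              integer(nrow(variants)))
  m <- matrix(m, nrow = nrow(variants), dimnames = list(
    paste0(variants$chrom, ":", variants$pos, "_", variants$ref, ">",
           variants$alt), samples))
  m
}

#' Assemble the per-gene regulatory feature table
#'
#' One row per sample: the response (normalized expression of the gene) and
#' six ordered predictor classes — accessibility at the gene's promoters and
#' enhancers, accessibility at CTCF peaks inside the array window,
#' accessibility at the top unannotated peaks in the window, binarized TF
#' footprints at the gene's CREs, normalized expression of the
#' venom-regulating TFs, and 0/1/2 genotype doses at variants inside the
#' gene's CREs (missing doses imputed to the per-variant mode; variants
#' missing in more than half the samples are dropped). Samples missing any
#' layer are dropped with a message.
#'
#' @param gene Gene identifier.
#' @param expr Normalized expression matrix, genes x samples (count scale).
#' @param peaks Interval tibble of accessibility peaks (with element_class
#'   and gene annotations).
#' @param peak_scores Numeric matrix, peaks x samples.
#' @param occupancy A `venomreg_occupancy` for TFBS footprints.
#' @param tfbs Interval tibble for the occupancy rows, with a `gene` column.
#' @param variants Variant tibble.
#' @param tf_genes Character vector of venom-regulating TF gene ids.
#' @param min_samples Minimal number of samples shared by all layers.
#' @param k_denovo Number of unannotated peaks to include.
#' @return A list of class `venomreg_features`: gene, samples, response
#'   (named vector) and `classes` (named list of samples x variables
#'   matrices in the fixed class order).
#' @export
assemble_feature_table <- function(gene, expr, peaks, peak_scores,
                                   occupancy, tfbs, variants, tf_genes,
                                   min_samples = 4L, k_denovo = 3L) {
  if (!gene %in% rownames(expr)) stop("gene '", gene,
                                      "' absent from expression matrix")
  samples <- Reduce(intersect, list(colnames(expr), colnames(peak_scores),
                                    colnames(occupancy$bound),
                                    variant_samples(variants)))
  dropped <- setdiff(colnames(expr), samples)
  if (length(dropped)) {
    message("samples missing a layer dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(samples) < min_samples) {
    stop("only ", length(samples), " samples shared by all layers; need ",
         min_samples)
  }
  gene_cres <- peaks[!is.na(peaks$gene) & peaks$gene == gene &
                       peaks$element_class %in% c("promoter", "enhancer"), ,
                     drop = FALSE]
  if (nrow(gene_cres) == 0L) stop("gene '", gene, "' has no annotated CREs")
  window <- build_gene_window(gene_cres)
  classes <- list()

  classes$cre_accessibility <-
    t(peak_scores[gene_cres$name, samples, drop = FALSE])

  ctcf <- peaks[peaks$element_class == "ctcf" &
                  peaks$chrom == window$chrom[1] &
                  peaks$start < window$end[1] &
                  peaks$end > window$start[1], , drop = FALSE]
  classes$ctcf_accessibility <-
    t(peak_scores[ctcf$name, samples, drop = FALSE])

  denovo <- select_denovo_peaks(peak_scores, peaks, window, k = k_denovo)
  classes$denovo_accessibility <-
    t(peak_scores[denovo, samples, drop = FALSE])

  site_rows <- tfbs[!is.na(tfbs$gene) & tfbs$gene == gene, , drop = FALSE]
  classes$tf_footprints <-
    t(occupancy$bound[site_rows$name, samples, drop = FALSE])

  classes$tf_expression <-
    t(expr[intersect(tf_genes, rownames(expr)), samples, drop = FALSE])

  in_cre <- rep(FALSE, nrow(variants))
  if (nrow(variants)) {
    vi <- variant_interval(variants)
    for (r in seq_len(nrow(gene_cres))) {
      in_cre <- in_cre | (vi$chrom == gene_cres$chrom[r] &
                            vi$start >= gene_cres$start[r] &
                            vi$end <= gene_cres$end[r])
    }
  }
  dose <- genotype_dose(variants[in_cre, , drop = FALSE], samples)
  if (nrow(dose)) {
    too_missing <- rowMeans(is.na(dose)) > 0.5
    dose <- dose[!too_missing, , drop = FALSE]
    for (r in seq_len(nrow(dose))) {
      if (anyNA(dose[r, ])) dose[r, is.na(dose[r, ])] <- impute_mode(dose[r, ])
    }
  }
  classes$cre_genotype <- t(dose)

  structure(list(gene = gene, samples = samples,
                 response = stats::setNames(expr[gene, samples], samples),
                 classes = classes[FEATURE_CLASSES]),
            class = "venomreg_features")
}

#' First principal axis of a contrast block
#'
#' Uncentered PCA (contrasts have zero expectation under Brownian motion) of
#' a contrasts x variables block via singular value decomposition. The PC1
#' sign is fixed so the largest-magnitude loading is positive. Single-column
#' blocks pass through unchanged with variance explained 1.
#'
#' @param block Numeric matrix, contrasts x variables.
#' @param center Center columns before decomposition (default FALSE).
#' @return List with `scores` (length = rows of block), `var_explained`
#'   (in \[0,1\]) and `loadings`.
#' @export
class_pca_pc1 <- function(block, center = FALSE) {
  if (ncol(block) == 1L) {
    return(list(scores = block[, 1], var_explained = 1,
                loadings = stats::setNames(1, colnames(block))))
  }
  x <- if (center) scale(block, center = TRUE, scale = FALSE) else block
  sv <- svd(x)
  load <- sv$v[, 1]
  if (load[which.max(abs(load))] < 0) load <- -load
  list(scores = as.vector(x %*% load),
       var_explained = sv$d[1]^2 / sum(sv$d^2),
       loadings = stats::setNames(load, colnames(block)))
}

#' Fit the per-gene regulatory regression on contrasts
#'
#' Ordinary least squares of the response contrasts on one predictor column
#' per feature class, with intercept by default. Collinear predictors are
#' dropped deterministically, later classes in the fixed class order first.
#'
#' @param response_contrasts Numeric vector of response contrasts.
#' @param class_predictors Named list of numeric vectors (one per retained
#'   class), same length as the response.
#' @param gene Gene label carried into the result.
#' @param var_explained Optional named numeric vector of per-class PC1
#'   variance explained.
#' @param intercept Include an intercept (default TRUE; through-origin with
#'   FALSE).
#' @param dropped Optional named character vector of classes already dropped
#'   upstream, reason per class.
#' @return A tibble of class `venomreg_gene_model`, one row per class:
#'   gene, class, coefficient, abs_coefficient, p_value, significant,
#'   pc1_var_explained, status; attributes r_squared and n_contrasts.
#' @export
fit_gene_model <- function(response_contrasts, class_predictors,
                           gene = NA_character_, var_explained = NULL,
                           intercept = TRUE, dropped = NULL) {
  k <- length(class_predictors)
  n <- length(response_contrasts)
  if (n <= k + as.integer(intercept)) {
    stop("need more contrasts (", n, ") than parameters (",
         k + as.integer(intercept), ")")
  }
  x <- do.call(cbind, class_predictors)
  keep <- colnames(x)
  design <- function(cols) {
    m <- x[, cols, drop = FALSE]
    if (intercept) cbind(`(Intercept)` = 1, m) else m
  }
  collinear <- character(0)
  while (length(keep) &&
         qr(design(keep))$rank < length(keep) + as.integer(intercept)) {
    collinear <- c(collinear, keep[length(keep)])
    keep <- keep[-length(keep)]
  }
  df <- data.frame(.response = response_contrasts,
                   x[, keep, drop = FALSE], check.names = FALSE)
  fml <- if (intercept) .response ~ . else .response ~ . + 0
  fit <- stats::lm(fml, data = df)
  coefs <- summary(fit)$coefficients
  rows <- purrr::map_dfr(names(class_predictors), function(cl) {
    if (cl %in% keep) {
      tibble::tibble(class = cl,
                     coefficient = coefs[cl, 1],
                     p_value = coefs[cl, 4],
                     status = "fit")
    } else {
      tibble::tibble(class = cl, coefficient = NA_real_,
                     p_value = NA_real_, status = "dropped_collinear")
    }
  })
  if (!is.null(dropped) && length(dropped)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      class = names(dropped), coefficient = NA_real_, p_value = NA_real_,
      status = unname(dropped)))
  }
  out <- rows |>
    dplyr::mutate(gene = gene,
                  abs_coefficient = abs(.data$coefficient),
                  significant = !is.na(.data$p_value) & .data$p_value < 0.05,
                  pc1_var_explained =
                    if (is.null(var_explained)) NA_real_ else
                      unname(var_explained[.data$class])) |>
    dplyr::select("gene", "class", "coefficient", "abs_coefficient",
                  "p_value", "significant", "pc1_var_explained", "status") |>
    dplyr::arrange(match(.data$class, FEATURE_CLASSES))
  class(out) <- c("venomreg_gene_model", class(out))
  attr(out, "r_squared") <- summary(fit)$r.squared
  attr(out, "n_contrasts") <- n
  attr(out, "model") <- fit
  out
}

#' @export
glance.venomreg_gene_model <- function(x, ...) {
  tibble::tibble(gene = x$gene[1],
                 r_squared = attr(x, "r_squared"),
                 n_contrasts = attr(x, "n_contrasts"),
                 n_classes_fit = sum(x$status == "fit"),
                 n_significant = sum(x$significant))
}

#' @export
tidy.venomreg_gene_model <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Run the contrast regression for one gene
#'
#' Assembles the feature table, transforms the response and every feature
#' into phylogenetically independent contrasts, reduces each multi-variable
#' class to its first principal axis, and fits the joint regression.
#'
#' @inheritParams assemble_feature_table
#' @param tree Guide tree whose tips are the samples.
#' @param pca_mode `"pc1"` reduces every multi-variable class to PC1 (one
#'   coefficient per class); `"n_rule"` only reduces classes with more
#'   variables than samples and otherwise keeps all columns.
#' @param intercept Passed to [fit_gene_model()].
#' @param epsilon_frac Passed to [pic_contrasts()].
#' @return A `venomreg_gene_model` tibble.
#' @export
model_gene <- function(gene, tree, expr, peaks, peak_scores, occupancy,
                       tfbs, variants, tf_genes,
                       pca_mode = c("pc1", "n_rule"), intercept = TRUE,
                       min_samples = 4L, k_denovo = 3L,
                       epsilon_frac = 1e-6) {
  pca_mode <- match.arg(pca_mode)
  ft <- assemble_feature_table(gene, expr, peaks, peak_scores, occupancy,
                               tfbs, variants, tf_genes,
                               min_samples = min_samples,
                               k_denovo = k_denovo)
  samples <- ft$samples
  n_s <- length(samples)
  blocks <- ft$classes
  dropped <- character(0)
  all_cols <- matrix(ft$response, ncol = 1L,
                     dimnames = list(samples, ".response"))
  col_class <- ".response"
  for (cl in names(blocks)) {
    b <- blocks[[cl]]
    if (is.null(b) || ncol(b) == 0L) {
      dropped[cl] <- "dropped_empty"
      next
    }
    keep <- apply(b, 2L, function(col) stats::var(col) > 0)
    b <- b[, keep, drop = FALSE]
    if (ncol(b) == 0L) {
      dropped[cl] <- "dropped_zero_variance"
      next
    }
    colnames(b) <- paste0(cl, "..", colnames(b))
    all_cols <- cbind(all_cols, b[samples, , drop = FALSE])
    col_class <- c(col_class, rep(cl, ncol(b)))
  }
  contrasts <- pic_contrasts(tree, all_cols, epsilon_frac = epsilon_frac)
  response_c <- contrasts[, 1]
  predictors <- list()
  var_exp <- numeric(0)
  for (cl in setdiff(unique(col_class), ".response")) {
    block <- contrasts[, col_class == cl, drop = FALSE]
    reduce <- ncol(block) > 1L &&
      (pca_mode == "pc1" || ncol(block) > n_s)
    if (reduce) {
      pc <- class_pca_pc1(block)
      predictors[[cl]] <- pc$scores
      var_exp[cl] <- pc$var_explained
    } else if (ncol(block) == 1L) {
      predictors[[cl]] <- block[, 1]
      var_exp[cl] <- 1
    } else {
      for (j in seq_len(ncol(block))) {
        predictors[[colnames(block)[j]]] <- block[, j]
      }
    }
  }
  fit_gene_model(response_c, predictors, gene = gene,
                 var_explained = var_exp, intercept = intercept,
                 dropped = dropped)
}

#' Per-gene regulatory-correlate matrix
#'
#' Runs [model_gene()] for every eligible gene and stacks the per-class
#' rows into the gene x feature-class results matrix. Genes without
#' annotated CREs (or failing assembly for another reason) are reported in
#' the `excluded` attribute with the reason rather than silently dropped.
#'
#' @inheritParams model_gene
#' @param genes Character vector of genes to model.
#' @return A tibble of class `venomreg_matrix`: one row per gene x class,
#'   columns as in [fit_gene_model()] plus r_squared and n_contrasts;
#'   attribute `excluded` is a tibble (gene, reason).
#' @export
run_model_matrix <- function(genes, tree, expr, peaks, peak_scores,
                             occupancy, tfbs, variants, tf_genes,
                             pca_mode = c("pc1", "n_rule"),
                             intercept = TRUE, min_samples = 4L,
                             k_denovo = 3L, epsilon_frac = 1e-6) {
  pca_mode <- match.arg(pca_mode)
  results <- list()
  excluded <- list()
  for (g in genes) {
    res <- tryCatch(
      model_gene(g, tree, expr, peaks, peak_scores, occupancy, tfbs,
                 variants, tf_genes, pca_mode = pca_mode,
                 intercept = intercept, min_samples = min_samples,
                 k_denovo = k_denovo, epsilon_frac = epsilon_frac),
      error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        tibble::tibble(gene = g, reason = conditionMessage(res))
    } else {
      res$r_squared <- attr(res, "r_squared")
      res$n_contrasts <- attr(res, "n_contrasts")
      results[[length(results) + 1L]] <- tibble::as_tibble(res)
    }
  }
  out <- if (length(results)) dplyr::bind_rows(results) else
    tibble::tibble(gene = character(), class = character(),
                   coefficient = numeric(), abs_coefficient = numeric(),
                   p_value = numeric(), significant = logical(),
                   pc1_var_explained = numeric(), status = character(),
                   r_squared = numeric(), n_contrasts = integer())
  class(out) <- c("venomreg_matrix", class(out))
  attr(out, "excluded") <- if (length(excluded)) dplyr::bind_rows(excluded)
    else tibble::tibble(gene = character(), reason = character())
  out
}

#' Dot-matrix view of the per-gene regulatory-correlate results
#'
#' Point size encodes the absolute coefficient, color the -log10 p-value
#' (shifting at the significance point), and significant gene x class cells
#' are outlined.
#'
#' @param object A `venomreg_matrix` from [run_model_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venomreg_matrix <- function(object, ...) {
  df <- dplyr::filter(object, .data$status == "fit")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$class)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$abs_coefficient,
                                     color = -log10(.data$p_value))) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                        ggplot2::aes(size = .data$abs_coefficient),
                        shape = 21, color = "black", fill = NA,
                        stroke = 0.8) +
    ggplot2::scale_color_gradient2(low = "grey70", mid = "grey50",
                                   high = "#B2182B",
                                   midpoint = -log10(0.05),
                                   name = "-log10 p") +
    ggplot2::scale_size_continuous(name = "|coefficient|") +
    ggplot2::labs(x = "venom gene", y = "feature class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
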