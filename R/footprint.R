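# Footprint score binarization into bound/unbound calls, per-element
# occupancy counting, and intersection of bound sites with variants.

# Deterministic 1-D 2-means: centers initialized at the 10th and 90th
# percentiles, Lloyd iterations to convergence. Returns the two centers.
two_means_1d <- function(x, max_iter = 100L) {
  centers <- unname(stats::quantile(x, c(0.1, 0.9), type = 7))
  if (diff(centers) == 0) return(NULL)
  for (it in seq_len(max_iter)) {
    assign_hi <- abs(x - centers[2]) < abs(x - centers[1])
    if (!any(assign_hi) || all(assign_hi)) break
    new_centers <- c(mean(x[!assign_hi]), mean(x[assign_hi]))
    if (isTRUE(all.equal(new_centers, centers))) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  sort(centers)
}

#' Binarize footprint scores into bound/unbound calls
#'
#' Footprint scores at candidate binding sites are split per sample into a
#' bound and an unbound population. When per-sample binding thresholds are
#' supplied (e.g. computed by upstream footprinting tooling) they are used
#' directly; otherwise each sample's threshold is estimated as the midpoint
#' between the two cluster centers of a deterministic 2-means split of that
#' sample's scores (centers initialized at the 10th and 90th percentiles).
#' Scores exactly at the threshold count as bound. A sample whose scores
#' are constant has no defined threshold and is called all-unbound with a
#' warning.
#'
#' @param scores Numeric matrix, TFBS x samples.
#' @param thresholds Optional named numeric vector of per-sample thresholds.
#' @param min_sites Minimal number of TFBS rows required to estimate a
#'   threshold.
#' @return A list of class `venomreg_occupancy` with `scores`, `bound`
#'   (binary matrix) and `thresholds`.
#' @export
binarize_footprints <- function(scores, thresholds = NULL, min_sites = 20L) {
  samples <- colnames(scores)
  if (is.null(thresholds)) {
    if (nrow(scores) < min_sites) {
      stop("need at least ", min_sites,
           " TFBS rows to estimate thresholds; supply them explicitly")
    }
    thresholds <- vapply(samples, function(s) {
      centers <- two_means_1d(scores[, s])
      if (is.null(centers)) {
        warning("constant scores for sample '", s,
                "'; threshold undefined, all sites called unbound")
        return(Inf)
      }
      mean(centers)
    }, numeric(1))
  } else {
    missing <- setdiff(samples, names(thresholds))
    if (length(missing)) stop("thresholds missing for: ",
                              paste(missing, collapse = ", "))
    thresholds <- thresholds[samples]
  }
  bound <- sweep(scores, 2L, thresholds, ">=") * 1L
  structure(list(scores = scores, bound = bound, thresholds = thresholds),
            class = "venomreg_occupancy")
}

#' @exportS3Method base::print
print.venomreg_occupancy <- function(x, ...) {
  cat("<occupancy: ", nrow(x$bound), " TFBS x ", ncol(x$bound),
      " samples; ", round(100 * mean(x$bound), 1), "% bound>\n", sep = "")
  invisible(x)
}

#' Count bound TFBSs per TF per sample within an element
#'
#' @param occ A `venomreg_occupancy` from [binarize_footprints()].
#' @param tfbs Interval tibble for the TFBS rows of the occupancy matrix
#'   (same order/names), with a `tf_name` column and an `element` column
#'   naming the containing element.
#' @param element Name of the element to summarize.
#' @return Tibble with sample, tf_name, n_bound (zero counts retained).
#' @export
count_binding_events <- function(occ, tfbs, element) {
  rows <- which(tfbs$element == element)
  if (!length(rows)) {
    warning("element '", element, "' has no TFBS")
    return(tibble::tibble(sample = character(), tf_name = character(),
                          n_bound = integer()))
  }
  sub <- occ$bound[rows, , drop = FALSE]
  tf <- tfbs$tf_name[rows]
  tidyr::expand_grid(sample = colnames(sub), tf_name = unique(tf)) |>
    dplyr::rowwise() |>
    dplyr::mutate(n_bound = sum(sub[tf == .data$tf_name, .data$sample])) |>
    dplyr::ungroup()
}

#' Intersect bound TFBSs with overlapping variants
#'
#' For every TFBS x variant pair where the variant's reference span overlaps
#' the site's half-open interval, tabulates each sample's joint (bound,
#' genotype) state and flags the site as differentially bound with a motif
#' variant when binding segregates perfectly with the allele: every
#' alternate-carrying sample unbound and at least one homozygous-reference
#' sample bound, or the mirror image.
#'
#' @param occ A `venomreg_occupancy`.
#' @param tfbs Interval tibble for the occupancy rows (chrom, start, end,
#'   name, tf_name).
#' @param variants Variant tibble.
#' @return Tibble with tfbs, tf_name, variant coordinates, per-state sample
#'   lists (comma-separated) and a `flagged` logical.
#' @export
intersect_bound_variants <- function(occ, tfbs, variants) {
  samples <- intersect(colnames(occ$bound), variant_samples(variants))
  out <- list()
  vi <- variant_interval(variants)
  for (i in seq_len(nrow(tfbs))) {
    ov <- which(vi$chrom == tfbs$chrom[i] &
                  vi$start < tfbs$end[i] & vi$end > tfbs$start[i])
    for (j in ov) {
      gt <- unlist(variants[j, samples])
      bound <- occ$bound[tfbs$name[i], samples] == 1L
      carrier <- gt %in% c("het", "hom_alt")
      refhom <- gt == "hom_ref"
      flagged <- (any(refhom) && any(carrier)) &&
        ((all(!bound[carrier]) && any(bound[refhom])) ||
           (all(bound[carrier]) && any(refhom) && all(!bound[refhom])))
      site_name <- tfbs$name[i]
      site_tf <- tfbs$tf_name[i]
      out[[length(out) + 1L]] <- tibble::tibble(
        tfbs = site_name, tf_name = site_tf,
        chrom = variants$chrom[j], pos = variants$pos[j],
        ref = variants$ref[j], alt = variants$alt[j],
        bound_ref_samples = paste(samples[refhom & bound], collapse = ","),
        unbound_ref_samples = paste(samples[refhom & !bound],
                                    collapse = ","),
        bound_alt_samples = paste(samples[carrier & bound], collapse = ","),
        unbound_alt_samples = paste(samples[carrier & !bound],
                                    collapse = ","),
        flagged = flagged)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(tfbs = character(), tf_name = character(),
                          chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          bound_ref_samples = character(),
                          unbound_ref_samples = character(),
                          bound_alt_samples = character(),
                          unbound_alt_samples = character(),
                          flagged = logical()))
  }
  dplyr::bind_rows(out)
}

#' Per-sample TF binding frequency bar chart for one element
#' @param object A `venomreg_occupancy`.
#' @param tfbs,element As in [count_binding_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_binding_events <- function(object, tfbs, element, ...) {
  counts <- count_binding_events(object, tfbs, element)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$sample, y = .data$n_bound,
                                       fill = .data$tf_name)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "bound TFBSs", fill = "TF",
                  title = element) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
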