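# End-to-end orchestration of the analysis stages over an input bundle,
# with deterministic plain-text outputs.

#' Run the full analysis pipeline over a bundle
#'
#' Executes every stage in order — gland combining, normalization, variance
#' analysis, the TF-venom correlation network, CLR transcriptome-proteome
#' coupling, per-CRE consensus projection with nucleotide diversity,
#' variant-induced TFBS change classification and the sharing spectrum,
#' footprint binarization with variant intersection, depth-ratio deletion
#' calling, and the phylogenetic-contrast regulatory regression — and
#' optionally writes each result as a TSV. All stages are deterministic
#' given the bundle, so a fixed generator seed yields byte-identical
#' outputs.
#'
#' @param bundle A `venomreg_bundle` (see [simulate_bundle()]) or an
#'   equivalently shaped list read from disk.
#' @param out_dir Optional directory for TSV outputs.
#' @param model_genes Genes to model (default: all venom genes with
#'   annotated CREs).
#' @param deletion_query Optional one-row interval tibble for the deletion
#'   scan; defaults to the enhancer arrays covered by the depth windows,
#'   padded by one window width.
#' @return A named list of stage results.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, model_genes = NULL,
                         deletion_query = NULL) {
  res <- list()
  combined <- combine_glands(bundle$counts, bundle$meta)
  combined <- combined[, bundle$tree$tip.label, drop = FALSE]
  res$size_factors <- size_factors_median_of_ratios(combined)
  norm_counts <- normalize_counts(combined, transform = "none",
                                  size_factors = res$size_factors)
  norm_log <- normalize_counts(combined, transform = "log2p1",
                               size_factors = res$size_factors)
  res$normalized <- norm_log

  res$variance_all <- expression_variance(norm_log)
  focal <- bundle$meta$individual[bundle$meta$lineage == "lin1"]
  focal <- intersect(unique(focal), colnames(norm_log))
  res$variance_within <- if (length(focal) >= 2)
    expression_variance(norm_log, samples = focal) else NULL
  v <- res$variance_all
  res$variance_test <- variance_group_test(
    v$variance[v$gene %in% bundle$venom_genes],
    v$variance[v$gene %in% bundle$nvp_genes])

  res$correlations <- tf_venom_correlation(norm_log, bundle$tf_genes,
                                           bundle$venom_genes)

  venom_mrna <- norm_counts[intersect(bundle$venom_genes,
                                      rownames(norm_counts)), ,
                            drop = FALSE]
  res$proteo_fit <- mrna_protein_fit(
    pair_abundances(venom_mrna, bundle$protein))

  cres <- bundle$peaks[bundle$peaks$element_class %in%
                         c("promoter", "enhancer"), , drop = FALSE]
  samples <- bundle$tree$tip.label
  pi_rows <- list()
  change_rows <- list()
  for (i in seq_len(nrow(cres))) {
    cre_row <- cres[i, ]
    cls <- cre_row$element_class
    ref_seq <- bundle$cre_seqs[[cre_row$name]]
    seqs <- vapply(samples, function(s)
      project_consensus(ref_seq, bundle$variants, s, cre_row),
      character(1))
    pi_rows[[i]] <- nucleotide_diversity(
      consensus_set(cre_row, c(reference = ref_seq, seqs))) |>
      dplyr::mutate(element_class = cls, gene = cre_row$gene)
    ch <- classify_tfbs_changes(ref_seq, bundle$variants, bundle$motifs,
                                cre_row)
    if (nrow(ch)) change_rows[[length(change_rows) + 1L]] <-
        dplyr::mutate(ch, cre = cre_row$name, element_class = cls)
  }
  res$diversity <- dplyr::bind_rows(pi_rows)
  res$tfbs_changes <- if (length(change_rows))
    dplyr::bind_rows(change_rows) else NULL
  if (!is.null(res$tfbs_changes)) {
    pres <- changes_presence(res$tfbs_changes, samples)
    res$sharing_spectrum <- tfbs_sharing_spectrum(pres)
  }

  res$occupancy <- binarize_footprints(bundle$footprint_scores)
  res$bound_variants <- intersect_bound_variants(res$occupancy,
                                                 bundle$tfbs,
                                                 bundle$variants)

  depth_span <- range(c(bundle$depth$windows$start,
                        bundle$depth$windows$end))
  if (is.null(deletion_query)) {
    covered <- cres[cres$element_class == "enhancer" &
                      cres$chrom == bundle$depth$windows$chrom[1] &
                      cres$start >= depth_span[1] &
                      cres$end <= depth_span[2], , drop = FALSE]
    if (nrow(covered)) {
      width <- bundle$depth$windows$end[1] - bundle$depth$windows$start[1]
      deletion_query <- tibble::tibble(
        chrom = covered$chrom[1],
        start = max(depth_span[1], min(covered$start) - 4L * width),
        end = min(depth_span[2], max(covered$end) + 4L * width))
    }
  }
  if (!is.null(deletion_query)) {
    dr <- depth_ratio(bundle$depth$depth, bundle$depth$windows,
                      exclude = deletion_query)
    res$deletion_calls <- call_deletion(dr, deletion_query)
    res$deletion_span <- summarize_deletion(res$deletion_calls)
  }

  if (is.null(model_genes)) {
    model_genes <- intersect(bundle$venom_genes,
                             unique(stats::na.omit(cres$gene)))
  }
  res$model_matrix <- run_model_matrix(
    model_genes, bundle$tree, norm_log, bundle$peaks, bundle$peak_scores,
    res$occupancy, bundle$tfbs, bundle$variants, bundle$tf_genes)

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

round_num <- function(df, digits = 10) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ signif(.x, digits)))
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_score_tsv(res$normalized, p("normalized_log2.tsv"),
                  id_col = "gene")
  readr::write_tsv(round_num(res$variance_all), p("variance_all.tsv"))
  if (!is.null(res$variance_within)) {
    readr::write_tsv(round_num(res$variance_within),
                     p("variance_within.tsv"))
  }
  readr::write_tsv(round_num(res$variance_test), p("variance_test.tsv"))
  readr::write_tsv(round_num(tibble::as_tibble(res$correlations)),
                   p("tf_venom_correlations.tsv"))
  readr::write_tsv(round_num(glance(res$proteo_fit)), p("proteo_fit.tsv"))
  readr::write_tsv(round_num(res$diversity), p("cre_diversity.tsv"))
  if (!is.null(res$tfbs_changes)) {
    readr::write_tsv(res$tfbs_changes, p("tfbs_changes.tsv"))
    readr::write_tsv(tibble::as_tibble(res$sharing_spectrum),
                     p("tfbs_sharing_spectrum.tsv"))
  }
  readr::write_tsv(res$bound_variants, p("bound_variant_tfbs.tsv"))
  if (!is.null(res$deletion_calls)) {
    readr::write_tsv(round_num(res$deletion_calls), p("deletion_calls.tsv"))
    readr::write_tsv(res$deletion_span, p("deletion_span.tsv"))
  }
  readr::write_tsv(round_num(tibble::as_tibble(res$model_matrix)),
                   p("regulatory_model_matrix.tsv"))
  invisible(out_dir)
}
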