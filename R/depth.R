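# Deletion evidence from windowed resequencing depth ratios.

#' Normalize windowed depth by per-sample background medians
#'
#' ratio\[w, s\] = depth\[w, s\] / median_s, where median_s is the sample's
#' median depth over background windows. By default the background excludes
#' the query region so a large deletion cannot drag its own baseline down.
#'
#' @param depth Numeric matrix, windows x samples.
#' @param windows Interval tibble describing the rows of `depth`.
#' @param exclude Optional one-row interval tibble (e.g. the query region)
#'   removed from the background before taking medians.
#' @return A list of class `venomreg_depth` with `ratio` (windows x samples),
#'   `windows` and `medians`.
#' @export
depth_ratio <- function(depth, windows, exclude = NULL) {
  bg <- rep(TRUE, nrow(windows))
  if (!is.null(exclude)) {
    bg <- !(windows$chrom == exclude$chrom[1] &
              windows$start < exclude$end[1] &
              windows$end > exclude$start[1])
  }
  if (!any(bg)) stop("no background windows left after exclusion")
  medians <- apply(depth[bg, , drop = FALSE], 2L, stats::median)
  if (any(medians <= 0)) {
    stop("zero median depth for sample(s): ",
         paste(colnames(depth)[medians <= 0], collapse = ", "))
  }
  structure(list(ratio = sweep(depth, 2L, medians, "/"),
                 windows = windows, medians = medians),
            class = "venomreg_depth")
}

#' Call per-sample deletions over a query interval from depth ratios
#'
#' A homozygous deletion is called when at least `min_consecutive_windows`
#' windows inside the query have depth ratio below `hom_threshold`; a
#' heterozygous deletion when the supporting windows sit below
#' `het_threshold` (but not below `hom_threshold` throughout). Qualifying
#' windows separated by at most `max_gap` non-qualifying windows are merged
#' into one supporting run — single boundary windows of a true heterozygous
#' deletion drift above the threshold by counting noise, and merging across
#' such gaps is standard read-depth segmentation practice. The run with the
#' most supporting windows is reported, with its window span.
#'
#' @param ratios A `venomreg_depth` from [depth_ratio()].
#' @param query One-row interval tibble covering the candidate deletion.
#' @param hom_threshold Ratio below which a window counts as homozygous
#'   deleted (default 0.25).
#' @param het_threshold Ratio below which a window counts as deleted on one
#'   haplotype (default 0.75).
#' @param min_consecutive_windows Minimal number of supporting windows
#'   (default 3).
#' @param max_gap Maximal number of consecutive non-qualifying windows
#'   bridged inside a run (default 1).
#' @return Tibble with sample, call (`none`/`het_del`/`hom_del`), run_length
#'   (supporting windows), run_start, run_end (coordinates of the supporting
#'   window run) and mean_ratio over the run.
#' @export
call_deletion <- function(ratios, query, hom_threshold = 0.25,
                          het_threshold = 0.75,
                          min_consecutive_windows = 3L, max_gap = 1L) {
  w <- ratios$windows
  in_query <- which(w$chrom == query$chrom[1] &
                      w$start < query$end[1] & w$end > query$start[1])
  if (length(in_query) < min_consecutive_windows) {
    stop("query interval covered by ", length(in_query),
         " windows; need at least ", min_consecutive_windows)
  }
  in_query <- in_query[order(w$start[in_query])]
  best_run <- function(low) {
    idx <- which(unname(low))
    if (length(idx) < min_consecutive_windows) return(NULL)
    grp <- cumsum(c(1L, diff(idx) > max_gap + 1L))
    sizes <- tabulate(grp)
    if (max(sizes) < min_consecutive_windows) return(NULL)
    members <- idx[grp == which.max(sizes)]
    c(from = min(members), to = max(members), support = length(members))
  }
  purrr::map_dfr(colnames(ratios$ratio), function(s) {
    x <- ratios$ratio[in_query, s]
    hom <- best_run(x < hom_threshold)
    het <- best_run(x < het_threshold)
    if (!is.null(hom)) {
      call <- "hom_del"; run <- hom
    } else if (!is.null(het)) {
      call <- "het_del"; run <- het
    } else {
      return(tibble::tibble(sample = s, call = "none", run_length = 0L,
                            run_start = NA_integer_, run_end = NA_integer_,
                            mean_ratio = mean(x)))
    }
    idx <- in_query[run[["from"]]:run[["to"]]]
    tibble::tibble(sample = s, call = call,
                   run_length = as.integer(run[["support"]]),
                   run_start = min(w$start[idx]),
                   run_end = max(w$end[idx]),
                   mean_ratio = mean(ratios$ratio[idx, s]))
  })
}

#' Consensus deletion span across carrier samples
#'
#' Breakpoints of a deletion are shared by its carriers, so the interval is
#' estimated by pooling the supporting runs of every sample with a
#' non-`none` call: the union of their spans, with the carrier list and
#' per-zygosity counts.
#'
#' @param calls Tibble from [call_deletion()].
#' @return One-row tibble with start, end, n_carriers, n_hom, n_het and a
#'   comma-separated carrier list; zero rows when nothing was called.
#' @export
summarize_deletion <- function(calls) {
  hit <- calls[calls$call != "none", , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_carriers = integer(), n_hom = integer(),
                          n_het = integer(), carriers = character()))
  }
  tibble::tibble(start = min(hit$run_start), end = max(hit$run_end),
                 n_carriers = nrow(hit),
                 n_hom = sum(hit$call == "hom_del"),
                 n_het = sum(hit$call == "het_del"),
                 carriers = paste(sort(hit$sample), collapse = ","))
}

#' Depth-ratio profile across a region, one line per sample
#' @param object A `venomreg_depth`.
#' @param region Optional one-row interval tibble restricting the windows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_depth_ratio <- function(object, region = NULL, ...) {
  w <- object$windows
  keep <- rep(TRUE, nrow(w))
  if (!is.null(region)) {
    keep <- w$chrom == region$chrom[1] & w$start < region$end[1] &
      w$end > region$start[1]
  }
  df <- tibble::as_tibble(object$ratio[keep, , drop = FALSE]) |>
    dplyr::mutate(mid = (w$start[keep] + w$end[keep]) / 2) |>
    tidyr::pivot_longer(-"mid", names_to = "sample", values_to = "ratio")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$ratio,
                                   color = .data$sample)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = c(0.25, 0.75), linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "position", y = "depth ratio") +
    ggplot2::theme_minimal()
}
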