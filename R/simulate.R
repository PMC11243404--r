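# Seeded synthetic-data generator: a complete, internally consistent input
# bundle (tree, counts, accessibility, footprints, variants, CRE sequences,
# depth, protein) with known ground truth, emulating a 12-sample,
# 4-lineage rattlesnake sampling design.

#' Simulate a lineage tree with within-lineage sample tips
#'
#' A pure-birth tree over the lineages; each sample is then attached under
#' its lineage's tip with a short branch of length `epsilon_frac` times the
#' tree height, so within-lineage covariance is high but the Brownian-motion
#' contrast model remains exactly satisfiable. With one sample per lineage
#' the lineage tips are simply relabeled.
#'
#' @param n_lineages Number of lineages (>= 2).
#' @param samples_per_lineage Samples attached under each lineage (>= 1).
#' @param seed Integer seed; the same seed gives an identical tree.
#' @param epsilon_frac Sample-branch length as a fraction of tree height.
#' @return An `ape::phylo` tree with `n_lineages * samples_per_lineage`
#'   tips named `<lineage>_<i>`.
#' @export
simulate_tree <- function(n_lineages, samples_per_lineage, seed,
                          epsilon_frac = 0.01) {
  if (n_lineages < 2L) stop("need at least 2 lineages")
  if (samples_per_lineage < 1L) stop("need at least 1 sample per lineage")
  set.seed(seed)
  base <- ape::rphylo(n_lineages, birth = 1, death = 0)
  base$tip.label <- paste0("lin", seq_len(n_lineages))
  height <- max(ape::node.depth.edgelength(base))
  eps <- format(epsilon_frac * height, scientific = FALSE, digits = 12)
  nwk <- ape::write.tree(base)
  for (l in base$tip.label) {
    labels <- paste0(l, "_", seq_len(samples_per_lineage))
    rep_with <- if (samples_per_lineage == 1L) labels else
      paste0("(", paste0(labels, ":", eps, collapse = ","), ")")
    nwk <- sub(paste0(l, ":"), paste0(rep_with, ":"), nwk, fixed = TRUE)
  }
  ape::read.tree(text = nwk)
}

#' Sample metadata implied by a simulated tree
#'
#' @param tree Tree from [simulate_tree()].
#' @param gland_replicates Emit two rows (left/right gland) per individual.
#' @return Metadata tibble with sample_id, individual, lineage, population,
#'   gland_side.
#' @export
tree_sample_meta <- function(tree, gland_replicates = FALSE) {
  ind <- tree$tip.label
  lineage <- sub("_[0-9]+$", "", ind)
  idx <- as.integer(sub("^.*_", "", ind))
  # the focal lineage carries a latitude-population structure
  population <- ifelse(lineage == "lin1",
                       c("south", "mid", "north")[(idx - 1L) %% 3L + 1L],
                       lineage)
  base <- tibble::tibble(individual = ind, lineage = lineage,
                         population = population)
  if (!gland_replicates) {
    return(dplyr::mutate(base, sample_id = .data$individual,
                         gland_side = NA_character_) |>
             dplyr::select("sample_id", "individual", "lineage",
                           "population", "gland_side"))
  }
  dplyr::bind_rows(
    dplyr::mutate(base, sample_id = paste0(.data$individual, "_L"),
                  gland_side = "left"),
    dplyr::mutate(base, sample_id = paste0(.data$individual, "_R"),
                  gland_side = "right")) |>
    dplyr::arrange(.data$individual, .data$gland_side) |>
    dplyr::select("sample_id", "individual", "lineage", "population",
                  "gland_side")
}

# One Brownian-motion draw on the tree: per-tip values with covariance
# rate * shared-path-length. Uses the current RNG stream. The Cholesky
# factor of the tip covariance can be precomputed with bm_chol() when many
# draws are taken from the same tree.
sim_bm <- function(tree, rate = 1, chol_factor = NULL) {
  if (is.null(chol_factor)) chol_factor <- bm_chol(tree)
  tips <- colnames(chol_factor)
  stats::setNames(as.vector(t(chol_factor) %*% stats::rnorm(length(tips))) *
                    sqrt(rate), tips)
}

bm_chol <- function(tree) {
  chol(ape::vcv(tree))
}

#' Simulate a counts matrix with Brownian lineage signal
#'
#' Per-gene latent log-means evolve by Brownian motion on the tree (rate
#' `bm_rate`), optionally plus planted linear contributions from supplied
#' driver variables; counts are negative-binomial around exp(latent) with
#' the given dispersion (dispersion 0 gives deterministic rounded means).
#'
#' @param tree Tree whose tips are the individuals.
#' @param n_genes Number of genes.
#' @param effects Optional list of planted effects, each
#'   `list(gene = <index or name>, driver = <named per-tip vector>,
#'   beta = <effect size>)`; the driver is standardized across tips before
#'   scaling by beta.
#' @param baseline_log_mean Baseline natural-log mean count.
#' @param bm_rate Brownian rate of the latent log-mean (scalar or per-gene).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed Integer seed.
#' @param gene_names Optional gene names (default g1..gN).
#' @param gland_replicates Emit left/right gland libraries per individual,
#'   each negative-binomial around half the individual's mean.
#' @return List with `counts` (genes x samples integer matrix), `latent`
#'   (genes x individuals log-mean matrix) and `meta`.
#' @export
simulate_expression <- function(tree, n_genes, effects = NULL,
                                baseline_log_mean = 5, bm_rate = 0.25,
                                dispersion = 0.1, seed = 1,
                                gene_names = NULL,
                                gland_replicates = FALSE) {
  set.seed(seed)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes)
  bm_rate <- rep_len(bm_rate, n_genes)
  tips <- tree$tip.label
  chol_factor <- bm_chol(tree)
  latent <- matrix(baseline_log_mean, n_genes, length(tips),
                   dimnames = list(gene_names, tips))
  for (g in seq_len(n_genes)) {
    if (bm_rate[g] > 0) latent[g, ] <- latent[g, ] + sim_bm(tree, bm_rate[g], chol_factor)
  }
  for (ef in effects) {
    g <- ef$gene
    if (is.character(g) && !g %in% gene_names ||
        is.numeric(g) && (g < 1 || g > n_genes)) {
      stop("planted effect references unknown gene: ", g)
    }
    drv <- ef$driver[tips]
    drv_sd <- stats::sd(drv)
    if (drv_sd > 0) drv <- (drv - mean(drv)) / drv_sd
    latent[g, ] <- latent[g, ] + ef$beta * drv
  }
  meta <- tree_sample_meta(tree, gland_replicates = gland_replicates)
  draw <- function(mu) {
    if (dispersion == 0) return(round(mu))
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  if (gland_replicates) {
    counts <- matrix(0L, n_genes, nrow(meta),
                     dimnames = list(gene_names, meta$sample_id))
    for (s in meta$sample_id) {
      ind <- meta$individual[meta$sample_id == s]
      counts[, s] <- as.integer(draw(exp(latent[, ind]) / 2))
    }
  } else {
    counts <- matrix(0L, n_genes, length(tips),
                     dimnames = list(gene_names, tips))
    for (s in tips) counts[, s] <- as.integer(draw(exp(latent[, s])))
  }
  list(counts = counts, latent = latent, meta = meta)
}

#' Default synthetic-bundle configuration
#'
#' Sized to the study design the generator emulates: 4 lineages with 3
#' sampled individuals each, ~50 venom genes of which 41 carry predicted
#' enhancers and all carry promoters, a compact venom-regulating TF panel,
#' bimodal footprint scores, a handful of motif-breaking variants, and one
#' several-kilobase enhancer deletion carried by two individuals of the
#' focal lineage.
#'
#' @return A named list of generator parameters.
#' @export
default_config <- function() {
  list(
    n_lineages = 4L, samples_per_lineage = 3L,
    n_venom = 50L, n_enhancers = 41L, n_nvp = 30L, n_background = 80L,
    tf_names = c("GATA4", "GATA6", "FOS", "DDIT3", "ATF4", "XBP1",
                 "PITX2", "EHF", "NFIB", "KLF4",
                 paste0("TF", 11:40)),
    baseline_log_mean = 5, venom_bm_rate = 0.6, nvp_bm_rate = 0.1,
    background_bm_rate = 0.25, tf_bm_rate = 0.4, dispersion = 0.1,
    gland_replicates = TRUE,
    n_planted = 5L, planted_beta = 1.5, driver_bm_rate = 1,
    tfbs_per_cre = 3L, n_breaking_snp = 9L, n_breaking_indel = 1L,
    snps_per_cre = 2L, individual_variant_prob = 0.4,
    footprint_flip_prob = 0.08,
    accessibility_log_mean = 3, accessibility_bm_rate = 0.15,
    accessibility_noise_sd = 0.05, accessibility_peak_sd = 0.3,
    driver_score_sd = 6,
    footprint_mu_unbound = 1, footprint_mu_bound = 8, footprint_sd = 1,
    footprint_bound_prob = 0.7,
    gene_spacing = 50000L, promoter_len = 500L, enhancer_len = 800L,
    deletion_gene_index = 2L, deletion_pad = 1500L,
    depth_mean = 50, depth_window = 500L, depth_flank = 20000L,
    protein_factor_sd = 0.3, protein_noise_sd = 0.5
  )
}

venom_gene_names <- function(n) {
  fams <- c(rep("SVMP", 15), rep("SVSP", 15), rep("PLA2", 10),
            rep("CTL", 10))
  nm <- paste0(fams, stats::ave(seq_along(fams), fams, FUN = seq_along))
  rep_len(nm, n)
}

nvp_gene_names <- function(n) {
  fams <- c(rep("ADAM", 10), rep("nvPLA2", 8), rep("BDEF", 6),
            rep("nvSP", 6))
  nm <- paste0(fams, stats::ave(seq_along(fams), fams, FUN = seq_along))
  rep_len(nm, n)
}

#' Annotated CRE and peak layout for the synthetic genome
#'
#' Lays venom gene arrays along one chromosome: per gene a promoter, an
#' enhancer (for the first `n_enhancers` genes), one CTCF-bound peak, and
#' three unannotated variable peaks, all inside the gene's array window.
#'
#' @param config Configuration list, see [default_config()].
#' @return Interval tibble of peaks with element_class and gene columns.
#' @export
default_cre_annotation <- function(config = default_config()) {
  genes <- venom_gene_names(config$n_venom)
  rows <- list()
  for (i in seq_along(genes)) {
    g0 <- (i - 1L) * config$gene_spacing
    g <- genes[i]
    add <- function(start, len, cls, suffix) {
      s0 <- g0 + start
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        chrom = "chr1", start = s0, end = s0 + len,
        name = paste0(g, "_", suffix), element_class = cls, gene = g)
    }
    add(1000L, config$promoter_len, "promoter", "prom")
    if (i <= config$n_enhancers) add(3000L, config$enhancer_len,
                                     "enhancer", "enh")
    add(1600L, 400L, "ctcf", "ctcf")
    add(300L, 300L, "denovo_peak", "peak1")
    add(1800L, 300L, "denovo_peak", "peak2")
    add(2100L, 300L, "denovo_peak", "peak3")
    add(2400L, 300L, "denovo_peak", "peak4")
  }
  dplyr::bind_rows(rows)
}

# A strongly specific motif: per column one consensus base with count 12,
# others 0. Length-6 motifs lose a hit at the 0.15 similarity threshold
# after a single consensus->worst-base substitution.
make_consensus_motif <- function(motif_id, tf_name, consensus) {
  L <- nchar(consensus)
  pfm <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  pfm[cbind(idx, seq_len(L))] <- 12
  new_motif(motif_id, tf_name, pfm)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the regulatory layers of the bundle
#'
#' Generates, consistently with one another: accessibility scores at all
#' peaks (log-normal; the planted enhancers carry the Brownian latent
#' driver of their target gene), bimodal footprint scores at TFBSs planted
#' in CRE sequences (bound state forced to unbound in samples carrying a
#' motif-breaking alternate allele), variants inside CREs including the
#' designated motif-breaking ones, reference CRE sequences containing the
#' planted motif instances, a windowed depth table carrying one
#' several-kilobase deletion, and the motif set itself.
#'
#' @param tree Tree from [simulate_tree()] (tips = individuals).
#' @param cre_annotation Peak tibble from [default_cre_annotation()].
#' @param config Configuration list.
#' @param seed Integer seed.
#' @return A list with peaks, peak_scores, motifs, tfbs, footprint_scores,
#'   variants, cre_seqs, depth (list windows/depth), drivers and truth
#'   components (planted, motif_breaking, deletion).
#' @export
simulate_regulatory_layers <- function(tree, cre_annotation,
                                       config = default_config(), seed = 1) {
  set.seed(seed)
  tips <- tree$tip.label
  n_s <- length(tips)
  lineage <- sub("_[0-9]+$", "", tips)
  peaks <- cre_annotation

  motif_ids <- c("MA0001", "MA0002", "MA0003", "MA0004", "MA0005", "MA0006")
  motif_tfs <- config$tf_names[seq_along(motif_ids)]
  motifs <- purrr::map2(motif_ids, motif_tfs, function(id, tf) {
    make_consensus_motif(id, tf, random_dna(6L))
  })
  names(motifs) <- motif_ids

  cres <- peaks[peaks$element_class %in% c("promoter", "enhancer"), ,
                drop = FALSE]
  cre_seqs <- character(nrow(cres))
  names(cre_seqs) <- cres$name
  tfbs_rows <- list()
  for (i in seq_len(nrow(cres))) {
    len <- cres$end[i] - cres$start[i]
    s <- random_dna(len)
    slots <- seq(10L, len - 20L,
                 length.out = config$tfbs_per_cre)   # 0-based offsets
    for (k in seq_len(config$tfbs_per_cre)) {
      m <- motifs[[sample(length(motifs), 1L)]]
      off <- as.integer(slots[k])
      strand <- sample(c("+", "-"), 1L)
      cons <- paste(c("A", "C", "G", "T")[apply(m$pfm, 2L, which.max)],
                    collapse = "")
      planted <- if (strand == "+") cons else revcomp(cons)
      substr(s, off + 1L, off + nchar(planted)) <- planted
      tfbs_rows[[length(tfbs_rows) + 1L]] <- tibble::tibble(
        chrom = cres$chrom[i], start = cres$start[i] + off,
        end = cres$start[i] + off + nchar(planted),
        name = paste0(cres$name[i], "_site", k),
        motif_id = m$motif_id, tf_name = m$tf_name, strand = strand,
        element = cres$name[i], element_class = cres$element_class[i],
        gene = cres$gene[i])
    }
    cre_seqs[i] <- s
  }
  tfbs <- dplyr::bind_rows(tfbs_rows)

  # -- variants ------------------------------------------------------------
  lineage_levels <- unique(lineage)
  # lineage-fixed differences most of the time, segregating within-population
  # polymorphism otherwise (the latter produces singleton TFBS sharing
  # classes, as in real resequencing panels)
  draw_lineage_gt <- function() {
    if (stats::runif(1) < config$individual_variant_prob) {
      repeat {
        af <- stats::runif(1, 0.05, 0.45)
        doses <- stats::rbinom(n_s, 2L, af)
        if (any(doses > 0L)) {
          return(stats::setNames(
            c("hom_ref", "het", "hom_alt")[doses + 1L], tips))
        }
      }
    }
    repeat {
      gt <- sample(c("hom_ref", "het", "hom_alt"), length(lineage_levels),
                   replace = TRUE, prob = c(0.5, 0.25, 0.25))
      if (any(gt != "hom_ref")) return(stats::setNames(gt, lineage_levels))
    }
  }
  var_rows <- list()
  add_variant <- function(chrom, pos, ref, alt, gts) {
    per_sample <- if (all(tips %in% names(gts))) gts[tips] else gts[lineage]
    row <- c(list(chrom = chrom, pos = as.integer(pos),
                  ref = unname(ref), alt = unname(alt)),
             as.list(unname(per_sample)))
    names(row)[-(1:4)] <- tips
    var_rows[[length(var_rows) + 1L]] <<- tibble::as_tibble(row)
  }
  base_at <- function(cre_i, off) {
    substr(cre_seqs[cre_i], off + 1L, off + 1L)
  }
  in_tfbs <- function(cre_name, off) {
    any(tfbs$element == cre_name &
          tfbs$start - cres$start[match(cre_name, cres$name)] <= off &
          tfbs$end - cres$start[match(cre_name, cres$name)] > off)
  }
  # neutral SNPs outside any planted TFBS, one per position
  for (i in seq_len(nrow(cres))) {
    len <- cres$end[i] - cres$start[i]
    placed <- 0L
    tries <- 0L
    taken <- integer(0)
    while (placed < config$snps_per_cre && tries < 200L) {
      tries <- tries + 1L
      off <- sample.int(len, 1L) - 1L
      if (off %in% taken || in_tfbs(cres$name[i], off)) next
      ref <- base_at(i, off)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      add_variant(cres$chrom[i], cres$start[i] + off + 1L, ref, alt,
                  draw_lineage_gt())
      taken <- c(taken, off)
      placed <- placed + 1L
    }
  }
  # motif-breaking variants: consensus base -> worst base inside a planted
  # TFBS; carriers are the individuals of one non-focal lineage
  enh_tfbs <- tfbs[tfbs$element_class == "enhancer", , drop = FALSE]
  n_break <- config$n_breaking_snp + config$n_breaking_indel
  chosen <- enh_tfbs[sample(nrow(enh_tfbs), n_break), , drop = FALSE]
  breaking <- list()
  carrier_sizes <- c(1L, 1L, 2L, 3L, 3L, 6L, 9L, 11L)
  for (b in seq_len(nrow(chosen))) {
    site <- chosen[b, ]
    # carrier sets of varied size, from private alleles to nearly fixed
    # ones, so presence/absence sharing spans the full spectrum
    carriers <- sample(tips, sample(carrier_sizes, 1L))
    gts <- stats::setNames(rep("hom_ref", n_s), tips)
    gts[carriers] <- "hom_alt"
    cre_i <- match(site$element, cres$name)
    site_off <- site$start - cres$start[cre_i]
    if (b <= config$n_breaking_snp) {
      m <- motifs[[site$motif_id]]
      col <- 3L                      # a core column of the planted site
      off <- site_off + (if (site$strand == "+") col - 1L
                         else (ncol(m$pfm) - col))
      ref <- base_at(cre_i, off)
      worst <- c("A", "C", "G", "T")[which.min(m$pfm[, col])]
      alt <- if (site$strand == "+") worst else revcomp(worst)
      if (alt == ref) alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      pos <- cres$start[cre_i] + off + 1L
    } else {
      off <- site_off + 1L           # 2-bp deletion inside the site
      ref <- substr(cre_seqs[cre_i], off + 1L, off + 3L)
      alt <- substr(ref, 1L, 1L)
      pos <- cres$start[cre_i] + off + 1L
    }
    add_variant(site$chrom, pos, ref, alt, gts)
    breaking[[b]] <- tibble::tibble(
      tfbs = site$name, motif_id = site$motif_id, chrom = site$chrom,
      pos = as.integer(pos), ref = unname(ref), alt = unname(alt),
      carriers = paste(sort(carriers), collapse = ","))
  }
  variants <- dplyr::bind_rows(var_rows) |>
    dplyr::arrange(.data$chrom, .data$pos)
  motif_breaking <- dplyr::bind_rows(breaking)

  # -- accessibility -------------------------------------------------------
  planted_genes <- unique(cres$gene[cres$element_class == "enhancer"])
  planted_genes <- planted_genes[seq_len(config$n_planted)]
  drivers <- list()
  peak_scores <- matrix(NA_real_, nrow(peaks), n_s,
                        dimnames = list(peaks$name, tips))
  chol_factor <- bm_chol(tree)
  # accessibility is a heritable quantitative trait: per-peak level,
  # Brownian variation on the tree, and a small measurement noise
  for (i in seq_len(nrow(peaks))) {
    peak_scores[i, ] <- exp(stats::rnorm(1, config$accessibility_log_mean,
                                         config$accessibility_peak_sd) +
                              sim_bm(tree, config$accessibility_bm_rate,
                                     chol_factor)[tips] +
                              stats::rnorm(n_s, 0,
                                           config$accessibility_noise_sd))
  }
  for (g in planted_genes) {
    drv <- exp(config$accessibility_log_mean) +
      config$driver_score_sd * sim_bm(tree, config$driver_bm_rate,
                                      chol_factor)
    drivers[[g]] <- drv
    enh_name <- peaks$name[peaks$gene == g & peaks$element_class ==
                             "enhancer"]
    # the planted enhancer's score IS the gene's latent driver (on the
    # signal scale), so accessibility linearly tracks the expression
    # log-mean it drives
    peak_scores[enh_name, ] <- drv
  }

  # -- footprints ----------------------------------------------------------
  bound_true <- matrix(0L, nrow(tfbs), n_s,
                       dimnames = list(tfbs$name, tips))
  for (i in seq_len(nrow(tfbs))) {
    lin_bound <- stats::rbinom(length(lineage_levels), 1L,
                               config$footprint_bound_prob)
    names(lin_bound) <- lineage_levels
    flips <- stats::rbinom(n_s, 1L, config$footprint_flip_prob)
    bound_true[i, ] <- abs(lin_bound[lineage] - flips)
  }
  for (b in seq_len(nrow(motif_breaking))) {
    site <- motif_breaking$tfbs[b]
    carr <- strsplit(motif_breaking$carriers[b], ",")[[1]]
    bound_true[site, ] <- 1L
    bound_true[site, carr] <- 0L
  }
  mu <- ifelse(bound_true == 1L, config$footprint_mu_bound,
               config$footprint_mu_unbound)
  footprint_scores <- matrix(
    stats::rnorm(length(mu), mu, config$footprint_sd),
    nrow(tfbs), n_s, dimnames = dimnames(bound_true))

  # -- deletion + depth ----------------------------------------------------
  del_gene <- venom_gene_names(config$n_venom)[config$deletion_gene_index]
  del_enh <- peaks[peaks$gene == del_gene &
                     peaks$element_class == "enhancer", ]
  deletion <- tibble::tibble(
    chrom = del_enh$chrom[1],
    start = del_enh$start[1] - config$deletion_pad,
    end = del_enh$end[1] + config$deletion_pad,
    name = paste0(del_gene, "_del"), element_class = "other",
    gene = del_gene)
  focal <- tips[lineage == "lin1"]
  del_samples <- tibble::tibble(sample = focal[1:2],
                                zygosity = c("hom_del", "het_del"))
  flank_lo <- max(0L, deletion$start - config$depth_flank)
  flank_hi <- deletion$end + config$depth_flank
  starts <- seq(flank_lo, flank_hi - config$depth_window,
                by = config$depth_window)
  windows <- tibble::tibble(chrom = deletion$chrom, start = starts,
                            end = starts + config$depth_window,
                            name = paste0(deletion$chrom, ":", starts, "-",
                                          starts + config$depth_window),
                            element_class = "other", gene = NA_character_)
  depth <- matrix(stats::rpois(nrow(windows) * n_s, config$depth_mean),
                  nrow(windows), n_s,
                  dimnames = list(windows$name, tips))
  in_del <- windows$start >= deletion$start & windows$end <= deletion$end
  for (k in seq_len(nrow(del_samples))) {
    f <- if (del_samples$zygosity[k] == "hom_del") 0.02 else 0.5
    depth[in_del, del_samples$sample[k]] <-
      stats::rpois(sum(in_del), config$depth_mean * f)
  }

  list(peaks = peaks, peak_scores = peak_scores, motifs = unname(motifs),
       tfbs = tfbs, footprint_scores = footprint_scores,
       bound_true = bound_true, variants = variants, cre_seqs = cre_seqs,
       depth = list(windows = windows, depth = depth),
       drivers = drivers, planted_genes = planted_genes,
       motif_breaking = motif_breaking,
       deletion = list(interval = deletion, samples = del_samples))
}

#' Simulate venom protein abundances from mRNA
#'
#' protein = mRNA x gene-specific factor x log-normal noise. With
#' `factor_sd = 0` and `noise_sd = 0` protein is exactly proportional to
#' mRNA per sample, so the CLR-transformed matrices coincide.
#'
#' @param mrna Numeric matrix (venom genes x samples), e.g. combined counts.
#' @param factor_sd Log-sd of the per-gene factor.
#' @param noise_sd Log-sd of the per-observation noise.
#' @param seed Integer seed.
#' @return Numeric matrix, same shape as `mrna`.
#' @export
simulate_protein <- function(mrna, factor_sd = 0.3, noise_sd = 0.5,
                             seed = 1) {
  set.seed(seed)
  fac <- exp(stats::rnorm(nrow(mrna), 0, factor_sd))
  noise <- matrix(exp(stats::rnorm(length(mrna), 0, noise_sd)),
                  nrow(mrna), ncol(mrna))
  out <- mrna * fac * noise
  dimnames(out) <- dimnames(mrna)
  out
}

#' Generate the full synthetic input bundle
#'
#' Draws the tree, the regulatory layers, the expression counts (with the
#' planted enhancer-accessibility drivers feeding the designated genes' log
#' means), and the protein abundances, and returns them together with the
#' ground truth. The same seed and configuration always produce an
#' identical bundle.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Integer seed.
#' @return A list of class `venomreg_bundle` with elements tree, meta,
#'   counts, gene_classes, peaks, peak_scores, motifs, tfbs,
#'   footprint_scores, variants, cre_seqs, depth, protein and `truth`.
#' @export
simulate_bundle <- function(config = default_config(), seed = 1) {
  tree <- simulate_tree(config$n_lineages, config$samples_per_lineage,
                        seed = seed)
  annotation <- default_cre_annotation(config)
  layers <- simulate_regulatory_layers(tree, annotation, config,
                                       seed = seed + 1L)
  venom <- venom_gene_names(config$n_venom)
  nvp <- nvp_gene_names(config$n_nvp)
  tfs <- config$tf_names
  background <- paste0("bg", seq_len(config$n_background))
  gene_names <- c(venom, nvp, tfs, background)
  gene_classes <- tibble::tibble(
    gene = gene_names,
    class = rep(c("venom", "nvp", "tf", "background"),
                c(length(venom), length(nvp), length(tfs),
                  length(background))))
  rates <- rep(c(config$venom_bm_rate, config$nvp_bm_rate,
                 config$tf_bm_rate, config$background_bm_rate),
               c(length(venom), length(nvp), length(tfs),
                 length(background)))
  effects <- purrr::map(layers$planted_genes, function(g) {
    list(gene = g, driver = layers$drivers[[g]],
         beta = config$planted_beta)
  })
  # a shared trans latent couples two TFs with one non-enhancer-driven
  # venom gene, giving the correlation network a true positive
  set.seed(seed + 4L)
  trans <- sim_bm(tree, 1)
  trans_gene <- venom[min(20L, length(venom))]
  effects <- c(effects,
               list(list(gene = tfs[1], driver = trans, beta = 1.2),
                    list(gene = tfs[2], driver = trans, beta = 1.0),
                    list(gene = trans_gene, driver = trans, beta = 1.2)))
  expr <- simulate_expression(
    tree, length(gene_names), effects = effects,
    baseline_log_mean = config$baseline_log_mean, bm_rate = rates,
    dispersion = config$dispersion, seed = seed + 2L,
    gene_names = gene_names, gland_replicates = config$gland_replicates)
  combined <- if (config$gland_replicates) {
    combine_glands(expr$counts, expr$meta)
  } else expr$counts
  combined <- combined[, tree$tip.label, drop = FALSE]
  protein <- simulate_protein(combined[venom, , drop = FALSE],
                              factor_sd = config$protein_factor_sd,
                              noise_sd = config$protein_noise_sd,
                              seed = seed + 3L)
  truth <- list(
    seed = seed,
    planted_effects = tibble::tibble(
      gene = layers$planted_genes, feature_class = "cre_accessibility",
      effect_size = config$planted_beta),
    motif_breaking = layers$motif_breaking,
    deletion = layers$deletion,
    bound_true = layers$bound_true,
    drivers = layers$drivers,
    dispersion = config$dispersion,
    depth_mean = config$depth_mean)
  structure(list(tree = tree, meta = expr$meta, counts = expr$counts,
                 counts_combined = combined, latent = expr$latent,
                 gene_classes = gene_classes, peaks = layers$peaks,
                 peak_scores = layers$peak_scores, motifs = layers$motifs,
                 tfbs = layers$tfbs,
                 footprint_scores = layers$footprint_scores,
                 variants = layers$variants, cre_seqs = layers$cre_seqs,
                 depth = layers$depth, protein = protein,
                 tf_genes = tfs, venom_genes = venom, nvp_genes = nvp,
                 config = config, truth = truth),
            class = "venomreg_bundle")
}

#' @exportS3Method base::print
print.venomreg_bundle <- function(x, ...) {
  cat("<synthetic bundle: ", length(x$tree$tip.label), " individuals, ",
      nrow(x$counts), " genes, ", nrow(x$peaks), " peaks, ",
      nrow(x$tfbs), " TFBSs, ", nrow(x$variants), " variants; seed ",
      x$truth$seed, ">\n", sep = "")
  invisible(x)
}

#' Write a bundle to disk as plain-text files
#'
#' Emits counts.tsv, meta.tsv, peaks.bed, peak_scores.tsv, tfbs.bed,
#' footprint_scores.tsv, variants.vcf, cres.fa, motifs.jaspar, tree.nwk,
#' depth.tsv, protein.tsv and truth.json. Output is byte-deterministic for
#' a fixed bundle.
#'
#' @param bundle A `venomreg_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_counts_tsv(bundle$counts, p("counts.tsv"))
  readr::write_tsv(bundle$meta, p("meta.tsv"))
  write_bed(bundle$peaks, p("peaks.bed"))
  write_score_tsv(bundle$peak_scores, p("peak_scores.tsv"))
  writeLines(paste(bundle$tfbs$chrom, bundle$tfbs$start, bundle$tfbs$end,
                   bundle$tfbs$name, bundle$tfbs$motif_id,
                   bundle$tfbs$strand, bundle$tfbs$tf_name,
                   bundle$tfbs$element, bundle$tfbs$gene, sep = "\t"),
             p("tfbs.bed"))
  write_score_tsv(bundle$footprint_scores, p("footprint_scores.tsv"),
                  id_col = "tfbs")
  write_vcf_minimal(bundle$variants, p("variants.vcf"))
  write_fasta(bundle$cre_seqs, p("cres.fa"))
  write_jaspar_pfm(bundle$motifs, p("motifs.jaspar"))
  ape::write.tree(bundle$tree, p("tree.nwk"))
  write_depth_tsv(bundle$depth$windows, bundle$depth$depth, p("depth.tsv"))
  write_score_tsv(bundle$protein, p("protein.tsv"), id_col = "gene")
  truth <- bundle$truth
  truth$bound_true <- NULL
  truth$drivers <- NULL
  truth$deletion <- list(interval = as.list(truth$deletion$interval),
                         samples = truth$deletion$samples)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Simulate one gene's feature blocks and contrast regression
#'
#' A lightweight replicate of the per-gene modeling pipeline used for
#' calibration studies: feature blocks of realistic widths are drawn
#' (continuous blocks with Brownian lineage structure, binary footprint and
#' 0/1/2 genotype blocks with lineage structure), the response is Brownian
#' noise plus `beta` times the standardized enhancer-accessibility driver,
#' and the full contrast -> per-class PC1 -> regression path is run.
#'
#' @param tree Tree whose tips are the samples.
#' @param beta Planted effect size on the cre_accessibility class (0 =
#'   null gene).
#' @param bm_rate Brownian rate of the response noise.
#' @param block_widths Named integer vector of variables per class.
#' @param seed Integer seed.
#' @return A `venomreg_gene_model` tibble (see [fit_gene_model()]).
#' @export
simulate_gene_model_replicate <- function(
    tree, beta = 0, bm_rate = 0.25,
    block_widths = c(cre_accessibility = 2L, ctcf_accessibility = 1L,
                     denovo_accessibility = 3L, tf_footprints = 6L,
                     tf_expression = 8L, cre_genotype = 4L),
    seed = 1) {
  set.seed(seed)
  tips <- tree$tip.label
  n <- length(tips)
  lineage <- sub("_[0-9]+$", "", tips)
  lineage_levels <- unique(lineage)
  chol_factor <- bm_chol(tree)
  blocks <- list()
  latents <- list()
  for (cl in names(block_widths)) {
    w <- block_widths[[cl]]
    b <- matrix(NA_real_, n, w, dimnames = list(tips, paste0(cl, seq_len(w))))
    # continuous feature classes share a per-class latent axis (the
    # within-class correlation that makes the PC1 reduction meaningful),
    # each variable adding its own Brownian + measurement noise
    latents[[cl]] <- sim_bm(tree, 1, chol_factor)
    for (j in seq_len(w)) {
      if (cl %in% c("tf_footprints")) {
        lv <- stats::rbinom(length(lineage_levels), 1L, 0.5)
        names(lv) <- lineage_levels
        b[, j] <- lv[lineage]
      } else if (cl == "cre_genotype") {
        lv <- sample(0:2, length(lineage_levels), replace = TRUE)
        names(lv) <- lineage_levels
        b[, j] <- lv[lineage]
      } else {
        b[, j] <- latents[[cl]] + sim_bm(tree, 0.25, chol_factor) +
          stats::rnorm(n, 0, 0.1)
      }
    }
    blocks[[cl]] <- b
  }
  driver <- latents$cre_accessibility
  response <- sim_bm(tree, bm_rate, chol_factor)
  if (beta != 0 && stats::sd(driver) > 0) {
    response <- response +
      beta * (driver - mean(driver)) / stats::sd(driver)
  }
  all_cols <- cbind(.response = response, do.call(cbind, blocks))
  col_class <- c(".response",
                 rep(names(block_widths), times = block_widths))
  keep <- c(TRUE, apply(all_cols[, -1, drop = FALSE], 2L,
                        function(x) stats::var(x) > 0))
  all_cols <- all_cols[, keep, drop = FALSE]
  col_class <- col_class[keep]
  contrasts <- pic_contrasts(tree, all_cols)
  predictors <- list()
  var_exp <- numeric(0)
  dropped <- character(0)
  for (cl in names(block_widths)) {
    cols <- which(col_class == cl)
    if (!length(cols)) {
      dropped[cl] <- "dropped_zero_variance"
      next
    }
    pc <- class_pca_pc1(contrasts[, cols, drop = FALSE])
    predictors[[cl]] <- pc$scores
    var_exp[cl] <- pc$var_explained
  }
  fit_gene_model(contrasts[, 1], predictors, gene = "sim",
                 var_explained = var_exp, dropped = dropped)
}
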