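# Variant projection onto cis-regulatory element sequences, nucleotide
# diversity, motif scanning on reference vs alternate alleles, TFBS gain/loss
# classification and the TFBS sharing spectrum.

DNA_BASES <- c("A", "C", "G", "T")

seq_to_int <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(DNA_BASES, "N"))
  if (length(bad)) stop("sequence contains non-ACGTN characters: ",
                        paste(bad, collapse = ","))
  match(chars, DNA_BASES)   # N -> NA
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Project a sample's variants onto a CRE reference sequence
#'
#' Applies the sample's genotyped variants inside a cis-regulatory element
#' to the element's reference sequence. Homozygous-alternate genotypes
#' substitute the alternate allele; heterozygotes substitute the alternate
#' allele too by default (`het = "alt"`), which maximizes sensitivity for
#' binding-site change detection — pass `het = "ref"` for the conservative
#' projection. Missing genotypes leave the reference unchanged. Indels
#' change the sequence length and the coordinates of later variants are
#' shifted accordingly.
#'
#' @param cre_sequence Reference DNA string of the element.
#' @param variants Variant tibble (see [read_vcf_minimal()]).
#' @param sample Sample id (must be a genotype column of `variants`).
#' @param cre One-row interval tibble locating the element (BED coordinates).
#' @param het Allele projected at heterozygous sites, `"alt"` or `"ref"`.
#' @return The projected DNA string for that sample.
#' @export
project_consensus <- function(cre_sequence, variants, sample, cre,
                              het = c("alt", "ref")) {
  het <- match.arg(het)
  if (!sample %in% colnames(variants)) {
    stop("no genotypes for sample '", sample, "'")
  }
  if (nrow(variants) == 0L) return(cre_sequence)
  inside <- variants$chrom == cre$chrom[1] &
    variants$pos - 1L >= cre$start[1] &
    variants$pos - 1L + nchar(variants$ref) <= cre$end[1]
  v <- variants[inside, , drop = FALSE]
  gt <- v[[sample]]
  apply_alt <- gt == "hom_alt" | (gt == "het" & het == "alt")
  v <- v[apply_alt, , drop = FALSE]
  if (nrow(v) == 0L) return(cre_sequence)
  v <- v[order(v$pos), , drop = FALSE]
  spans_end <- v$pos + nchar(v$ref) - 1L
  if (nrow(v) > 1L && any(v$pos[-1L] <= spans_end[-nrow(v)])) {
    bad <- which(v$pos[-1L] <= spans_end[-nrow(v)])
    stop("overlapping variants applied to the same haplotype at positions ",
         paste(v$pos[c(bad, bad + 1L)], collapse = ", "))
  }
  out <- cre_sequence
  shift <- 0L
  for (i in seq_len(nrow(v))) {
    off <- v$pos[i] - 1L - cre$start[1] + shift   # 0-based within sequence
    ref_len <- nchar(v$ref[i])
    found <- substr(out, off + 1L, off + ref_len)
    if (found != v$ref[i]) {
      stop("reference allele mismatch at ", v$chrom[i], ":", v$pos[i],
           ": expected '", v$ref[i], "', sequence has '", found, "'")
    }
    out <- paste0(substr(out, 1L, off), v$alt[i],
                  substr(out, off + ref_len + 1L, nchar(out)))
    shift <- shift + nchar(v$alt[i]) - ref_len
  }
  out
}

#' Build a consensus set for one element
#'
#' @param cre One-row interval tibble.
#' @param sequences Named character vector of per-sample projected sequences;
#'   must include an entry named `"reference"`.
#' @return A list of class `venomreg_consensus`.
#' @export
consensus_set <- function(cre, sequences) {
  if (!"reference" %in% names(sequences)) {
    stop("consensus set must include the reference sequence")
  }
  structure(list(cre = cre, sequences = sequences),
            class = "venomreg_consensus")
}

# Count mismatches between two sequences over columns where both carry a
# concrete base; sequences of unequal length are globally aligned first.
pair_diff <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -1, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 1)
    a <- as.character(Biostrings::alignedPattern(al))
    b <- as.character(Biostrings::alignedSubject(al))
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  c(d = sum(ca[ok] != cb[ok]), L = sum(ok))
}

#' Nucleotide diversity of a consensus set
#'
#' pi = mean over sequence pairs of d_ij / L_ij, where d_ij counts mismatched
#' columns and L_ij the columns where both sequences carry a concrete
#' (non-gap, non-N) base. Each individual contributes a single projected
#' haplotype, so the estimate is downward-biased relative to a 2n-haplotype
#' estimator; see the package vignette. Pairs with no comparable site are
#' excluded with a warning.
#'
#' @param cons A `venomreg_consensus` from [consensus_set()].
#' @param include_reference Count the reference as one of the sequences
#'   (default FALSE: diversity across sampled individuals only).
#' @return Tibble with cre, n_sequences, pi, n_pairs, n_pairs_excluded.
#' @export
nucleotide_diversity <- function(cons, include_reference = FALSE) {
  seqs <- cons$sequences
  if (!include_reference) {
    seqs <- seqs[names(seqs) != "reference"]
  }
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences for diversity")
  pairs <- utils::combn(n, 2L)
  ratios <- rep(NA_real_, ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    dl <- pair_diff(seqs[[pairs[1, k]]], seqs[[pairs[2, k]]])
    if (dl[["L"]] > 0) ratios[k] <- dl[["d"]] / dl[["L"]]
  }
  if (anyNA(ratios)) {
    if (all(is.na(ratios))) stop("all sequence pairs lack comparable sites")
    warning(sum(is.na(ratios)), " pair(s) with no comparable sites excluded")
  }
  tibble::tibble(cre = cons$cre$name[1],
                 n_sequences = n,
                 pi = mean(ratios, na.rm = TRUE),
                 n_pairs = sum(!is.na(ratios)),
                 n_pairs_excluded = sum(is.na(ratios)))
}

# Per-position log-odds matrix of a motif under its background, with a
# per-column pseudo-count split by background frequency.
motif_logodds <- function(motif, pseudocount = 0.8) {
  pfm <- motif$pfm
  bg <- motif$background[DNA_BASES]
  colsum <- colSums(pfm)
  prob <- sweep(pfm + pseudocount * bg, 2L, colsum + pseudocount, "/")
  log(sweep(prob, 1L, bg, "/"))
}

scan_one_strand <- function(idx, lo, motif_id, tf_name, strand, keep_at,
                            score_min, score_max) {
  L <- ncol(lo)
  n_win <- length(idx) - L + 1L
  if (n_win < 1L) return(NULL)
  hits <- vector("list", 0L)
  denom <- score_max - score_min
  cols <- seq_len(L)
  for (p in seq_len(n_win)) {
    b <- idx[p:(p + L - 1L)]
    if (anyNA(b)) next            # window contains N
    score <- sum(lo[cbind(b, cols)])
    rel <- (score - score_min) / denom
    if (rel >= keep_at) {
      hits[[length(hits) + 1L]] <- c(p = p, score = score, rel = rel)
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  tibble::tibble(motif_id = motif_id, tf_name = tf_name,
                 window = as.integer(unname(h[, "p"])), strand = strand,
                 score = unname(h[, "score"]),
                 rel_score = unname(h[, "rel"]))
}

#' Scan a sequence for motif hits on both strands
#'
#' Windows are scored with the motif's log-odds matrix (per-column
#' pseudo-count, uniform background by default) and retained when the
#' max-normalized relative score, (score - min) / (max - min), is at least
#' 1 - `similarity_threshold` (0.85 at the default threshold of 0.15).
#' Windows containing N are skipped; motifs whose log-odds matrix is flat
#' (max = min) are skipped with a warning. Overlapping hits of the same
#' motif are all reported.
#'
#' @param sequence DNA string over A,C,G,T,N.
#' @param motifs List of motif objects (see [read_jaspar_pfm()]).
#' @param similarity_threshold Maximal allowed relative-score deficit.
#' @param pseudocount Per-column pseudo-count added to the PFM.
#' @return Tibble with motif_id, tf_name, offset (0-based window start on
#'   the input sequence), strand, score, rel_score.
#' @export
scan_motifs <- function(sequence, motifs, similarity_threshold = 0.15,
                        pseudocount = 0.8) {
  idx_f <- seq_to_int(sequence)
  n <- length(idx_f)
  idx_r <- seq_to_int(revcomp(sequence))
  keep_at <- 1 - similarity_threshold
  out <- list()
  for (m in motifs) {
    lo <- motif_logodds(m, pseudocount)
    L <- ncol(lo)
    if (n < L) next
    smin <- sum(apply(lo, 2L, min))
    smax <- sum(apply(lo, 2L, max))
    if (smax - smin < .Machine$double.eps) {
      warning("motif '", m$motif_id,
              "' has a flat score range and was skipped")
      next
    }
    fwd <- scan_one_strand(idx_f, lo, m$motif_id, m$tf_name, "+",
                           keep_at, smin, smax)
    rev <- scan_one_strand(idx_r, lo, m$motif_id, m$tf_name, "-",
                           keep_at, smin, smax)
    if (!is.null(fwd)) {
      fwd$offset <- fwd$window - 1L
      out[[length(out) + 1L]] <- fwd
    }
    if (!is.null(rev)) {
      # window p on the reverse complement starts at original 0-based
      # offset n - p - L + 1 (1-based window p covers rc[p .. p+L-1])
      rev$offset <- n - rev$window - L + 1L
      out[[length(out) + 1L]] <- rev
    }
  }
  if (!length(out)) {
    return(tibble::tibble(motif_id = character(), tf_name = character(),
                          offset = integer(), strand = character(),
                          score = numeric(), rel_score = numeric()))
  }
  dplyr::bind_rows(out) |>
    dplyr::select("motif_id", "tf_name", "offset", "strand",
                  "score", "rel_score") |>
    dplyr::arrange(.data$motif_id, .data$offset, .data$strand)
}

# Substitute one variant's alternate allele into a reference sequence
# fragment whose first base is at 0-based element offset `frag_off`.
apply_variant <- function(fragment, frag_off, var_off, ref, alt) {
  pos <- var_off - frag_off          # 0-based within the fragment
  found <- substr(fragment, pos + 1L, pos + nchar(ref))
  if (found != ref) {
    stop("reference allele mismatch in scan window: expected '", ref,
         "', found '", found, "'")
  }
  paste0(substr(fragment, 1L, pos), alt,
         substr(fragment, pos + nchar(ref) + 1L, nchar(fragment)))
}

#' Classify TFBS gains and losses induced by variants
#'
#' For each variant inside the element, a window extending
#' (max motif length - 1) bases either side of the variant span is scanned
#' on the reference-allele and the alternate-allele sequence. Per motif, a
#' hit present only on the reference allele is a loss, only on the
#' alternate a gain; hits present on both alleles whose best score moved by
#' at least `score_delta` are reported as retained with a changed score.
#'
#' @param cre_sequence Reference sequence of the element.
#' @param variants Variant tibble restricted to (or overlapping) the element.
#' @param motifs List of motif objects.
#' @param cre One-row interval tibble locating the element.
#' @param similarity_threshold Passed to [scan_motifs()].
#' @param score_delta Minimal best-score change for
#'   `retained_changed_score`.
#' @return Tibble with variant fields, motif_id, tf_name, change
#'   (`gained`/`lost`/`retained_changed_score`), n_hits_ref, n_hits_alt and
#'   `carriers` (comma-separated samples carrying the alternate allele).
#' @export
classify_tfbs_changes <- function(cre_sequence, variants, motifs, cre,
                                  similarity_threshold = 0.15,
                                  score_delta = 1e-6) {
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          motif_id = character(), tf_name = character(),
                          change = character(), n_hits_ref = integer(),
                          n_hits_alt = integer(), carriers = character())
  if (nrow(variants) == 0L || length(motifs) == 0L) return(empty)
  max_l <- max(vapply(motifs, function(m) ncol(m$pfm), integer(1)))
  samples <- variant_samples(variants)
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v_off <- variants$pos[i] - 1L - cre$start[1]
    if (v_off < 0L || v_off + nchar(variants$ref[i]) >
        nchar(cre_sequence)) next
    lo <- max(0L, v_off - (max_l - 1L))
    hi <- min(nchar(cre_sequence),
              v_off + nchar(variants$ref[i]) + (max_l - 1L))
    ref_win <- substr(cre_sequence, lo + 1L, hi)
    alt_win <- apply_variant(ref_win, lo, v_off,
                             variants$ref[i], variants$alt[i])
    hits_ref <- scan_motifs(ref_win, motifs, similarity_threshold)
    hits_alt <- scan_motifs(alt_win, motifs, similarity_threshold)
    gt <- unlist(variants[i, samples])
    carriers <- paste(samples[gt %in% c("het", "hom_alt")], collapse = ",")
    for (m in motifs) {
      hr <- hits_ref[hits_ref$motif_id == m$motif_id, , drop = FALSE]
      ha <- hits_alt[hits_alt$motif_id == m$motif_id, , drop = FALSE]
      change <- if (nrow(hr) > 0L && nrow(ha) == 0L) "lost"
        else if (nrow(hr) == 0L && nrow(ha) > 0L) "gained"
        else if (nrow(hr) > 0L && nrow(ha) > 0L &&
                 abs(max(hr$score) - max(ha$score)) >= score_delta)
          "retained_changed_score"
        else NA_character_
      if (is.na(change)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = variants$chrom[i], pos = variants$pos[i],
        ref = variants$ref[i], alt = variants$alt[i],
        motif_id = m$motif_id, tf_name = m$tf_name, change = change,
        n_hits_ref = nrow(hr), n_hits_alt = nrow(ha),
        carriers = carriers)
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Per-sample TFBS presence implied by gain/loss calls
#'
#' Expands a table of variant-induced TFBS changes (see
#' [classify_tfbs_changes()]) into a binary presence matrix: for a lost
#' site, presence in the samples not carrying the alternate allele; for a
#' gained site, presence in the carriers. Score-only changes are skipped
#' (the site is present in everyone). The result feeds
#' [tfbs_sharing_spectrum()].
#'
#' @param changes Tibble from [classify_tfbs_changes()] (rows may come from
#'   several elements).
#' @param samples Character vector of all sample ids.
#' @return Binary matrix, one row per gained/lost change, samples as
#'   columns.
#' @export
changes_presence <- function(changes, samples) {
  rows <- changes[changes$change %in% c("gained", "lost"), , drop = FALSE]
  out <- matrix(0L, nrow(rows), length(samples),
                dimnames = list(
                  paste0(rows$motif_id, "@", rows$chrom, ":", rows$pos),
                  samples))
  for (i in seq_len(nrow(rows))) {
    carr <- strsplit(rows$carriers[i], ",")[[1]]
    carr <- intersect(carr, samples)
    if (rows$change[i] == "gained") {
      out[i, carr] <- 1L
    } else {
      out[i, setdiff(samples, carr)] <- 1L
    }
  }
  out
}

#' TFBS sharing spectrum
#'
#' Histogram, in the style of a site frequency spectrum, of how many
#' individuals share each variable binding site. Sites present in no sample
#' or in every sample are not variable and are excluded.
#'
#' @param presence Binary matrix, TFBS x samples (1 = site present/bound).
#' @return A tibble of class `venomreg_spectrum` with columns n_shared
#'   (1 .. n_samples - 1), count and fraction; the fraction of variable
#'   sites unique to one individual is available via attribute
#'   `fraction_unique`.
#' @export
tfbs_sharing_spectrum <- function(presence) {
  if (!all(presence %in% c(0, 1))) stop("presence matrix must be binary")
  n <- ncol(presence)
  shared <- rowSums(presence)
  variable <- shared > 0 & shared < n
  counts <- tabulate(shared[variable], nbins = n - 1L)
  total <- sum(counts)
  out <- tibble::tibble(n_shared = seq_len(n - 1L), count = counts,
                        fraction = if (total > 0) counts / total else
                          rep(NA_real_, n - 1L))
  class(out) <- c("venomreg_spectrum", class(out))
  attr(out, "fraction_unique") <- if (total > 0) counts[1] / total else NA_real_
  attr(out, "n_variable") <- total
  out
}

#' Bar chart of the TFBS sharing spectrum
#' @param object A `venomreg_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venomreg_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$n_shared),
                                       y = .data$fraction)) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::labs(x = "individuals sharing the TFBS",
                  y = "fraction of variable TFBSs") +
    ggplot2::theme_minimal()
}
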