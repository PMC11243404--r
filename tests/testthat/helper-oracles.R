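# Independent oracles and shared fixtures for the suite.

# One default bundle shared across test files (generation is seeded, so
# regenerating would give the same object; caching just saves time).
.shared <- new.env(parent = emptyenv())

shared_bundle <- function() {
  if (is.null(.shared$bundle)) .shared$bundle <- simulate_bundle(seed = 101)
  .shared$bundle
}

shared_occupancy <- function() {
  if (is.null(.shared$occ)) {
    .shared$occ <- binarize_footprints(shared_bundle()$footprint_scores)
  }
  .shared$occ
}

write_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Brute-force nucleotide diversity over equal-length sequences: average
# pairwise mismatch fraction over columns where both bases are concrete.
brute_pi <- function(seqs) {
  n <- length(seqs)
  mats <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mats[[i]]; b <- mats[[j]]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      if (sum(ok) > 0) vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
    }
  }
  mean(vals)
}

# Naive per-window motif scan, written independently of the package scanner:
# explicit probability computation and window loops on both strands.
naive_scan <- function(sequence, motif, threshold = 0.15,
                       pseudocount = 0.8) {
  bases <- c("A", "C", "G", "T")
  bg <- motif$background[bases]
  pfm <- motif$pfm
  L <- ncol(pfm)
  w <- matrix(NA_real_, 4, L)
  for (k in seq_len(L)) {
    for (b in seq_len(4)) {
      p <- (pfm[b, k] + pseudocount * bg[b]) / (sum(pfm[, k]) + pseudocount)
      w[b, k] <- log(p / bg[b])
    }
  }
  smin <- sum(apply(w, 2, min)); smax <- sum(apply(w, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  scan_str <- function(chars, strand, to_offset) {
    for (p in seq_len(length(chars) - L + 1)) {
      win <- chars[p:(p + L - 1)]
      if (any(!win %in% bases)) next
      s <- 0
      for (k in seq_len(L)) s <- s + w[match(win[k], bases), k]
      rel <- (s - smin) / (smax - smin)
      if (rel >= 1 - threshold) {
        hits[[length(hits) + 1]] <<- data.frame(
          motif_id = motif$motif_id, offset = to_offset(p),
          strand = strand, score = s, rel_score = rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  scan_str(chars, "+", function(p) p - 1L)
  rc <- rev(unname(comp[chars]))
  rc[is.na(rc)] <- "N"
  scan_str(rc, "-", function(p) n - p - L + 1L)
  if (!length(hits)) {
    return(data.frame(motif_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      rel_score = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), ]
}

random_motif <- function(len = sample(4:10, 1)) {
  pfm <- matrix(stats::rpois(4 * len, 3) + stats::rbinom(4 * len, 1, 0.3) *
                  stats::rpois(4 * len, 10), 4, len)
  pfm[, colSums(pfm) == 0] <- 1
  venomreg:::new_motif(paste0("R", sample(1e6, 1)), "TFX", pfm)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# GLS quadratic form (x - mu_hat)' C^{-1} (x - mu_hat) via an independent
# Cholesky solve of the Brownian tip covariance.
gls_quadratic_form <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  R <- chol(C)
  z <- backsolve(R, x, transpose = TRUE)
  o <- backsolve(R, rep(1, length(x)), transpose = TRUE)
  mu <- sum(o * z) / sum(o * o)
  sum((z - mu * o)^2)
}
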