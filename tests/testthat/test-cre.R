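# Consensus projection, nucleotide diversity, motif scanning, TFBS changes.

one_cre <- function(len = 10L) {
  tibble::tibble(chrom = "chr1", start = 100L, end = 100L + len,
                 name = "cre1", element_class = "enhancer", gene = "g1")
}

variant_row <- function(pos, ref, alt, gt = "hom_alt") {
  tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt, s1 = gt)
}

test_that("consensus projection substitutes SNPs and applies indels", {
  cre <- one_cre()
  snp <- variant_row(106L, "C", "T")
  expect_equal(project_consensus("AAAAACAAAA", snp, "s1", cre),
               "AAAAATAAAA")
  del <- variant_row(103L, "ACT", "A")
  expect_equal(project_consensus("AAACTAAAAA", del, "s1", cre), "AAAAAAAA")
  ins <- variant_row(103L, "A", "AGG")
  expect_equal(project_consensus("AAACTAAAAA", ins, "s1", cre),
               "AAAGGCTAAAAA")
})

test_that("heterozygote policy, missing genotypes, coordinate shifts", {
  cre <- one_cre()
  het <- variant_row(106L, "C", "T", gt = "het")
  expect_equal(project_consensus("AAAAACAAAA", het, "s1", cre),
               "AAAAATAAAA")
  expect_equal(project_consensus("AAAAACAAAA", het, "s1", cre, het = "ref"),
               "AAAAACAAAA")
  miss <- variant_row(106L, "C", "T", gt = "missing")
  expect_equal(project_consensus("AAAAACAAAA", miss, "s1", cre),
               "AAAAACAAAA")
  # deletion before a SNP shifts the later substitution correctly
  both <- dplyr::bind_rows(variant_row(102L, "AA", "A"),
                           variant_row(106L, "C", "G"))
  expect_equal(project_consensus("AAAAACAAAA", both, "s1", cre),
               "AAAAGAAAA")
  # conflicting overlapping variants are rejected
  overlap <- dplyr::bind_rows(variant_row(103L, "ACT", "A"),
                              variant_row(104L, "C", "G"))
  expect_error(project_consensus("AAACTAAAAA", overlap, "s1", cre),
               "overlapping")
  # reference mismatch is caught
  wrong <- variant_row(106L, "G", "T")
  expect_error(project_consensus("AAAAACAAAA", wrong, "s1", cre),
               "mismatch")
})

test_that("projection round-trips the bundle's genotypes", {
  b <- shared_bundle()
  cres <- b$peaks[b$peaks$element_class %in% c("promoter", "enhancer"), ]
  snps <- b$variants[nchar(b$variants$ref) == 1 &
                       nchar(b$variants$alt) == 1, ]
  cre <- cres[cres$name == "SVSP1_prom", ]
  for (s in colnames(b$truth$bound_true)[1:3]) {
    proj <- project_consensus(b$cre_seqs[[cre$name]], snps, s, cre)
    ref <- b$cre_seqs[[cre$name]]
    diffs <- which(strsplit(proj, "")[[1]] != strsplit(ref, "")[[1]])
    inside <- snps[snps$pos - 1 >= cre$start & snps$pos - 1 < cre$end, ]
    applied <- inside$pos[inside[[s]] %in% c("het", "hom_alt")] - cre$start
    expect_setequal(diffs, applied)
  }
})

test_that("nucleotide diversity matches hand and brute-force values", {
  cre <- one_cre(4L)
  cs <- consensus_set(cre, c(reference = "AAAA", a = "AAAA", b = "AAAT",
                             c = "AATT"))
  res <- nucleotide_diversity(cs)
  expect_equal(res$pi, ((1 + 2 + 1) / 4) / 3, tolerance = 1e-12)

  same <- consensus_set(cre, c(reference = "ACGT", a = "ACGT", b = "ACGT"))
  expect_equal(nucleotide_diversity(same)$pi, 0)

  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    L <- sample(5:100, 1)
    seqs <- vapply(seq_len(n), function(k) random_seq(L), character(1))
    names(seqs) <- paste0("s", seq_len(n))
    cs <- consensus_set(one_cre(L), c(reference = random_seq(L), seqs))
    expect_equal(nucleotide_diversity(cs)$pi, brute_pi(seqs),
                 tolerance = 1e-12)
  }
})

test_that("N-only pairs are excluded from diversity with a warning", {
  cre <- one_cre(4L)
  cs <- consensus_set(cre, c(reference = "ACGT", a = "NNNN", b = "ACGT",
                             c = "ACGA"))
  expect_warning(res <- nucleotide_diversity(cs), "excluded")
  expect_equal(res$n_pairs, 1L)
  expect_equal(res$pi, 0.25)
  all_n <- consensus_set(cre, c(reference = "ACGT", a = "NNNN", b = "NNNN"))
  expect_error(suppressWarnings(nucleotide_diversity(all_n)), "comparable")
})

test_that("duplicating a majority-allele sequence never raises pi", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    L <- sample(6:30, 1)
    seqs <- vapply(seq_len(n), function(k) random_seq(L), character(1))
    names(seqs) <- paste0("s", seq_len(n))
    # majority consensus sequence
    mat <- do.call(rbind, strsplit(seqs, ""))
    maj <- apply(mat, 2, function(col)
      names(sort(table(col), decreasing = TRUE))[1])
    seqs2 <- c(seqs, sdup = paste(maj, collapse = ""))
    cs1 <- consensus_set(one_cre(L), c(reference = seqs[[1]], seqs))
    cs2 <- consensus_set(one_cre(L), c(reference = seqs[[1]], seqs2))
    expect_lte(nucleotide_diversity(cs2)$pi,
               nucleotide_diversity(cs1)$pi + 1e-12)
  }
})

test_that("scanner reports a maximal hit on the consensus sequence", {
  m <- venomreg:::make_consensus_motif("M1", "TF1", "ACGTAC")
  hits <- scan_motifs(paste0(strrep("T", 15), "ACGTAC", strrep("G", 15)),
                      list(m))
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$offset, 15L)
  expect_equal(plus$rel_score, 1)
})

test_that("scanner degenerate inputs are handled", {
  flat <- venomreg:::new_motif("F", "TFX", matrix(2, 4, 5))
  expect_warning(h <- scan_motifs(random_seq(30), list(flat)), "flat")
  expect_equal(nrow(h), 0L)
  expect_error(scan_motifs("ACGTX", list(random_motif(4))), "non-ACGTN")
  # windows containing N are skipped, others still scanned
  m <- venomreg:::make_consensus_motif("M1", "TF1", "ACGT")
  h <- scan_motifs("NNNNACGTNN", list(m))
  expect_true(all(h$offset == 4L))
})

test_that("scanner agrees with the naive oracle on random inputs", {
  set.seed(29)
  for (i in 1:40) {
    m <- random_motif()
    s <- random_seq(sample(30:120, 1))
    mine <- scan_motifs(s, list(m))
    mine <- mine[order(mine$offset, mine$strand), ]
    ref <- naive_scan(s, m)
    expect_equal(nrow(mine), nrow(ref))
    if (nrow(ref)) {
      expect_equal(mine$offset, ref$offset)
      expect_equal(mine$strand, ref$strand)
      expect_equal(mine$score, ref$score, tolerance = 1e-9)
      expect_equal(mine$rel_score, ref$rel_score, tolerance = 1e-9)
    }
  }
})

test_that("planted consensus motifs are found at the planted offset", {
  set.seed(37)
  for (i in 1:20) {
    m <- venomreg:::make_consensus_motif("P", "TFP", random_seq(8))
    cons <- paste(c("A", "C", "G", "T")[apply(m$pfm, 2, which.max)],
                  collapse = "")
    off <- sample(0:40, 1)
    strand <- sample(c("+", "-"), 1)
    planted <- if (strand == "+") cons else venomreg:::revcomp(cons)
    s <- random_seq(60)
    substr(s, off + 1, off + 8) <- planted
    hits <- scan_motifs(s, list(m))
    expect_true(any(hits$offset == off & hits$strand == strand))
  }
})

test_that("variant-induced TFBS loss, gain and symmetry", {
  m <- venomreg:::make_consensus_motif("M1", "TF1", "ACGTAC")
  cre <- one_cre(26L)
  seq_ref <- paste0(strrep("T", 10), "ACGTAC", strrep("T", 10))
  # SNP destroying the core consensus base
  lost_var <- variant_row(113L, "G", "A")
  ch <- classify_tfbs_changes(seq_ref, lost_var, list(m), cre)
  expect_equal(ch$change[ch$motif_id == "M1"], "lost")
  # swapping ref and alt alleles turns the loss into a gain
  seq_alt <- project_consensus(seq_ref, lost_var, "s1", cre)
  gain_var <- variant_row(113L, "A", "G")
  ch2 <- classify_tfbs_changes(seq_alt, gain_var, list(m), cre)
  expect_equal(ch2$change[ch2$motif_id == "M1"], "gained")
  # a variant far from any motif window reports nothing
  far <- variant_row(101L, "T", "C")
  seq_far <- paste0(strrep("T", 20), "CCCCCC")
  expect_equal(nrow(classify_tfbs_changes(seq_far, far, list(m), cre)), 0L)
})

test_that("an indel can create a consensus match", {
  m <- venomreg:::make_consensus_motif("M1", "TF1", "ACGTAC")
  cre <- one_cre(25L)
  # reference lacks the G needed for the core; a 1-bp insertion restores it
  seq_ref <- paste0(strrep("T", 10), "ACTAC", strrep("T", 10))
  ins <- variant_row(112L, "C", "CG")
  ch <- classify_tfbs_changes(seq_ref, ins, list(m), cre)
  expect_true("gained" %in% ch$change[ch$motif_id == "M1"])
  # full-sequence rescan confirms the hit exists only on the alternate
  alt_seq <- project_consensus(seq_ref, ins, "s1", cre)
  expect_equal(nrow(scan_motifs(seq_ref, list(m))), 0L)
  expect_gt(nrow(scan_motifs(alt_seq, list(m))), 0L)
})

test_that("sharing spectrum counts and excludes as specified", {
  presence <- rbind(a = c(1, 0, 0, 0), b = c(1, 0, 0, 0),
                    c = c(0, 1, 0, 0), d = c(1, 1, 1, 1),
                    e = c(0, 0, 0, 0), f = c(1, 1, 0, 0))
  colnames(presence) <- paste0("s", 1:4)
  sp <- tfbs_sharing_spectrum(presence)
  expect_equal(sp$count, c(3L, 1L, 0L))
  expect_equal(attr(sp, "n_variable"), 4L)
  expect_equal(attr(sp, "fraction_unique"), 0.75)
  expect_equal(sum(sp$count), 4L)
  expect_error(tfbs_sharing_spectrum(presence * 2), "binary")
})

test_that("change-derived presence feeds the spectrum", {
  ch <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L),
                       ref = c("A", "C"), alt = c("T", "G"),
                       motif_id = c("M1", "M2"), tf_name = c("x", "y"),
                       change = c("lost", "gained"),
                       n_hits_ref = c(1L, 0L), n_hits_alt = c(0L, 1L),
                       carriers = c("s1", "s2,s3"))
  pres <- changes_presence(ch, paste0("s", 1:4))
  expect_equal(unname(pres[1, ]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(pres[2, ]), c(0L, 1L, 1L, 0L))
})
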