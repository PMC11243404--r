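# Readers and writers for the plain-text formats the pipeline touches:
# TSV matrices, BED, VCF (GT only), JASPAR PFM text, FASTA, Newick.
# Assay data travel as named matrices (genes/intervals x samples); interval
# and variant annotations travel as tibbles.

CRE_CLASSES <- c("promoter", "enhancer", "ctcf", "denovo_peak", "other")
GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Read a gene-by-sample counts matrix from TSV
#'
#' The file must be tab-separated with gene identifiers in the first column
#' and a header row of sample identifiers. Every cell must be a non-negative
#' integer; fractional or negative values are rejected, as are duplicated
#' gene identifiers.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix with genes as rownames and samples as colnames.
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !nzchar(lines[1])) {
    stop("no header: '", path, "' is empty")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (length(samples) == 0L) stop("no sample columns in '", path, "'")
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  mat <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  for (i in seq_along(fields)) {
    vals <- fields[[i]][-1L]
    if (length(vals) != length(samples)) {
      stop("row '", genes[i], "' has ", length(vals), " values, expected ",
           length(samples))
    }
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | num != floor(num) | num < 0)
    if (length(bad)) {
      stop("non-integer count at row '", genes[i], "', column '",
           samples[bad[1]], "': '", vals[bad[1]], "'")
    }
    mat[i, ] <- as.integer(num)
  }
  mat
}

#' Write a counts matrix to TSV
#'
#' @param counts Integer matrix (genes x samples) with dimnames.
#' @param path Output path.
#' @param id_col Name of the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path, id_col = "gene") {
  write_matrix_tsv(counts, path, id_col)
}

write_matrix_tsv <- function(mat, path, id_col) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                           collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read an interval-by-sample score matrix from TSV
#'
#' First column holds interval names (matching a BED annotation), the header
#' row holds sample identifiers; all values must be finite numbers.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix, intervals x samples.
#' @export
read_score_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("score TSV needs an id column plus sample columns")
  ids <- df[[1]]
  mat <- vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(ids, colnames(df)[-1]))
  if (any(!is.finite(mat))) stop("non-finite score values in '", path, "'")
  mat
}

#' @rdname read_score_tsv
#' @param scores Numeric matrix with dimnames.
#' @param id_col Name of the identifier column.
#' @export
write_score_tsv <- function(scores, path, id_col = "interval") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(scores)), collapse = "\t"), con)
  body <- apply(scores, 1L, function(r)
    paste(formatC(r, digits = 10, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(scores), body, sep = "\t"), con)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED3+ is accepted: columns chrom, start, end, then optionally a name
#' (column 4) and an element class (column 5, when it is one of
#' `promoter`, `enhancer`, `ctcf`, `denovo_peak`, `other`). Coordinates are
#' kept 0-based half-open exactly as on disk. A strand column, if present,
#' is ignored (interval-level computations here are strand-free; motif
#' scanning handles strand itself). Element classes may instead be supplied
#' through `class_map`, a named character vector mapping interval names to
#' classes, which takes precedence over column 5.
#'
#' @param path Path to a BED file.
#' @param class_map Optional named character vector, interval name -> class.
#' @param gene_map Optional named character vector, interval name -> gene.
#' @return A tibble with columns chrom, start, end, name, element_class, gene.
#' @export
read_bed <- function(path, class_map = NULL, gene_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- if (length(fields)) min(lengths(fields)) else 0L
  if (length(fields) && n_col < 3L) stop("BED requires at least 3 columns")
  if (length(fields) && any(lengths(fields) >= 6L)) {
    message("BED strand column present; strand is ignored")
  }
  get_col <- function(k) vapply(fields, function(f)
    if (length(f) >= k) f[k] else NA_character_, character(1))
  chrom <- get_col(1L)
  start <- suppressWarnings(as.numeric(get_col(2L)))
  end <- suppressWarnings(as.numeric(get_col(3L)))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("non-numeric BED coordinates")
  }
  if (any(start < 0) || any(start >= end)) {
    stop("invalid BED interval(s): require 0 <= start < end")
  }
  name <- get_col(4L)
  name[is.na(name)] <- paste0(chrom[is.na(name)], ":", start[is.na(name)],
                              "-", end[is.na(name)])
  cls <- get_col(5L)
  cls[!cls %in% CRE_CLASSES] <- NA_character_
  if (!is.null(class_map)) {
    mapped <- unname(class_map[name])
    cls <- ifelse(is.na(mapped), cls, mapped)
  }
  cls[is.na(cls)] <- "other"
  if (!all(cls %in% CRE_CLASSES)) {
    stop("unknown element class(es): ",
         paste(setdiff(unique(cls), CRE_CLASSES), collapse = ", "))
  }
  gene <- if (is.null(gene_map)) NA_character_ else unname(gene_map[name])
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), name = name,
                 element_class = cls, gene = gene)
}

#' Write intervals to BED
#'
#' Emits BED5 (chrom, start, end, name, element_class).
#'
#' @param intervals Interval tibble as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  writeLines(paste(intervals$chrom, intervals$start, intervals$end,
                   intervals$name, intervals$element_class, sep = "\t"),
             path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file with a GT entry in FORMAT. Multiallelic records are
#' split into one row per alternate allele; for a split record, genotypes
#' referring to the other alternate allele are coded from the perspective of
#' the retained allele (an allele not matching ref or the retained alt counts
#' as ref-like, so 1/2 splits to het + het). Phased (`|`) and unphased (`/`)
#' separators are both accepted; `.` haplotypes give `missing`.
#'
#' @param path Path to a VCF file (plain text or bgzip).
#' @param region Optional one-row interval tibble; only variants whose
#'   1-based position lies inside the 0-based half-open interval are kept.
#' @return A tibble with columns chrom, pos (1-based), ref, alt, followed by
#'   one character column per sample with values `hom_ref`, `het`, `hom_alt`
#'   or `missing`.
#' @export
read_vcf_minimal <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2L) {
    stop("VCF has no sample columns")
  }
  samples <- colnames(v@gt)[-1L]
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (nrow(fix) == 0L) {
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character())
    for (s in samples) out[[s]] <- character()
    return(out)
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt_raw[i, , drop = TRUE]
    for (ai in seq_along(alts)) {
      codes <- vapply(gts, parse_gt, character(1), alt_index = ai)
      names(codes) <- samples
      rows[[length(rows) + 1L]] <- c(
        list(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
             ref = fix$REF[i], alt = alts[ai]),
        as.list(codes))
    }
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (!is.null(region)) {
    keep <- out$chrom == region$chrom[1] &
      out$pos - 1L >= region$start[1] & out$pos - 1L < region$end[1]
    out <- out[keep, , drop = FALSE]
  }
  out
}

# One GT string -> genotype code relative to alternate allele `alt_index`.
parse_gt <- function(gt, alt_index) {
  if (is.na(gt) || gt == ".") return("missing")
  gt <- strsplit(gt, ":", fixed = TRUE)[[1]][1]
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) == 0L || any(!grepl("^[0-9.]+$", alleles))) {
    warning("malformed GT '", gt, "' treated as missing")
    return("missing")
  }
  if (any(alleles == ".")) return("missing")
  n_alt <- sum(alleles == as.character(alt_index))
  c("hom_ref", "het", "hom_alt")[pmin(n_alt, 2L) + 1L]
}

#' Sample identifiers carried by a variant tibble
#' @param variants Tibble from [read_vcf_minimal()].
#' @return Character vector of sample ids.
#' @export
variant_samples <- function(variants) {
  setdiff(colnames(variants), c("chrom", "pos", "ref", "alt"))
}

#' BED-convention interval spanned by each variant
#'
#' Converts 1-based variant positions to 0-based half-open intervals covering
#' the reference allele: start = pos - 1, end = pos - 1 + nchar(ref).
#'
#' @param variants Tibble from [read_vcf_minimal()].
#' @return Interval tibble (chrom, start, end, name, element_class, gene).
#' @export
variant_interval <- function(variants) {
  tibble::tibble(chrom = variants$chrom,
                 start = variants$pos - 1L,
                 end = variants$pos - 1L + nchar(variants$ref),
                 name = paste0(variants$chrom, ":", variants$pos, "_",
                               variants$ref, ">", variants$alt),
                 element_class = "other", gene = NA_character_)
}

#' Write a variant tibble as a minimal plain-text VCF
#'
#' @param variants Tibble as returned by [read_vcf_minimal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(variants, path) {
  samples <- variant_samples(variants)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  code2gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  for (i in seq_len(nrow(variants))) {
    gts <- code2gt[unlist(variants[i, samples])]
    writeLines(paste(c(variants$chrom[i], variants$pos[i], ".",
                       variants$ref[i], variants$alt[i], ".", "PASS", ".",
                       "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read motifs from JASPAR PFM text
#'
#' Accepts the JASPAR 4-row text format: a `>motif_id tf_name` header line
#' followed by rows `A [ 1 2 3 ]` (brackets optional) for A, C, G, T. Counts
#' must be non-negative, rows equal length, and motif length at least 4.
#' The background is set uniform (0.25 per base).
#'
#' @param path Path to a JASPAR-format text file.
#' @return A list of motif objects (fields motif_id, tf_name, pfm, background).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) stop("no motif headers ('>') found in '", path, "'")
  bounds <- c(starts, length(lines) + 1L)
  motifs <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    block <- lines[starts[m]:(bounds[m + 1L] - 1L)]
    header <- strsplit(sub("^>", "", block[1]), "[ \t]+")[[1]]
    motif_id <- header[1]
    tf_name <- if (length(header) > 1L) header[2] else header[1]
    rows <- block[-1]
    bases <- toupper(substr(rows, 1, 1))
    if (!setequal(bases, c("A", "C", "G", "T")) || length(rows) != 4L) {
      stop("motif '", motif_id, "': need exactly one row per base A,C,G,T")
    }
    counts <- lapply(rows, function(r) {
      nums <- regmatches(r, gregexpr("-?[0-9.]+", r))[[1]]
      as.numeric(nums)
    })
    names(counts) <- bases
    lens <- lengths(counts)
    if (length(unique(lens)) != 1L) {
      stop("motif '", motif_id, "': rows of unequal length")
    }
    pfm <- do.call(rbind, counts[c("A", "C", "G", "T")])
    if (any(pfm < 0)) stop("motif '", motif_id, "': negative count")
    if (ncol(pfm) < 4L) stop("motif '", motif_id, "': length < 4")
    if (any(colSums(pfm) <= 0)) stop("motif '", motif_id, "': empty column")
    motifs[[m]] <- new_motif(motif_id, tf_name, pfm)
  }
  motifs
}

new_motif <- function(motif_id, tf_name, pfm,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  rownames(pfm) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, tf_name = tf_name, pfm = pfm,
                 background = background),
            class = "venomreg_motif")
}

#' @exportS3Method base::print
print.venomreg_motif <- function(x, ...) {
  cat("<motif ", x$motif_id, " (", x$tf_name, "), length ",
      ncol(x$pfm), ">\n", sep = "")
  invisible(x)
}

#' Write motifs in JASPAR PFM text format
#' @param motifs List of motif objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$motif_id, " ", m$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ", paste(format(m$pfm[b, ], trim = TRUE),
                                        collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read a rooted, branch-length-annotated tree from Newick
#'
#' Branch lengths are required: downstream phylogenetically independent
#' contrasts are undefined without them. Polytomies are accepted and resolved
#' later, at contrast time.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in '", path, "'")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("branch lengths required for contrasts; tree in '", path,
         "' lacks them")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Read and write FASTA as a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a windowed depth table
#'
#' The file is a BED-like TSV: chrom, start, end, then one numeric depth
#' column per sample.
#'
#' @param path Path to the depth TSV.
#' @return A list with `windows` (interval tibble) and `depth`
#'   (windows x samples numeric matrix).
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) < 4L) stop("depth TSV needs chrom,start,end plus samples")
  windows <- tibble::tibble(chrom = as.character(df[[1]]),
                            start = as.integer(df[[2]]),
                            end = as.integer(df[[3]]),
                            name = paste0(df[[1]], ":", df[[2]], "-", df[[3]]),
                            element_class = "other", gene = NA_character_)
  depth <- as.matrix(df[-(1:3)])
  rownames(depth) <- windows$name
  list(windows = windows, depth = depth)
}

#' @rdname read_depth_tsv
#' @param windows Interval tibble.
#' @param depth Windows x samples matrix.
#' @export
write_depth_tsv <- function(windows, depth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("chrom", "start", "end", colnames(depth)),
                   collapse = "\t"), con)
  body <- apply(depth, 1L, function(r)
    paste(formatC(r, digits = 10, format = "g"), collapse = "\t"))
  writeLines(paste(windows$chrom, windows$start, windows$end, body,
                   sep = "\t"), con)
  invisible(path)
}

#' Check cross-file label consistency of an input bundle
#'
#' Verifies that every sample referenced by a matrix exists in the metadata,
#' that score-matrix rows are annotated in the interval table, and that
#' variants fall inside an annotated element.
#'
#' @param meta Sample metadata tibble (sample_id, lineage, population,
#'   gland_side).
#' @param counts Optional counts matrix.
#' @param scores Optional list of score matrices.
#' @param intervals Optional interval tibble.
#' @param variants Optional variant tibble.
#' @return A tibble of issues (zero rows when the bundle is consistent).
#' @export
validate_bundle <- function(meta, counts = NULL, scores = NULL,
                            intervals = NULL, variants = NULL) {
  issues <- list()
  note <- function(what, detail) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(what = what,
                                                     detail = detail)
  }
  if (anyDuplicated(meta$sample_id)) note("meta", "duplicate sample_id")
  known <- meta$sample_id
  check_samples <- function(ids, where) {
    extra <- setdiff(ids, known)
    if (length(extra)) note(where, paste("unknown samples:",
                                         paste(extra, collapse = ",")))
  }
  if (!is.null(counts)) check_samples(colnames(counts), "counts")
  if (!is.null(scores)) {
    for (nm in names(scores)) {
      check_samples(colnames(scores[[nm]]), nm)
      if (!is.null(intervals)) {
        extra <- setdiff(rownames(scores[[nm]]), intervals$name)
        if (length(extra)) note(nm, paste("intervals not in BED:",
                                          paste(extra, collapse = ",")))
      }
    }
  }
  if (!is.null(variants)) {
    check_samples(variant_samples(variants), "variants")
    if (!is.null(intervals) && nrow(variants)) {
      vi <- variant_interval(variants)
      inside <- vapply(seq_len(nrow(vi)), function(i) {
        any(intervals$chrom == vi$chrom[i] &
              intervals$start <= vi$start[i] &
              intervals$end >= vi$end[i])
      }, logical(1))
      if (any(!inside)) note("variants",
                             paste("outside annotated elements:",
                                   paste(vi$name[!inside], collapse = ",")))
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(what = character(), detail = character())
}
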