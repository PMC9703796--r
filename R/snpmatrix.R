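## Genome-skimming SNP post-processing: per-site filters, VCF <-> alignment
## conversion, consensus calling, missing-data thresholds, invariant-site
## removal, gene-length filtering, reference masking, and supermatrix
## concatenation with partition bookkeeping.
##
## Coordinate conventions: variant records are 1-based (VCF); coverage
## intervals are 0-based half-open (BED); converters sit at every I/O
## boundary. Alignments are character matrices, taxa in rows, with "N" the
## missing symbol and "-" the gap; an optional "partitions" attribute
## (data.frame name/start/end, 1-based inclusive) records gene spans.

MISSING_CHARS <- c("N", "n", "-", "?")

#' Construct a per-site variant record set
#'
#' A columnar container for VCF-like records: per-site chromosome, 1-based
#' position, reference base and site quality, plus per-sample genotype
#' (allele pair), read depth and optional genotype quality.
#'
#' @param chrom Character vector of chromosome ids (one per site).
#' @param pos Integer vector of 1-based positions.
#' @param ref Character vector of reference bases.
#' @param qual Numeric site quality scores.
#' @param a1,a2 Character matrices (samples x sites) of called alleles in
#'   `A,C,G,T`, `NA` for missing.
#' @param depth Integer matrix (samples x sites) of read depths, >= 0.
#' @param samples Character vector of sample names (rownames of the matrices).
#' @param gq Optional numeric matrix (samples x sites) of genotype qualities.
#' @return An object of class `site_records`.
#' @export
site_records <- function(chrom, pos, ref, qual, a1, a2, depth, samples,
                         gq = NULL) {
  ns <- length(pos)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be >= 1 (1-based records)")
  if (length(chrom) != ns || length(ref) != ns || length(qual) != ns)
    stop("chrom/pos/ref/qual lengths differ")
  for (m in list(a1, a2, depth)) {
    if (!is.matrix(m) || ncol(m) != ns || nrow(m) != length(samples))
      stop("per-sample matrices must be samples x sites")
  }
  if (anyNA(depth)) stop("depth must not be NA (use 0 for no reads)")
  if (any(depth < 0)) stop("negative read depth")
  bad <- !is.na(a1) & !a1 %in% c("A", "C", "G", "T")
  if (any(bad)) stop("alleles must be A/C/G/T or NA")
  bad <- !is.na(a2) & !a2 %in% c("A", "C", "G", "T")
  if (any(bad)) stop("alleles must be A/C/G/T or NA")
  rownames(a1) <- rownames(a2) <- rownames(depth) <- samples
  if (!is.null(gq)) rownames(gq) <- samples
  structure(list(chrom = as.character(chrom), pos = pos,
                 ref = as.character(ref), qual = as.numeric(qual),
                 a1 = a1, a2 = a2, depth = depth, gq = gq,
                 samples = as.character(samples)),
            class = "site_records")
}

#' @export
print.site_records <- function(x, ...) {
  cat(sprintf("site_records: %d sites x %d samples\n",
              length(x$pos), length(x$samples)))
  invisible(x)
}

#' Number of sites in a record set
#' @param x A `site_records` object.
#' @export
n_sites <- function(x) length(x$pos)

#' Apply per-site, per-sample filters to variant records
#'
#' A sample's base at a site is set to missing ("N") when its read depth is
#' below `min_depth`, the site quality is below `min_quality`, or the
#' genotype is heterozygous; otherwise the called base is kept. The
#' boundaries pass: depth 4 and quality 20 survive the default filters, as
#' only values strictly below the cutoffs are deleted.
#'
#' @param records A [site_records()] object.
#' @param min_depth Minimum read depth (default 4).
#' @param min_quality Minimum quality score (default 20).
#' @param het_policy `"mask_sample"` (default) masks only the heterozygous
#'   sample; `"drop_site"` masks the whole site when any sample is
#'   heterozygous.
#' @param quality_source `"site"` (default) uses the site-level QUAL;
#'   `"genotype"` uses the per-sample genotype quality (requires `gq`).
#' @return A character matrix (samples x sites) of bases and "N", with
#'   attribute `mask_reason`: a matrix of `"ok"`, `"depth"`, `"quality"`,
#'   `"het"`, `"missing"` (precedence in that order).
#' @export
filter_sites <- function(records, min_depth = 4L, min_quality = 20,
                         het_policy = c("mask_sample", "drop_site"),
                         quality_source = c("site", "genotype")) {
  het_policy <- match.arg(het_policy)
  quality_source <- match.arg(quality_source)
  if (min_depth < 0) stop("min_depth must be >= 0")
  ns <- n_sites(records)
  nsamp <- length(records$samples)
  qualm <- if (quality_source == "site") {
    matrix(rep(records$qual, each = nsamp), nrow = nsamp)
  } else {
    if (is.null(records$gq))
      stop("quality_source = 'genotype' requires genotype qualities (gq)")
    records$gq
  }
  het <- !is.na(records$a1) & !is.na(records$a2) & records$a1 != records$a2
  if (het_policy == "drop_site")
    het <- matrix(rep(apply(het, 2L, any), each = nsamp), nrow = nsamp)
  reason <- matrix("ok", nsamp, ns)
  reason[het] <- "het"
  reason[qualm < min_quality] <- "quality"
  reason[records$depth < min_depth] <- "depth"     # highest precedence last
  reason[is.na(records$a1) | is.na(records$a2)] <- "missing"
  calls <- records$a1
  calls[reason != "ok"] <- "N"
  rownames(calls) <- records$samples
  dimnames(reason) <- dimnames(calls)
  attr(calls, "mask_reason") <- reason
  calls
}

#' @rdname filter_sites
#' @export
filter_site <- filter_sites

#' Convert variant records to an aligned character matrix
#'
#' One alignment column per record, in record order; per-sample characters
#' come from [filter_sites()]. Records must be sorted by (chrom, position).
#'
#' @inheritParams filter_sites
#' @param sample_order Row order of the output (default: record order).
#' @param ... Passed to [filter_sites()].
#' @return A character matrix (samples x sites) with column names
#'   `chrom:pos`.
#' @export
sites_to_alignment <- function(records, sample_order = records$samples, ...) {
  o <- order(records$chrom, records$pos, method = "radix")
  if (any(o != seq_along(o)))
    stop("records must be sorted by (chrom, position)")
  if (!setequal(sample_order, records$samples))
    stop("sample_order must be a permutation of the record samples")
  calls <- filter_sites(records, ...)
  m <- calls[match(sample_order, records$samples), , drop = FALSE]
  colnames(m) <- paste0(records$chrom, ":", records$pos)
  attr(m, "mask_reason") <- NULL
  m
}

#' Most-common-base consensus with IUPAC ties
#'
#' Per site, the base with the highest count wins; ties produce the IUPAC
#' ambiguity code of the tied bases; a site with no counts yields "N".
#'
#' @param counts A list, one element per site, each a named numeric vector of
#'   base counts (names among A,C,G,T).
#' @return A single consensus string.
#' @export
consensus_sequence <- function(counts) {
  iupac <- stats::setNames(names(Biostrings::IUPAC_CODE_MAP),
                           Biostrings::IUPAC_CODE_MAP)
  vapply(counts, function(ct) {
    ct <- ct[!is.na(ct) & ct > 0]
    if (!length(ct)) return("N")
    top <- sort(names(ct)[ct == max(ct)], method = "radix")
    if (length(top) == 1L) return(top)
    code <- iupac[[paste(top, collapse = "")]]
    if (is.null(code)) "N" else code
  }, "") |> paste(collapse = "")
}

## ---- column filters -------------------------------------------------------

.is_missing_char <- function(x) x %in% MISSING_CHARS

#' Fraction of missing characters per alignment column
#'
#' Missing symbol "N" and gap "-" (also "?") both count as missing.
#'
#' @param matrix Character matrix, taxa in rows.
#' @param column Optional single column index; when omitted, the fraction is
#'   returned for every column.
#' @return Numeric vector of fractions in [0, 1].
#' @export
column_missing_fraction <- function(matrix, column = NULL) {
  if (!is.null(column)) {
    if (column < 1L || column > ncol(matrix)) stop("column index out of range")
    return(mean(.is_missing_char(matrix[, column])))
  }
  colMeans(apply(matrix, 2L, .is_missing_char))
}

## remap a 1-based inclusive partition table after dropping columns
.remap_partitions <- function(parts, keep) {
  if (is.null(parts)) return(NULL)
  newpos <- cumsum(keep)
  out <- lapply(seq_len(nrow(parts)), function(i) {
    span <- seq.int(parts$start[i], parts$end[i])
    surv <- span[keep[span]]
    if (!length(surv)) return(NULL)
    data.frame(name = parts$name[i], start = newpos[surv[1L]],
               end = newpos[surv[length(surv)]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) NULL else out
}

#' Drop alignment columns exceeding a missing-data threshold
#'
#' Keeps columns whose missing fraction is less than or equal to
#' `max_missing` (inclusive boundary: a threshold names the level of missing
#' data tolerated). Column order is preserved and any partition table is
#' remapped to the surviving coordinates. Stricter thresholds always yield a
#' subset of the columns kept at looser ones.
#'
#' @param matrix Character matrix, taxa in rows.
#' @param max_missing Maximum tolerated missing fraction in [0, 1].
#' @return The filtered matrix; attribute `n_removed` gives the column count
#'   dropped.
#' @export
apply_missing_threshold <- function(matrix, max_missing) {
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0, 1]")
  frac <- column_missing_fraction(matrix)
  keep <- frac <= max_missing
  out <- matrix[, keep, drop = FALSE]
  attr(out, "partitions") <- .remap_partitions(attr(matrix, "partitions"), keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove invariant alignment columns
#'
#' Keeps columns with at least two distinct states among A,C,G,T (case
#' insensitive); missing symbols, gaps and ambiguity codes do not count as
#' states. Partition tables are remapped.
#'
#' @param matrix Character matrix, taxa in rows.
#' @return The variable-sites matrix; attributes `n_kept` and `n_removed`.
#' @export
remove_invariant_sites <- function(matrix) {
  states <- c("A", "C", "G", "T")
  keep <- apply(matrix, 2L, function(col) {
    s <- unique(toupper(col))
    length(intersect(s, states)) >= 2L
  })
  out <- matrix[, keep, drop = FALSE]
  attr(out, "partitions") <- .remap_partitions(attr(matrix, "partitions"), keep)
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Concatenate gene alignments into a supermatrix
#'
#' Columns are appended left-to-right in input order. Taxa absent from a gene
#' are padded with "N" across that gene's span. The result carries a
#' partition table (1-based inclusive gene spans) in attribute `partitions`.
#'
#' @param matrices Named list of character matrices (taxa in rows). Unnamed
#'   inputs get names `gene1, gene2, ...`.
#' @param taxa Optional character vector fixing row order; defaults to the
#'   union of input taxa in order of first appearance.
#' @return The supermatrix with attribute `partitions`.
#' @export
concatenate_alignments <- function(matrices, taxa = NULL) {
  if (!length(matrices)) stop("need at least one alignment")
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    names(matrices) <- paste0("gene", seq_along(matrices))
  for (nm in names(matrices))
    if (anyDuplicated(rownames(matrices[[nm]])))
      stop("duplicate taxon within alignment ", nm)
  if (is.null(taxa)) {
    taxa <- character(0)
    for (m in matrices) taxa <- union(taxa, rownames(m))
  }
  widths <- vapply(matrices, ncol, 0L)
  total <- sum(widths)
  out <- matrix("N", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    rows <- intersect(taxa, rownames(m))
    out[rows, starts[i]:ends[i]] <- m[rows, , drop = FALSE]
  }
  attr(out, "partitions") <- data.frame(
    name = names(matrices), start = starts, end = ends,
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Split a supermatrix back into its partitions
#'
#' Inverse of [concatenate_alignments()]: cuts the matrix at the spans of its
#' partition table.
#'
#' @param matrix A supermatrix with a `partitions` attribute.
#' @return A named list of character matrices.
#' @export
split_by_partition <- function(matrix) {
  parts <- attr(matrix, "partitions")
  if (is.null(parts)) stop("matrix has no partition table")
  out <- lapply(seq_len(nrow(parts)), function(i)
    matrix[, parts$start[i]:parts$end[i], drop = FALSE])
  names(out) <- parts$name
  out
}

#' Keep reference regions covered by at least one sample
#'
#' Returns the union of all samples' covered intervals; the complement of
#' that union is the masked set (regions no sample matched). Intervals are
#' 0-based half-open throughout.
#'
#' @param reference_length Total reference length.
#' @param maps List (one element per sample) of data.frames with columns
#'   `start`, `end` (0-based half-open).
#' @return List with data.frames `kept` and `masked` (columns start, end).
#' @export
mask_uncovered <- function(reference_length, maps) {
  if (!length(maps)) stop("need at least one coverage map")
  all_ir <- IRanges::IRanges()
  for (m in maps) {
    if (!nrow(m)) next
    if (any(m$start < 0) || any(m$end > reference_length) ||
        any(m$end <= m$start))
      stop("coverage interval out of reference bounds [0, ",
           reference_length, ")")
    all_ir <- c(all_ir, IRanges::IRanges(start = m$start + 1L, end = m$end))
  }
  kept <- IRanges::reduce(all_ir)
  masked <- IRanges::setdiff(IRanges::IRanges(1L, reference_length), kept)
  to_df <- function(ir) data.frame(start = IRanges::start(ir) - 1L,
                                   end = IRanges::end(ir))
  list(kept = to_df(kept), masked = to_df(masked))
}

#' Filter gene alignments by minimum length
#'
#' Keeps alignments whose column count is at least `min_length` (inclusive).
#'
#' @param alignments Named list of character matrices.
#' @param min_length Minimum alignment length in bp.
#' @return The surviving subset of the input list.
#' @export
filter_genes_by_length <- function(alignments, min_length) {
  if (!length(alignments)) return(alignments)
  alignments[vapply(alignments, ncol, 0L) >= min_length]
}

## ---- file IO --------------------------------------------------------------

#' Read an aligned FASTA file into a character matrix
#' @param path FASTA path (optionally gzipped).
#' @return Character matrix, taxa in rows (uppercase).
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  rows <- strsplit(toupper(as.character(ss)), "", fixed = TRUE)
  if (length(unique(lengths(rows))) != 1L)
    stop("sequences in ", path, " have unequal lengths; not an alignment")
  m <- do.call(rbind, rows)
  rownames(m) <- names(ss)
  m
}

#' Write a character matrix as aligned FASTA
#' @param matrix Character matrix, taxa in rows.
#' @param path Output path; `.gz` triggers compression.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(matrix, path) {
  seqs <- apply(matrix, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(matrix)
  Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a RAxML-style partition file
#' @param matrix A supermatrix with a `partitions` attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_file <- function(matrix, path) {
  parts <- attr(matrix, "partitions")
  if (is.null(parts)) stop("matrix has no partition table")
  writeLines(sprintf("DNA, %s = %d-%d", parts$name, parts$start, parts$end),
             path)
  invisible(path)
}

#' Write variant records as a minimal VCF 4.2 file
#'
#' Site QUAL, per-sample GT:DP (and GQ when present). Alleles are indexed
#' against REF plus the observed alternates at each site.
#'
#' @param records A [site_records()] object.
#' @param path Output path; `.gz` triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_vcf_records <- function(records, path) {
  ns <- n_sites(records)
  has_gq <- !is.null(records$gq)
  fmt <- if (has_gq) "GT:DP:GQ" else "GT:DP"
  lines <- character(ns)
  for (j in seq_len(ns)) {
    ref <- records$ref[j]
    obs <- unique(stats::na.omit(c(records$a1[, j], records$a2[, j])))
    alt <- sort(setdiff(obs, ref), method = "radix")
    allele_idx <- stats::setNames(seq_along(c(ref, alt)) - 1L, c(ref, alt))
    gts <- vapply(seq_along(records$samples), function(i) {
      x1 <- records$a1[i, j]; x2 <- records$a2[i, j]
      gt <- if (is.na(x1) || is.na(x2)) "./." else
        paste(allele_idx[c(x1, x2)], collapse = "/")
      rest <- records$depth[i, j]
      if (has_gq) paste(gt, rest, records$gq[i, j], sep = ":")
      else paste(gt, rest, sep = ":")
    }, "")
    lines[j] <- paste(c(records$chrom[j], records$pos[j], ".", ref,
                        if (length(alt)) paste(alt, collapse = ",") else ".",
                        format(records$qual[j]), "PASS", ".", fmt, gts),
                      collapse = "\t")
  }
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              if (has_gq) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", records$samples), collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' Read a VCF file into a site_records object
#'
#' Uses `vcfR` for parsing; requires GT and DP FORMAT fields and biallelic or
#' multiallelic SNP records with single-base alleles.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [site_records()] object.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  gq <- if ("GQ" %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":")))
    vcfR::extract.gt(v, "GQ", as.numeric = TRUE) else NULL
  samples <- colnames(gt)
  ns <- nrow(fix)
  ref <- fix[, "REF"]
  altl <- strsplit(ifelse(is.na(fix[, "ALT"]) | fix[, "ALT"] == ".",
                          "", fix[, "ALT"]), ",", fixed = TRUE)
  a1 <- matrix(NA_character_, length(samples), ns)
  a2 <- matrix(NA_character_, length(samples), ns)
  for (j in seq_len(ns)) {
    alleles <- c(ref[j], altl[[j]])
    g <- gt[j, ]
    sp <- strsplit(ifelse(is.na(g), "./.", g), "[/|]")
    i1 <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1L)))
    i2 <- suppressWarnings(as.integer(vapply(sp, function(x)
      if (length(x) >= 2L) x[2L] else x[1L], "")))
    a1[, j] <- ifelse(is.na(i1), NA, alleles[i1 + 1L])
    a2[, j] <- ifelse(is.na(i2), NA, alleles[i2 + 1L])
  }
  dp[is.na(dp)] <- 0
  site_records(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               ref = ref, qual = as.numeric(fix[, "QUAL"]),
               a1 = a1, a2 = a2,
               depth = matrix(as.integer(t(dp)), length(samples), ns),
               samples = samples,
               gq = if (is.null(gq)) NULL else
                 matrix(as.numeric(t(gq)), length(samples), ns))
}
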