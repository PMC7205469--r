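# Read counting (strict containment), RPKM, d3'UTR ratios and the two-sample
# fold-change / binned Z-score sensitivity classification.

#' Read aligned reads from SAM or BED
#'
#' SAM files are converted to BAM on the fly (Rsamtools) and loaded with
#' GenomicAlignments; 6-column BED is read with rtracklayer. Paired-end data
#' is treated as independent reads.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"sam"` or `"bed"`.
#' @return A `GRanges` of read intervals.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) "sam" else "bed"
  }
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    ga <- GenomicAlignments::readGAlignments(bam)
    gr <- GenomicRanges::granges(ga)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
  }
  gr
}

#' Collapse duplicate reads
#'
#' Duplicates are reads identical in (chromosome, 5' start, strand), matching
#' `samtools rmdup` semantics on single-end data; one representative is kept.
#'
#' @param reads `GRanges` of reads.
#' @return Deduplicated `GRanges`.
#' @export
dedup_reads <- function(reads) {
  if (length(reads) == 0) return(reads)
  five_prime <- ifelse(as.character(GenomicRanges::strand(reads)) == "-",
                       GenomicRanges::end(reads), GenomicRanges::start(reads))
  key <- paste(as.character(GenomicRanges::seqnames(reads)), five_prime,
               as.character(GenomicRanges::strand(reads)))
  reads[!duplicated(key)]
}

#' Count reads strictly contained in features
#'
#' A read increments a feature's count iff its interval is a subset of the
#' feature interval on the same chromosome (`intersectBed -f 1.0` semantics).
#' Counting is strand-agnostic (unstranded library prep). The library size is
#' the total number of (post-dedup) mapped reads, not just the counted ones.
#'
#' @param reads `GRanges` of reads.
#' @param features Split-feature data frame (see [build_split_annotation()]).
#' @param dedup Collapse duplicates first (see [dedup_reads()]).
#' @param sample_id Sample label stored in the table.
#' @return A `count_table`: list with `counts` (named integer vector over
#'   `feature_id`), `library_size`, `sample_id`.
#' @export
count_contained_reads <- function(reads, features, dedup = FALSE,
                                  sample_id = "sample") {
  if (any(features$end - features$start <= 0))
    stop("features must have positive length")
  if (dedup) reads <- dedup_reads(reads)
  fgr <- features_to_granges(features)
  counts <- integer(nrow(features))
  names(counts) <- features$feature_id
  if (length(reads) > 0) {
    hits <- GenomicRanges::findOverlaps(reads, fgr, type = "within",
                                        ignore.strand = TRUE)
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(features))
    counts[] <- tab
  }
  count_table(counts, library_size = length(reads), sample_id = sample_id)
}

#' Construct a count table
#'
#' @param counts Named non-negative integer vector (feature or gene ids).
#' @param library_size Total mapped reads in the sample.
#' @param sample_id Sample label.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, library_size, sample_id = "sample") {
  if (any(counts < 0)) stop("negative counts")
  if (library_size < 0) stop("negative library size")
  if (library_size > 0 && any(counts > library_size))
    stop("count exceeds library size")
  structure(list(counts = counts, library_size = as.numeric(library_size),
                 sample_id = sample_id), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s: %d features, library %s reads\n",
              x$sample_id, length(x$counts),
              format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Aggregate a feature-level count table to gene level
#'
#' @param table A `count_table` keyed by `feature_id`.
#' @param features The matching feature data frame.
#' @return A `count_table` keyed by `gene_id`.
#' @export
gene_level_counts <- function(table, features) {
  stopifnot(identical(names(table$counts), features$feature_id))
  agg <- tapply(table$counts, features$gene_id, sum)
  counts <- as.integer(agg)
  names(counts) <- names(agg)
  count_table(counts, table$library_size, table$sample_id)
}

#' Compute RPKM for every feature
#'
#' RPKM = count / (feature length in kb x mapped reads in millions).
#'
#' @param table A `count_table`.
#' @param features Feature data frame aligned with `table$counts`.
#' @return Named numeric vector of RPKM values.
#' @export
compute_rpkm <- function(table, features) {
  if (table$library_size <= 0) stop("library_size must be positive")
  stopifnot(identical(names(table$counts), features$feature_id))
  len_kb <- (features$end - features$start) / 1e3
  table$counts / (len_kb * table$library_size / 1e6)
}

#' Per-gene d3'UTR usage ratios
#'
#' ratio = RPKM(d3'UTR) / RPKM(upstream last-exon segment); `NA` when no read
#' maps to the upstream segment. Genes lacking either member of the feature
#' pair are skipped with a warning; genes without a validated proximal pA have
#' no d3utr feature and are therefore absent.
#'
#' @param table A feature-level `count_table`.
#' @param features Feature data frame aligned with `table$counts`.
#' @return Data frame: `gene_id`, `d3utr_count`, `upstream_count`,
#'   `d3utr_rpkm`, `upstream_rpkm`, `ratio`.
#' @export
compute_d3utr_ratios <- function(table, features) {
  rpkm <- compute_rpkm(table, features)
  d3 <- features$kind == "d3utr"
  up <- features$kind == "upstream_last_exon"
  d3_genes <- features$gene_id[d3]
  up_genes <- features$gene_id[up]
  common <- intersect(d3_genes, up_genes)
  orphans <- setdiff(union(d3_genes, up_genes), common)
  if (length(orphans))
    warning("skipping genes with unpaired split features: ",
            paste(orphans, collapse = ", "))
  d3_idx <- which(d3)[match(common, d3_genes)]
  up_idx <- which(up)[match(common, up_genes)]
  out <- data.frame(
    gene_id = common,
    d3utr_count = as.integer(table$counts[d3_idx]),
    upstream_count = as.integer(table$counts[up_idx]),
    d3utr_rpkm = as.numeric(rpkm[d3_idx]),
    upstream_rpkm = as.numeric(rpkm[up_idx]),
    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$upstream_count > 0,
                      out$d3utr_rpkm / out$upstream_rpkm, NA_real_)
  out
}

#' Two-sample differential expression with a binned Z-score criterion
#'
#' Size factors are median-of-ratios against the per-gene geometric mean
#' (computed over genes expressed in both samples). The fold-change is
#' `(mean_b + c) / (mean_a + c)` on normalized counts with pseudocount `c`.
#' The named-but-undefined "Z-score criterion" is implemented as: genes are
#' split into `n_bins` equal-occupancy bins by the reference (condition A)
#' normalized count -- binning on the reference keeps condition-B effects out
#' of the bin assignment -- and within each bin
#' `z = (log2 fc - median) / (1.4826 * MAD)`, with `p` the one-sided upper
#' normal tail. This is a documented robust stand-in for the DESeq-era test,
#' not a reproduction of it.
#'
#' @param a,b Gene-level `count_table`s (conditions A and B).
#' @param pseudocount Pseudocount on normalized counts (default 0.5).
#' @param n_bins Number of expression bins (default 20).
#' @param min_genes Minimum genes nonzero in both samples (default 50).
#' @return Data frame: `gene_id`, `mean_a`, `mean_b`, `fc`, `z`, `p`.
#' @export
differential_expression <- function(a, b, pseudocount = 0.5, n_bins = 20,
                                    min_genes = 50) {
  genes <- intersect(names(a$counts), names(b$counts))
  ca <- as.numeric(a$counts[genes]); cb <- as.numeric(b$counts[genes])
  both <- ca > 0 & cb > 0
  if (sum(both) < min_genes)
    stop("fewer than ", min_genes,
         " genes with nonzero counts in both samples; size factors unstable")
  ref <- sqrt(ca[both] * cb[both])
  sf_a <- stats::median(ca[both] / ref)
  sf_b <- stats::median(cb[both] / ref)
  mean_a <- ca / sf_a; mean_b <- cb / sf_b
  fc <- (mean_b + pseudocount) / (mean_a + pseudocount)
  l2fc <- log2(fc)
  bins <- ceiling(rank(mean_a, ties.method = "first") /
                  (length(mean_a) / n_bins))
  z <- numeric(length(l2fc))
  for (bi in unique(bins)) {
    idx <- bins == bi
    med <- stats::median(l2fc[idx])
    scale <- stats::mad(l2fc[idx])
    if (scale == 0) scale <- stats::sd(l2fc[idx])
    if (is.na(scale) || scale == 0) scale <- .Machine$double.eps
    z[idx] <- (l2fc[idx] - med) / scale
  }
  data.frame(gene_id = genes, mean_a = mean_a, mean_b = mean_b, fc = fc,
             z = z, p = stats::pnorm(z, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Label genes as sensitive, neutral or unassigned
#'
#' Sensitive: fold-change >= `fc_sensitive` and Z-score p < `p_sensitive`
#' (default: >= 3-fold, p < 0.01). Neutral: fold-change strictly between
#' `1/fc_neutral` and `fc_neutral` (default: less than 2-fold change either
#' way). Everything else is unassigned.
#'
#' @param records Output of [differential_expression()].
#' @param fc_sensitive,p_sensitive,fc_neutral Thresholds.
#' @return `records` with an added `label` column.
#' @export
classify_aire_sensitivity <- function(records, fc_sensitive = 3,
                                      p_sensitive = 0.01, fc_neutral = 2) {
  label <- rep("unassigned", nrow(records))
  label[records$fc >= fc_sensitive & records$p < p_sensitive] <- "sensitive"
  label[records$fc > 1 / fc_neutral & records$fc < fc_neutral &
        label == "unassigned"] <- "neutral"
  records$label <- label
  records
}

#' Write a table with NA literals
#'
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
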