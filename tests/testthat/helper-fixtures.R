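# Small in-code fixtures shared across test files. All coordinates 0-based
# half-open, matching the package's internal convention.

# a split-feature data frame from (gene_id, kind, start, end) rows
make_features <- function(..., chrom = "chr1", strand = "+") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], kind = r[[2]],
               start = as.numeric(r[[3]]), end = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)))
  df$chrom <- chrom
  df$strand <- strand
  df$length <- df$end - df$start
  df$feature_id <- make.unique(paste(df$gene_id, df$kind, sep = ":"),
                               sep = "#")
  df[, c("gene_id", "kind", "chrom", "strand", "start", "end", "length",
         "feature_id")]
}

# reads as GRanges from 0-based starts
make_reads <- function(starts, width = 50, chrom = "chr1", strand = "+") {
  GenomicRanges::GRanges(
    seqnames = rep(chrom, length(starts)),
    ranges = IRanges::IRanges(start = starts + 1, width = width),
    strand = rep(strand, length(starts)))
}

# a single-exon-structure gene: one upstream exon plus a last exon with UTR
toy_gene <- function(gene_id = "g1", strand = "+", chrom = "chr1",
                     utr = c(1200, 1500), last_exon = c(1000, 1500),
                     other = c(400, 700)) {
  gene_model(gene_id = gene_id, tx_id = paste0("NM_", gene_id),
             chrom = chrom, strand = strand,
             exons = rbind(other, last_exon),
             utr3 = matrix(utr, ncol = 2))
}

# brute-force strict-containment counting: O(reads x features) arithmetic on
# plain vectors, independent of the GenomicRanges path
brute_force_counts <- function(read_start, read_end, read_chrom,
                               features) {
  vapply(seq_len(nrow(features)), function(i) {
    sum(read_chrom == features$chrom[i] &
        read_start >= features$start[i] &
        read_end <= features$end[i])
  }, numeric(1))
}

# brute-force classic enrichment score: recompute the prefix score at every
# rank by explicit counting (O(N * |S|)) in exact integer arithmetic;
# positive extremum preferred on exact ties
brute_force_es <- function(positions, n) {
  k <- length(positions)
  mx <- -Inf; mn <- Inf
  for (i in seq_len(n)) {
    hits <- sum(positions <= i)
    s <- hits * n - i * k        # numerator of the running sum
    if (s > mx) mx <- s
    if (s < mn) mn <- s
  }
  if (mx >= -mn) mx / (k * (n - k)) else mn / (k * (n - k))
}
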