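# Split 3'UTR annotation: validate proximal polyA sites against gene models and
# cut the terminal 3' exon into an upstream segment and a distal 3'UTR (d3'UTR)
# segment whose expression ratio estimates long-isoform usage.
#
# All internal coordinates are 0-based half-open intervals; GTF input/output is
# 1-based inclusive (standard dialect).

#' Construct a gene model
#'
#' A gene model is one transcript's exon/CDS/3'UTR structure. Intervals are
#' 0-based half-open, exons sorted by genomic coordinate and non-overlapping,
#' and every 3'UTR interval must lie inside an exon.
#'
#' @param gene_id,tx_id Gene and transcript identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon intervals.
#' @param cds Optional length-2 vector, genomic span of the CDS.
#' @param utr3 Optional two-column matrix of 3'UTR intervals.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, tx_id, chrom, strand, exons, cds = NULL,
                       utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- .as_interval_matrix(exons)
  if (is.unsorted(exons[, 1], strictly = FALSE))
    stop("exons must be sorted by coordinate")
  if (any(exons[, 2] <= exons[, 1])) stop("degenerate exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("exons must be non-overlapping")
  if (!is.null(utr3)) {
    utr3 <- .as_interval_matrix(utr3)
    inside <- vapply(seq_len(nrow(utr3)), function(i) {
      any(utr3[i, 1] >= exons[, 1] & utr3[i, 2] <= exons[, 2])
    }, logical(1))
    if (!all(inside)) stop("utr3 intervals must be subsets of exons")
  }
  structure(list(gene_id = gene_id, tx_id = tx_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds, utr3 = utr3),
            class = "gene_model")
}

.as_interval_matrix <- function(x) {
  m <- matrix(as.numeric(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  m[order(m[, 1]), , drop = FALSE]
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s, %d exon(s), %d 3'UTR interval(s)\n",
              x$gene_id, x$tx_id, x$chrom, x$strand, nrow(x$exons),
              if (is.null(x$utr3)) 0L else nrow(x$utr3)))
  invisible(x)
}

# 3'-most (terminal) 3'UTR interval in transcript orientation, or NULL.
terminal_utr3 <- function(gene) {
  if (is.null(gene$utr3) || nrow(gene$utr3) == 0) return(NULL)
  u <- gene$utr3
  if (gene$strand == "+") u[which.max(u[, 2]), ] else u[which.min(u[, 1]), ]
}

#' Select the validated proximal polyA site of a gene
#'
#' A polyA-database site is validated when it falls inside the gene's terminal
#' 3'UTR and its genomic distance to the distal 3'UTR boundary is at least
#' `min_distance` bases. Among several validated sites, the most proximal one
#' (closest to the stop codon in transcript orientation) wins.
#'
#' @param gene A [gene_model()].
#' @param sites Data frame with columns `chrom`, `strand`, `position`
#'   (0-based cleavage coordinate), `gene_id`.
#' @param min_distance Minimum distance to the distal boundary (default 20).
#' @return A one-row data frame (the selected site) or `NULL`.
#' @export
select_proximal_pa <- function(gene, sites, min_distance = 20) {
  tu <- terminal_utr3(gene)
  if (is.null(tu) || is.null(sites) || nrow(sites) == 0) return(NULL)
  s <- sites[sites$gene_id == gene$gene_id &
             sites$chrom == gene$chrom &
             sites$strand == gene$strand, , drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  inside <- s$position >= tu[1] & s$position < tu[2]
  dist_to_distal <- if (gene$strand == "+") tu[2] - s$position
                    else s$position - tu[1]
  ok <- inside & dist_to_distal >= min_distance
  s <- s[ok, , drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  pick <- if (gene$strand == "+") which.min(s$position) else which.max(s$position)
  s[pick, , drop = FALSE]
}

#' Build the split annotation from gene models and polyA sites
#'
#' For each gene with a validated proximal pA the terminal 3' exon is split at
#' the pA into `upstream_last_exon` (last coding-exon segment fused with the
#' proximal 3'UTR) and `d3utr` (pA to the distal 3'UTR boundary); all other
#' exons are emitted unchanged as `other_exon`. Genes without a validated pA
#' emit their exons only and are flagged `single_pa`. When several transcripts
#' share a `gene_id` the one with the longest annotated 3'UTR is used.
#'
#' @param genes List of [gene_model()] objects.
#' @param sites polyA site data frame (see [select_proximal_pa()]).
#' @param min_distance Passed to [select_proximal_pa()].
#' @return List with `features` (data frame: `gene_id`, `kind`, `chrom`,
#'   `strand`, `start`, `end`, `length`, `feature_id`; 0-based half-open) and
#'   `genes` (data frame: `gene_id`, `has_pa`, `pa_position`).
#' @export
build_split_annotation <- function(genes, sites, min_distance = 20) {
  genes <- pick_transcript_per_gene(genes)
  feats <- vector("list", length(genes))
  summ <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    pa <- select_proximal_pa(g, sites, min_distance = min_distance)
    tu <- terminal_utr3(g)
    rows <- NULL
    if (!is.null(pa) && !is.null(tu)) {
      # last exon = the exon containing the terminal 3'UTR
      le_idx <- which(g$exons[, 1] <= tu[1] & g$exons[, 2] >= tu[2])[1]
      le <- g$exons[le_idx, ]
      p <- pa$position
      if (g$strand == "+") {
        up <- c(le[1], p); d3 <- c(p, tu[2])
      } else {
        up <- c(p, le[2]); d3 <- c(tu[1], p)
      }
      others <- g$exons[-le_idx, , drop = FALSE]
      rows <- rbind(
        data.frame(kind = "upstream_last_exon", start = up[1], end = up[2]),
        data.frame(kind = "d3utr", start = d3[1], end = d3[2]),
        if (nrow(others))
          data.frame(kind = "other_exon", start = others[, 1], end = others[, 2])
      )
      summ[[i]] <- data.frame(gene_id = g$gene_id, has_pa = TRUE,
                              pa_position = p)
    } else {
      rows <- data.frame(kind = "other_exon", start = g$exons[, 1],
                         end = g$exons[, 2])
      summ[[i]] <- data.frame(gene_id = g$gene_id, has_pa = FALSE,
                              pa_position = NA_real_)
    }
    rows$gene_id <- g$gene_id
    rows$chrom <- g$chrom
    rows$strand <- g$strand
    feats[[i]] <- rows
  }
  features <- do.call(rbind, feats)
  features$length <- features$end - features$start
  if (any(features$length <= 0)) stop("zero-length split feature produced")
  features <- features[, c("gene_id", "kind", "chrom", "strand",
                           "start", "end", "length")]
  features$feature_id <- make.unique(paste(features$gene_id, features$kind,
                                           sep = ":"), sep = "#")
  list(features = features, genes = do.call(rbind, summ))
}

#' Keep one transcript per gene (longest total 3'UTR)
#'
#' @param genes List of [gene_model()] objects.
#' @return Filtered list, one model per `gene_id`.
#' @export
pick_transcript_per_gene <- function(genes) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  utr_len <- vapply(genes, function(g) {
    if (is.null(g$utr3)) 0 else sum(g$utr3[, 2] - g$utr3[, 1])
  }, numeric(1))
  keep <- unlist(lapply(split(seq_along(genes), ids), function(idx) {
    idx[order(-utr_len[idx],
              vapply(genes[idx], `[[`, "", "tx_id"))[1]]
  }), use.names = FALSE)
  genes[sort(keep)]
}

#' Convert split features to GRanges (1-based)
#'
#' @param features Feature data frame from [build_split_annotation()].
#' @return A `GRanges` with `gene_id`, `kind`, `feature_id` metadata columns.
#' @export
features_to_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1, end = features$end),
    strand = features$strand,
    gene_id = features$gene_id, kind = features$kind,
    feature_id = features$feature_id)
}

#' Write a split annotation as GTF
#'
#' Feature kinds go in the GTF feature (3rd) column; `gene_id` and
#' `feature_id` in the attributes. 1-based inclusive coordinates.
#'
#' @param features Feature data frame from [build_split_annotation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_split_gtf <- function(features, path) {
  lines <- sprintf(
    '%s\tapakit\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; feature_id "%s";',
    features$chrom, features$kind, features$start + 1L,
    as.integer(features$end), features$strand, features$gene_id,
    features$feature_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a split annotation GTF
#'
#' @param path GTF file written by [write_split_gtf()].
#' @return Feature data frame in the internal 0-based representation.
#' @export
read_split_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    gene_id = gr$gene_id,
    kind = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  df$feature_id <- if (!is.null(gr$feature_id)) gr$feature_id else
    make.unique(paste(df$gene_id, df$kind, sep = ":"), sep = "#")
  df
}

#' Read polyA sites from a tab-delimited table
#'
#' Expected columns: `chrom`, `strand`, `position` (0-based), `gene_id`.
#'
#' @param path Input file.
#' @return Data frame of polyA sites.
#' @export
read_pa_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "strand", "position", "gene_id")
  if (!all(req %in% names(df)))
    stop("pA site table must have columns: ", paste(req, collapse = ", "))
  df
}

#' Write polyA sites to a tab-delimited table
#'
#' @param sites polyA site data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pa_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Accepts `exon`, `CDS` and 3'UTR records (`3UTR`, `three_prime_utr` or
#' `3'UTR` feature types), grouped by `transcript_id` (falling back to
#' `gene_id`).
#'
#' @param path GTF file.
#' @return List of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  type[type %in% c("three_prime_utr", "3'UTR")] <- "3UTR"
  tx <- if (!is.null(gr$transcript_id)) gr$transcript_id else gr$gene_id
  keep <- type %in% c("exon", "CDS", "3UTR")
  gr <- gr[keep]; type <- type[keep]; tx <- tx[keep]
  out <- lapply(split(seq_along(gr), tx), function(idx) {
    sub <- gr[idx]; st <- type[idx]
    ex <- sub[st == "exon"]
    cds <- sub[st == "CDS"]
    utr <- sub[st == "3UTR"]
    iv <- function(x) if (length(x) == 0) NULL else
      cbind(GenomicRanges::start(x) - 1, GenomicRanges::end(x))
    gene_model(
      gene_id = sub$gene_id[1],
      tx_id = tx[idx][1],
      chrom = as.character(GenomicRanges::seqnames(sub))[1],
      strand = as.character(GenomicRanges::strand(sub))[1],
      exons = iv(ex),
      cds = if (length(cds)) c(min(GenomicRanges::start(cds)) - 1,
                               max(GenomicRanges::end(cds))) else NULL,
      utr3 = iv(utr))
  })
  unname(out)
}

#' Write gene models to GTF
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(genes, path) {
  lines <- unlist(lapply(genes, function(g) {
    fmt <- function(kind, m) sprintf(
      '%s\tapakit\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      g$chrom, kind, as.integer(m[, 1]) + 1L, as.integer(m[, 2]),
      g$strand, g$gene_id, g$tx_id)
    c(fmt("exon", g$exons),
      if (!is.null(g$cds)) fmt("CDS", matrix(g$cds, ncol = 2)),
      if (!is.null(g$utr3)) fmt("3UTR", g$utr3))
  }))
  writeLines(lines, path)
  invisible(path)
}
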