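# Synthetic data with planted ground truth: gene models with optional proximal
# polyA sites, two-isoform read sets at controlled mixture proportions,
# multi-tissue expression matrices, probe intensity tables, first-order decay
# time courses, and coverage tracks with peaks at polyA sites.
#
# Every generator is fully determined by its seed; sizes and levels default to
# the conditions the analyses assume (mammalian-scale 3'UTR geometry, 50 b
# single-end reads, unstranded libraries).

#' Simulate gene models and proximal polyA sites
#'
#' Genes are laid out on one chromosome with 1-3 upstream exons and a terminal
#' exon holding a last coding-exon segment plus the 3'UTR. A configured
#' fraction of genes carries one proximal pA, by construction at least 20 b
#' from the distal 3'UTR boundary and at least 150 b from the 3'UTR start.
#'
#' @param n_genes Number of genes (default 200).
#' @param pa_fraction Fraction of genes with a proximal pA (default 0.8).
#' @param seed Integer seed.
#' @param chrom Chromosome name (default `"chrS"`).
#' @param utr_range 3'UTR length range in bases (default 600-1500).
#' @param cds_range Last coding-exon segment length range (default 200-800).
#' @param d3_min Minimum d3'UTR length (default 300).
#' @return List: `models` (list of [gene_model()]), `pa_sites` (data frame),
#'   `truth` (per-gene geometry and planted pA), `chrom_length`.
#' @export
simulate_annotation <- function(n_genes = 200, pa_fraction = 0.8, seed = 1,
                                chrom = "chrS", utr_range = c(600, 1500),
                                cds_range = c(200, 800), d3_min = 300) {
  stopifnot(pa_fraction >= 0, pa_fraction <= 1)
  if (pa_fraction > 0 && utr_range[1] < 40)
    stop("3'UTR shorter than 40 b with a pA requested: infeasible geometry")
  if (pa_fraction > 0 && utr_range[1] < d3_min + 150)
    stop("utr_range too short for d3_min plus a 150 b proximal segment")
  set.seed(seed)
  has_pa <- rep(FALSE, n_genes)
  if (pa_fraction > 0)
    has_pa[sample.int(n_genes, round(pa_fraction * n_genes))] <- TRUE
  cursor <- 1000
  models <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  sites <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("g%04d", i)
    strand <- sample(c("+", "-"), 1)
    n_other <- sample(1:3, 1)
    other_len <- round(stats::runif(n_other, 150, 400))
    gaps <- round(stats::runif(n_other, 200, 800))
    cds_part <- round(stats::runif(1, cds_range[1], cds_range[2]))
    utr_len <- round(stats::runif(1, utr_range[1], utr_range[2]))
    d3_len <- if (has_pa[i])
      round(stats::runif(1, d3_min, min(1200, utr_len - 150))) else NA_real_
    le_len <- cds_part + utr_len
    if (strand == "+") {
      starts <- cursor + cumsum(c(0, other_len + gaps))
      ends <- starts + c(other_len, le_len)
      le <- c(starts[n_other + 1], ends[n_other + 1])
      utr <- c(le[1] + cds_part, le[2])
      pa_pos <- if (has_pa[i]) utr[2] - d3_len else NA_real_
    } else {
      starts <- cursor + cumsum(c(0, le_len + gaps[1],
                                  if (n_other > 1)
                                    other_len[-n_other] + gaps[-1]))
      ends <- starts + c(le_len, other_len)
      le <- c(starts[1], ends[1])
      utr <- c(le[1], le[1] + utr_len)
      pa_pos <- if (has_pa[i]) utr[1] + d3_len else NA_real_
    }
    exons <- cbind(starts, ends)
    models[[i]] <- gene_model(
      gene_id = gid, tx_id = paste0("NM_", gid), chrom = chrom,
      strand = strand, exons = exons, utr3 = matrix(utr, ncol = 2))
    up_len <- if (has_pa[i]) le_len - d3_len else NA_real_
    truth[[i]] <- data.frame(
      gene_id = gid, chrom = chrom, strand = strand, has_pa = has_pa[i],
      pa_position = pa_pos, d3_length = d3_len, upstream_length = up_len,
      le_start = le[1], le_end = le[2], utr_start = utr[1], utr_end = utr[2],
      stringsAsFactors = FALSE)
    if (has_pa[i])
      sites[[i]] <- data.frame(chrom = chrom, strand = strand,
                               position = pa_pos, gene_id = gid,
                               stringsAsFactors = FALSE)
    cursor <- max(ends) + 1000
  }
  pa_sites <- do.call(rbind, sites[!vapply(sites, is.null, logical(1))])
  if (is.null(pa_sites))
    pa_sites <- data.frame(chrom = character(0), strand = character(0),
                           position = numeric(0), gene_id = character(0))
  list(models = models, pa_sites = pa_sites,
       truth = do.call(rbind, truth), chrom_length = cursor + 1000)
}

#' Simulate an aligned read set with a planted isoform mixture
#'
#' A fraction `pi` of a gene's transcript molecules are the long isoform
#' (covering the d3'UTR; genes without a pA are always "long"). Reads are
#' drawn uniformly over all (molecule, start) pairs -- i.e. molecules
#' contribute reads in proportion to their number of valid start positions,
#' the standard length-weighted sampling of shotgun RNA-seq -- with each read
#' contained in one exonic segment. Reads are 50 b single-end with random
#' strand (unstranded library).
#'
#' @param annotation Output of [simulate_annotation()].
#' @param pi Long-isoform fraction: scalar or named per-gene vector.
#' @param reads_per_gene Expected reads per gene: scalar or named vector.
#' @param read_length Read length in bases (default 50).
#' @param poisson Draw per-gene read totals from a Poisson around
#'   `reads_per_gene` (`TRUE`, default) or use them exactly.
#' @param seed Integer seed.
#' @param sample_id Sample label (attached as metadata).
#' @return A `GRanges` of reads with seqlengths set.
#' @export
simulate_reads <- function(annotation, pi = 0.5, reads_per_gene = 200,
                           read_length = 50, poisson = TRUE, seed = 1,
                           sample_id = "sample") {
  set.seed(seed)
  tr <- annotation$truth
  ids <- tr$gene_id
  pi_g <- if (length(pi) == 1) stats::setNames(rep(pi, nrow(tr)), ids)
          else pi[ids]
  n_g <- if (length(reads_per_gene) == 1)
    stats::setNames(rep(reads_per_gene, nrow(tr)), ids)
  else reads_per_gene[ids]
  if (poisson) n_g <- stats::setNames(stats::rpois(nrow(tr), n_g), ids)
  starts_all <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    n <- n_g[i]
    if (n == 0) next
    g <- annotation$models[[i]]
    ex <- g$exons
    # long-isoform segments: every exon; short isoform truncates the last
    # exon at the pA (transcript orientation)
    seg_long <- ex
    seg_short <- ex
    if (tr$has_pa[i]) {
      le_row <- which(ex[, 1] == tr$le_start[i])
      if (tr$strand[i] == "+") seg_short[le_row, 2] <- tr$pa_position[i]
      else seg_short[le_row, 1] <- tr$pa_position[i]
      seg_weight <- function(s) sum(pmax(s[, 2] - s[, 1] - read_length + 1, 0))
      w_long <- pi_g[i] * seg_weight(seg_long)
      w_short <- (1 - pi_g[i]) * seg_weight(seg_short)
      n_long <- stats::rbinom(1, n, w_long / (w_long + w_short))
    } else n_long <- n
    draw <- function(segs, m) {
      if (m == 0) return(numeric(0))
      w <- pmax(segs[, 2] - segs[, 1] - read_length + 1, 0)
      if (sum(w) == 0) return(numeric(0))
      sel <- sample.int(nrow(segs), m, replace = TRUE, prob = w)
      segs[sel, 1] + floor(stats::runif(m) * w[sel])
    }
    starts_all[[i]] <- c(draw(seg_long, n_long), draw(seg_short, n - n_long))
  }
  starts <- unlist(starts_all)
  n_reads <- length(starts)
  gr <- GenomicRanges::GRanges(
    seqnames = tr$chrom[1],
    ranges = IRanges::IRanges(start = starts + 1, width = read_length),
    strand = sample(c("+", "-"), n_reads, replace = TRUE))
  GenomeInfoDb::seqlengths(gr) <- annotation$chrom_length
  S4Vectors::metadata(gr)$sample_id <- sample_id
  gr
}

#' Write reads as SAM
#'
#' Minimal valid single-end SAM: `@HD`/`@SQ` header, flag 0/16 by strand,
#' simple `<len>M` CIGAR, `*` sequence and quality.
#'
#' @param reads `GRanges` of reads with seqlengths.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path) {
  sl <- GenomeInfoDb::seqlengths(reads)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
  flag <- ifelse(as.character(GenomicRanges::strand(reads)) == "-", 16L, 0L)
  body <- sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                  seq_along(reads), flag,
                  as.character(GenomicRanges::seqnames(reads)),
                  GenomicRanges::start(reads),
                  GenomicRanges::width(reads))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write reads as 6-column BED
#'
#' @param reads `GRanges` of reads.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%d\tr%06d\t0\t%s",
                   as.character(GenomicRanges::seqnames(reads)),
                   GenomicRanges::start(reads) - 1L,
                   GenomicRanges::end(reads),
                   seq_along(reads),
                   as.character(GenomicRanges::strand(reads)))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a multi-tissue expression matrix with planted restriction
#'
#' Plants tissue-specific genes (one high tissue), tissue-selective genes
#' (2-4 high tissues) and flat genes, with multiplicative log-normal noise.
#'
#' @param n_genes Total genes (default 300).
#' @param n_specific,n_selective Planted counts (defaults 30 and 30).
#' @param tissues Tissue names (default 22 generic tissues).
#' @param signal High-tissue expression level (default 100).
#' @param background Background level in other tissues (default 2; signal to
#'   background 50).
#' @param flat_level Expression of flat genes in every tissue (default 20).
#' @param noise_sdlog Log-normal noise sd (default 0.3; 0 for noiseless).
#' @param seed Integer seed.
#' @return List: `matrix` (genes x tissues), `truth` (data frame `gene_id`,
#'   `label`, `tissues`).
#' @export
simulate_tissue_matrix <- function(n_genes = 300, n_specific = 30,
                                   n_selective = 30,
                                   tissues = sprintf("tissue_%02d", 1:22),
                                   signal = 100, background = 2,
                                   flat_level = 20, noise_sdlog = 0.3,
                                   seed = 1) {
  stopifnot(n_specific + n_selective <= n_genes)
  set.seed(seed)
  nt <- length(tissues)
  ids <- sprintf("g%04d", seq_len(n_genes))
  mat <- matrix(flat_level, n_genes, nt, dimnames = list(ids, tissues))
  label <- rep("unassigned", n_genes)
  tagged <- character(n_genes)
  spec_idx <- seq_len(n_specific)
  sel_idx <- seq_len(n_selective) + n_specific
  for (i in spec_idx) {
    t1 <- sample(tissues, 1)
    mat[i, ] <- background
    mat[i, t1] <- signal
    label[i] <- "specific"; tagged[i] <- t1
  }
  for (i in sel_idx) {
    k <- sample(2:4, 1)
    ts <- sample(tissues, k)
    mat[i, ] <- background
    mat[i, ts] <- signal
    label[i] <- "selective"; tagged[i] <- paste(sort(ts), collapse = ",")
  }
  if (noise_sdlog > 0)
    mat <- mat * exp(matrix(stats::rnorm(n_genes * nt, 0, noise_sdlog),
                            n_genes, nt))
  list(matrix = mat,
       truth = data.frame(gene_id = ids, label = label, tissues = tagged,
                          stringsAsFactors = FALSE))
}

#' Simulate a probe intensity table with planted d3'UTR ratio shifts
#'
#' Probes are placed inside the split features of each gene (upstream probes
#' in the upstream last-exon segment, d3'UTR probes in the d3'UTR). Intensity
#' is gene expression, scaled in the d3'UTR by the planted condition ratio,
#' under multiplicative log-normal noise; replicate columns `a_1..a_r`,
#' `b_1..b_r`.
#'
#' @param features Split-feature data frame (genes without a d3utr feature
#'   get upstream-style probes only and end up excluded downstream).
#' @param ratio_a,ratio_b Named planted d3'UTR levels per condition (genes
#'   absent from the vectors default to 0.5).
#' @param n_upstream Upstream probes per gene (default 3).
#' @param n_d3_range d3'UTR probes per gene, inclusive range (default 2-4).
#' @param frac_single_d3 Fraction of genes demoted to a single d3'UTR probe,
#'   to exercise the exclusion rule (default 0).
#' @param expression_meanlog,expression_sdlog Per-gene log-normal expression
#'   (defaults log(100), 0.5).
#' @param noise_sdlog Per-probe/replicate log-normal noise sd (default 0.05).
#' @param replicates Replicate arrays per condition (default 2).
#' @param seed Integer seed.
#' @return Probe table data frame (see [read_probe_table()]).
#' @export
simulate_probes <- function(features, ratio_a, ratio_b, n_upstream = 3,
                            n_d3_range = c(2, 4), frac_single_d3 = 0,
                            expression_meanlog = log(100),
                            expression_sdlog = 0.5, noise_sdlog = 0.05,
                            replicates = 2, seed = 1) {
  set.seed(seed)
  genes <- unique(features$gene_id)
  single <- sample(genes, round(frac_single_d3 * length(genes)))
  cols <- c(paste0("a_", seq_len(replicates)),
            paste0("b_", seq_len(replicates)))
  rows <- vector("list", length(genes))
  probe_width <- 25
  place <- function(feat, m) {
    # m probe start positions spread inside one feature
    span <- feat$end - feat$start - probe_width
    feat$start + round(seq(0.1, 0.9, length.out = m) * span)
  }
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    fs <- features[features$gene_id == g, , drop = FALSE]
    up <- fs[fs$kind == "upstream_last_exon", , drop = FALSE]
    d3 <- fs[fs$kind == "d3utr", , drop = FALSE]
    if (nrow(up) == 0) up <- fs[fs$kind == "other_exon", , drop = FALSE][1, ]
    n_d3 <- if (nrow(d3) == 0) 0
            else if (g %in% single) 1
            else sample(seq(n_d3_range[1], n_d3_range[2]), 1)
    starts <- c(place(up[1, ], n_upstream),
                if (n_d3 > 0) place(d3[1, ], n_d3))
    kind <- c(rep("upstream", n_upstream), rep("d3", n_d3))
    expr <- stats::rlnorm(1, expression_meanlog, expression_sdlog)
    ra <- if (g %in% names(ratio_a)) ratio_a[[g]] else 0.5
    rb <- if (g %in% names(ratio_b)) ratio_b[[g]] else 0.5
    base <- cbind(
      matrix(rep(ifelse(kind == "d3", expr * ra, expr), replicates),
             ncol = replicates),
      matrix(rep(ifelse(kind == "d3", expr * rb, expr), replicates),
             ncol = replicates))
    noise <- exp(matrix(stats::rnorm(length(base), 0, noise_sdlog),
                        nrow = nrow(base)))
    intens <- base * noise
    colnames(intens) <- cols
    rows[[gi]] <- cbind(
      data.frame(probe_id = sprintf("%s_p%02d", g, seq_along(starts)),
                 gene_id = g, chrom = up$chrom[1], start = starts,
                 end = starts + probe_width, stringsAsFactors = FALSE),
      as.data.frame(intens))
  }
  do.call(rbind, rows)
}

#' Simulate replicate-level probe ratios under the null
#'
#' Gaussian replicate-level d3'UTR ratios with no condition effect, for
#' calibration studies of the per-gene direction test and the imbalance test.
#'
#' @param n_genes Genes per arm (default 500).
#' @param replicates Replicates per condition (default 2).
#' @param mean_ratio,sd Ratio mean and replicate noise sd (defaults 0.5,
#'   0.05).
#' @return List of two matrices `a`, `b` (genes x replicates).
#' @export
simulate_null_ratios <- function(n_genes = 500, replicates = 2,
                                 mean_ratio = 0.5, sd = 0.05) {
  list(a = matrix(stats::rnorm(n_genes * replicates, mean_ratio, sd),
                  n_genes, replicates),
       b = matrix(stats::rnorm(n_genes * replicates, mean_ratio, sd),
                  n_genes, replicates))
}

#' Simulate a transcription-shutoff decay time course
#'
#' Per-gene counts follow first-order decay,
#' `Poisson(expression x 2^(-t / half-life))`, with class-dependent
#' half-lives; the untreated control is `Poisson(expression)`. Library sizes
#' are the realized totals.
#'
#' @param classes Named numeric vector of half-lives in hours (use `Inf` for
#'   stable anchors); default `c(short = 2, long = 6, stable = Inf)`.
#' @param n_per_class Genes per class (default 200).
#' @param timepoints Hours after shutoff (default `c(3, 6, 12)`).
#' @param expression_meanlog,expression_sdlog Per-gene log-normal expression
#'   (defaults log(200), 1).
#' @param seed Integer seed.
#' @return List: `treated` (named list of gene-level `count_table`s by
#'   timepoint), `control`, `truth` (data frame `gene_id`, `class`,
#'   `half_life`).
#' @export
simulate_decay <- function(classes = c(short = 2, long = 6, stable = Inf),
                           n_per_class = 200, timepoints = c(3, 6, 12),
                           expression_meanlog = log(200),
                           expression_sdlog = 1, seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  ids <- sprintf("g%04d", seq_len(n))
  class <- rep(names(classes), each = n_per_class)
  hl <- rep(unname(classes), each = n_per_class)
  expr <- stats::rlnorm(n, expression_meanlog, expression_sdlog)
  make_table <- function(mu, sid) {
    counts <- stats::rpois(n, mu)
    names(counts) <- ids
    count_table(counts, library_size = sum(counts), sample_id = sid)
  }
  control <- make_table(expr, "t0")
  treated <- lapply(timepoints, function(tp)
    make_table(expr * 2^(-tp / hl), paste0("t", tp)))
  names(treated) <- as.character(timepoints)
  list(treated = treated, control = control,
       truth = data.frame(gene_id = ids, class = class, half_life = hl,
                          stringsAsFactors = FALSE))
}

#' Simulate a CLIP-style coverage track with peaks at polyA sites
#'
#' Uniform background plus Gaussian-shaped peaks of configured height at the
#' proximal pAs (or the distal 3'UTR boundaries) of a subset of genes.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param at `"proximal"` (planted pAs), `"distal"` (distal boundaries) or
#'   `"none"`.
#' @param peak_height Peak height above background (default 10).
#' @param peak_sd Gaussian peak sd in bases (default 25).
#' @param background Uniform background density (default 1).
#' @param genes Optional subset of gene ids carrying peaks.
#' @return An `RleList` coverage track.
#' @export
simulate_clip <- function(annotation, at = c("proximal", "distal", "none"),
                          peak_height = 10, peak_sd = 25, background = 1,
                          genes = NULL) {
  at <- match.arg(at)
  len <- annotation$chrom_length
  dens <- rep(background, len)
  tr <- annotation$truth
  if (!is.null(genes)) tr <- tr[tr$gene_id %in% genes, , drop = FALSE]
  if (at != "none") {
    centres <- if (at == "proximal") tr$pa_position[tr$has_pa]
      else ifelse(tr$strand == "+", tr$utr_end, tr$utr_start)
    centres <- centres[!is.na(centres)]
    half <- 4 * peak_sd
    for (c0 in centres) {
      idx <- max(1, c0 + 1 - half):min(len, c0 + 1 + half)
      dens[idx] <- dens[idx] +
        peak_height * exp(-((idx - (c0 + 1))^2) / (2 * peak_sd^2))
    }
  }
  out <- IRanges::RleList(S4Vectors::Rle(dens))
  names(out) <- tr$chrom[1] %||% "chrS"
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Write a coverage track as bedGraph
#'
#' @param track `RleList` coverage.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- methods::as(track, "GRanges")
  names(S4Vectors::mcols(gr)) <- "score"
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
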