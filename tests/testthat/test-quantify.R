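# Strict-containment counting, RPKM, d3'UTR ratios, differential expression.

test_that("a read counts iff strictly contained in the feature", {
  f <- make_features(list("g1", "d3utr", 100, 300))
  tab <- count_contained_reads(make_reads(c(150, 90, 100, 250, 251),
                                          width = 50), f)
  # [150,200) in, [90,140) out, [100,150) in, [250,300) in, [251,301) out
  expect_equal(unname(tab$counts), 3L)
  expect_equal(tab$library_size, 5)
})

test_that("empty read list gives zero counts and zero library size", {
  f <- make_features(list("g1", "d3utr", 100, 300))
  tab <- count_contained_reads(make_reads(numeric(0)), f)
  expect_equal(unname(tab$counts), 0L)
  expect_equal(tab$library_size, 0)
})

test_that("counting equals the brute-force containment oracle", {
  set.seed(42)
  for (rep in 1:5) {
    starts <- sort(sample(0:2000, 200, replace = TRUE))
    widths <- sample(20:80, 200, replace = TRUE)
    fs <- sort(sample(0:1800, 5))
    feats <- make_features(
      list("g1", "other_exon", fs[1], fs[1] + 400),
      list("g2", "other_exon", fs[2], fs[2] + 150),
      list("g3", "other_exon", fs[3], fs[3] + 700),
      list("g4", "other_exon", fs[4], fs[4] + 60),
      list("g5", "other_exon", fs[5], fs[5] + 250))
    reads <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = starts + 1, width = widths),
      strand = sample(c("+", "-"), 200, TRUE))
    got <- count_contained_reads(reads, feats)$counts
    want <- brute_force_counts(starts, starts + widths, rep("chr1", 200),
                               feats)
    expect_equal(unname(got), unname(want))
  }
})

test_that("dedup collapses (chrom, 5' start, strand) and is idempotent", {
  r <- c(make_reads(c(10, 10, 10, 50), strand = "+"),
         make_reads(10, strand = "-"))
  d1 <- dedup_reads(r)
  expect_length(d1, 3)   # 10+, 50+, 10-
  expect_identical(dedup_reads(d1), d1)
  # minus-strand 5' end is the interval end
  m <- c(make_reads(10, width = 50, strand = "-"),
         make_reads(20, width = 40, strand = "-"))  # both end at 60
  expect_length(dedup_reads(m), 1)
})

test_that("rpkm formula and scale equivariance", {
  f <- make_features(list("g1", "d3utr", 0, 500))
  tab <- count_table(c(`g1:d3utr` = 100L), library_size = 1e6)
  expect_equal(unname(compute_rpkm(tab, f)), 200)
  tab0 <- count_table(c(`g1:d3utr` = 0L), library_size = 1e6)
  expect_equal(unname(compute_rpkm(tab0, f)), 0)
  tab2 <- count_table(c(`g1:d3utr` = 100L), library_size = 2e6)
  expect_equal(unname(compute_rpkm(tab2, f)), 100)
  expect_error(compute_rpkm(count_table(c(`g1:d3utr` = 0L), 0), f),
               "positive")
})

test_that("d3'UTR ratio arithmetic, NA propagation and pairing", {
  f <- make_features(list("g1", "upstream_last_exon", 0, 500),
                     list("g1", "d3utr", 500, 800),
                     list("g2", "upstream_last_exon", 1000, 1500),
                     list("g2", "d3utr", 1500, 1800),
                     list("g3", "upstream_last_exon", 2000, 2500))
  counts <- c(100L, 30L, 0L, 10L, 5L)
  names(counts) <- f$feature_id
  tab <- count_table(counts, library_size = 1e6)
  expect_warning(r <- compute_d3utr_ratios(tab, f), "g3")
  r1 <- r[r$gene_id == "g1", ]
  expect_equal(r1$upstream_rpkm, 200)
  expect_equal(r1$d3utr_rpkm, 100)
  expect_equal(r1$ratio, 0.5)
  expect_true(is.na(r[r$gene_id == "g2", "ratio"]))  # upstream count 0
  expect_false("g3" %in% r$gene_id)
  # equal rpkm in both regions -> ratio 1
  counts2 <- c(50L, 30L, 50L, 30L, 0L); names(counts2) <- f$feature_id
  r2 <- suppressWarnings(compute_d3utr_ratios(
    count_table(counts2, 1e6), f))
  expect_equal(r2$ratio[r2$gene_id == "g1"], 1)
})

test_that("identical tables give unit fold-changes and size factors", {
  counts <- stats::setNames(as.integer(10 + seq_len(60) * 3),
                            sprintf("g%02d", 1:60))
  a <- count_table(counts, sum(counts), "a")
  de <- differential_expression(a, a)
  expect_equal(de$fc, rep(1, 60))
  expect_equal(de$mean_a, de$mean_b)
  expect_equal(unname(de$mean_a), unname(as.numeric(counts)))
})

test_that("median-of-ratios normalization matches the hand oracle", {
  ca <- c(10L, 20L, 30L, 40L, 50L, 60L)
  cb <- c(10L, 20L, 90L, 40L, 50L, 60L)
  names(ca) <- names(cb) <- paste0("g", 1:6)
  de <- differential_expression(count_table(ca, 210), count_table(cb, 270),
                                min_genes = 5)
  # oracle: ref = sqrt(ca*cb); sf = median(c/ref); normalized fc per gene
  ref <- sqrt(ca * cb)
  sfa <- median(ca / ref); sfb <- median(cb / ref)
  want_fc <- (cb / sfb + 0.5) / (ca / sfa + 0.5)
  expect_equal(de$fc, unname(want_fc))
  expect_equal(de$fc[3], (90 + 0.5) / (30 + 0.5))  # sf = 1 here
  expect_gt(de$fc[3], 2.9)
})

test_that("zero count in one sample stays finite via the pseudocount", {
  ca <- stats::setNames(c(0L, rep(20L, 59)), sprintf("g%02d", 1:60))
  cb <- stats::setNames(c(40L, rep(20L, 59)), sprintf("g%02d", 1:60))
  de <- differential_expression(count_table(ca, sum(ca)),
                                count_table(cb, sum(cb)))
  expect_true(all(is.finite(de$fc)))
  expect_equal(de$fc[1], 40.5 / 0.5)
})

test_that("too few shared expressed genes is an error", {
  ca <- stats::setNames(rep(c(0L, 5L), c(30, 10)), sprintf("g%02d", 1:40))
  expect_error(differential_expression(count_table(ca, 50),
                                       count_table(ca, 50)),
               "size factors")
})

test_that("sensitivity labels follow the fold-change and p thresholds", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    fc = c(3.5, 1.5, 2.5, 3.5, 0.4),
                    p = c(0.001, 0.5, 0.5, 0.5, 0.2))
  lab <- classify_aire_sensitivity(rec)$label
  expect_equal(lab, c("sensitive", "neutral", "unassigned", "unassigned",
                      "unassigned"))
})

test_that("estimated ratio converges to the planted isoform fraction", {
  ann <- simulate_annotation(n_genes = 12, pa_fraction = 1, seed = 21)
  set.seed(21)
  pi_g <- stats::setNames(runif(12, 0.1, 0.9), ann$truth$gene_id)
  sp <- build_split_annotation(ann$models, ann$pa_sites)
  for (sd in c(1, 2)) {
    reads <- simulate_reads(ann, pi = pi_g, reads_per_gene = 20000,
                            poisson = FALSE, seed = sd)
    r <- compute_d3utr_ratios(count_contained_reads(reads, sp$features),
                              sp$features)
    err <- abs(stats::setNames(r$ratio, r$gene_id)[names(pi_g)] - pi_g)
    expect_lt(mean(err), 0.03)
  }
})

test_that("ratios are stable under 50% read subsampling", {
  ann <- simulate_annotation(n_genes = 60, pa_fraction = 1, seed = 31)
  set.seed(31)
  pi_g <- stats::setNames(runif(60, 0.2, 0.8), ann$truth$gene_id)
  reads <- simulate_reads(ann, pi = pi_g, reads_per_gene = 4000, seed = 32)
  sp <- build_split_annotation(ann$models, ann$pa_sites)
  full <- compute_d3utr_ratios(count_contained_reads(reads, sp$features),
                               sp$features)
  half <- compute_d3utr_ratios(
    count_contained_reads(reads[sample(length(reads), length(reads) / 2)],
                          sp$features), sp$features)
  diff <- full$ratio - half$ratio[match(full$gene_id, half$gene_id)]
  expect_lt(abs(median(diff, na.rm = TRUE)), 0.02)
})

test_that("SAM and BED round-trip through the readers", {
  ann <- simulate_annotation(n_genes = 8, pa_fraction = 1, seed = 41)
  reads <- simulate_reads(ann, pi = 0.5, reads_per_gene = 30, seed = 42)
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, sam)
  back <- read_alignments(sam)
  expect_equal(length(back), length(reads))
  expect_equal(sort(GenomicRanges::start(back)),
               sort(GenomicRanges::start(reads)))
  expect_equal(sort(as.character(GenomicRanges::strand(back))),
               sort(as.character(GenomicRanges::strand(reads))))
  bed <- tempfile(fileext = ".bed")
  write_reads_bed(reads, bed)
  back2 <- read_alignments(bed)
  expect_equal(sort(GenomicRanges::start(back2)),
               sort(GenomicRanges::start(reads)))
})
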