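# Probe-level d3'UTR ratios, direction calls, and the imbalance test.

probe_df <- function(regions, intensities, gene = "g1") {
  data.frame(probe_id = sprintf("p%02d", seq_along(regions)),
             gene_id = gene, chrom = "chr1",
             start = seq_along(regions) * 100,
             end = seq_along(regions) * 100 + 25,
             region = regions, s1 = intensities,
             stringsAsFactors = FALSE)
}

test_that("probe ratio is mean(d3'UTR) over mean(all probes)", {
  p <- probe_df(c("d3", "d3", "up", "up", "up"), c(4, 6, 10, 10, 10))
  p$region[p$region == "d3"] <- "d3utr"
  expect_equal(probe_d3utr_ratio(p, "s1"), 0.625)   # 5 / 8
  # all probes equal -> ratio 1
  p2 <- probe_df(rep(c("d3utr", "upstream_last_exon"), c(2, 3)), rep(7, 5))
  expect_equal(probe_d3utr_ratio(p2, "s1"), 1)
  # fewer than two d3'UTR probes -> excluded
  p3 <- probe_df(c("d3utr", "upstream_last_exon", "upstream_last_exon"),
                 c(5, 5, 5))
  expect_true(is.na(probe_d3utr_ratio(p3, "s1")))
  expect_true(is.na(probe_d3utr_ratio(p3[0, ], "s1")))
})

test_that("background filter keeps probes above the quantile in all samples", {
  set.seed(1)
  df <- data.frame(probe_id = sprintf("p%03d", 1:100), gene_id = "g",
                   chrom = "chr1", start = 1:100, end = 2:101,
                   s1 = c(stats::runif(95, 10, 100), stats::runif(5, 0, 0.1)),
                   s2 = stats::runif(100, 10, 100))
  kept <- filter_expressed_probes(df, c("s1", "s2"))
  expect_lte(nrow(kept), 95)
  thr1 <- stats::quantile(df$s1, 0.05, names = FALSE)
  expect_true(all(kept$s1 > thr1))
})

test_that("probe region assignment uses containment within own gene", {
  feats <- make_features(list("g1", "upstream_last_exon", 0, 500),
                         list("g1", "d3utr", 500, 800),
                         list("g2", "d3utr", 1000, 1300))
  probes <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    gene_id = c("g1", "g1", "g1", "g2"),
    chrom = "chr1",
    start = c(100, 550, 1100, 1100),  # c is inside g2's d3utr but owned by g1
    end = c(125, 575, 1125, 1125))
  out <- assign_probe_region(probes, feats)
  expect_equal(out$region, c("upstream_last_exon", "d3utr", "unmapped",
                             "d3utr"))
})

test_that("welch_rows agrees with t.test on random data", {
  set.seed(5)
  a <- matrix(stats::rnorm(60, 5, 1), 15, 4)
  b <- matrix(stats::rnorm(45, 6, 2), 15, 3)
  w <- welch_rows(a, b)
  for (i in c(1, 7, 15)) {
    tt <- stats::t.test(b[i, ], a[i, ])
    expect_equal(w$p[i], tt$p.value)
    expect_equal(w$df[i], unname(tt$parameter))
  }
})

test_that("screen recovers planted shifts and flips under swap", {
  feats <- make_features(list("g1", "upstream_last_exon", 0, 500),
                         list("g1", "d3utr", 500, 800),
                         list("g2", "upstream_last_exon", 1000, 1500),
                         list("g2", "d3utr", 1500, 1800),
                         list("g3", "upstream_last_exon", 2000, 2500),
                         list("g3", "d3utr", 2500, 2800))
  # g1: increase 0.3 -> 0.6; g2: decrease 0.6 -> 0.3; g3: null
  probes <- simulate_probes(
    feats,
    ratio_a = c(g1 = 0.3, g2 = 0.6, g3 = 0.5),
    ratio_b = c(g1 = 0.6, g2 = 0.3, g3 = 0.5),
    noise_sdlog = 0.02, replicates = 3, seed = 8)
  probes <- assign_probe_region(probes, feats)
  sa <- paste0("a_", 1:3); sb <- paste0("b_", 1:3)
  scr <- array_screen(probes, sa, sb)
  expect_equal(scr$direction[scr$gene_id == "g1"], "increase")
  expect_equal(scr$direction[scr$gene_id == "g2"], "decrease")
  expect_equal(scr$method[1], "welch")
  swapped <- array_screen(probes, sb, sa)
  map <- c(increase = "decrease", decrease = "increase",
           not_significant = "not_significant", excluded = "excluded")
  expect_equal(unname(map[scr$direction]), swapped$direction)
})

test_that("identical conditions are never called significant", {
  feats <- make_features(list("g1", "upstream_last_exon", 0, 500),
                         list("g1", "d3utr", 500, 800))
  probes <- simulate_probes(feats, ratio_a = c(g1 = 0.5),
                            ratio_b = c(g1 = 0.5), noise_sdlog = 0,
                            seed = 2)
  probes <- assign_probe_region(probes, feats)
  scr <- array_screen(probes, c("a_1", "a_2"), c("b_1", "b_2"))
  expect_equal(scr$direction, "not_significant")
})

test_that("single-replicate designs fall back to fold-change calls", {
  feats <- make_features(list("g1", "upstream_last_exon", 0, 500),
                         list("g1", "d3utr", 500, 800),
                         list("g2", "upstream_last_exon", 1000, 1500),
                         list("g2", "d3utr", 1500, 1800))
  probes <- simulate_probes(feats, ratio_a = c(g1 = 0.2, g2 = 0.5),
                            ratio_b = c(g1 = 0.7, g2 = 0.5),
                            noise_sdlog = 0.01, replicates = 1, seed = 3)
  probes <- assign_probe_region(probes, feats)
  scr <- array_screen(probes, "a_1", "b_1")
  expect_equal(scr$method, rep("fold_change", 2))
  expect_equal(scr$direction[scr$gene_id == "g1"], "increase")
  expect_equal(scr$direction[scr$gene_id == "g2"], "not_significant")
})

test_that("imbalance chi-squared matches the textbook statistic", {
  cand <- rep(c("increase", "decrease"), c(50, 10))
  ctrl <- rep(c("increase", "decrease"), c(20, 22))
  out <- ratio_imbalance_test(cand, ctrl)
  m <- rbind(c(50, 10), c(20, 22))
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  chi <- sum((m - e)^2 / e)
  expect_equal(out$statistic, chi)
  expect_equal(out$p, stats::pchisq(chi, 1, lower.tail = FALSE))
  expect_equal(out$method, "chisq")
  # identical proportions: p ~ 1, no star
  out2 <- ratio_imbalance_test(rep(c("increase", "decrease"), c(30, 30)),
                               rep(c("increase", "decrease"), c(30, 30)))
  expect_gt(out2$p, 0.9)
  expect_equal(out2$stars, "")
})

test_that("star labels follow the published thresholds", {
  expect_equal(ratio_imbalance_test(
    rep(c("increase", "decrease"), c(40, 10)),
    rep(c("increase", "decrease"), c(12, 38)))$stars, "*")
  big <- ratio_imbalance_test(
    rep(c("increase", "decrease"), c(200, 20)),
    rep(c("increase", "decrease"), c(20, 200)))
  expect_lt(big$p, 1e-9)
  expect_equal(big$stars, "**")
})

test_that("zero margins fall back to Fisher's exact test, flagged", {
  out <- ratio_imbalance_test(rep("increase", 10),
                              rep("increase", 12))
  expect_equal(out$method, "fisher")
  expect_true(is.finite(out$p))
})

test_that("per-gene direction calls are never anti-conservative under null", {
  # Welch on duplicate arrays is conservative (~0.022 at alpha = 0.05);
  # assert the achievable guarantee: the call rate never exceeds alpha.
  set.seed(17)
  null <- simulate_null_ratios(n_genes = 20000, replicates = 2)
  w <- welch_rows(null$a, null$b)
  rate <- mean(w$p < 0.05, na.rm = TRUE)
  expect_lt(rate, 0.06)
  expect_gt(rate, 0.005)
})
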