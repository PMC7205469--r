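# Metaprofiles around polyA sites, decay ratios, shortening classes.

flat_track <- function(len = 5000, value = 2, chrom = "chrS") {
  out <- IRanges::RleList(S4Vectors::Rle(rep(value, len)))
  names(out) <- chrom
  out
}

test_that("uniform track yields a flat profile at the track value", {
  sites <- data.frame(chrom = "chrS", strand = "+",
                      position = c(1500, 2500, 3000))
  prof <- site_metaprofile(flat_track(value = 2.5), sites, window = 500,
                           binsize = 10)
  expect_equal(prof$bins, rep(2.5, 101))
  expect_equal(prof$n_sites, 3)
  expect_equal(length(prof$bins), 2 * 500 / 10 + 1)
})

test_that("delta peaks at the sites concentrate in the central bin", {
  len <- 6000
  v <- rep(0, len)
  sites <- data.frame(chrom = "chrS", strand = "+",
                      position = c(1500, 3000, 4200))
  v[sites$position + 1] <- 12   # delta of height 12 at each site
  tr <- IRanges::RleList(S4Vectors::Rle(v)); names(tr) <- "chrS"
  prof <- site_metaprofile(tr, sites, window = 300, binsize = 10)
  centre <- 300 / 10 + 1
  expect_equal(which.max(prof$bins), centre)
  # per-base central value is the peak height (all sites aligned)
  expect_equal(prof$per_base[301], 12)
  # central bin covers offsets [-5, 4] around the site
  expect_equal(prof$bins[centre], mean(prof$per_base[296:305]))
})

test_that("minus-strand windows are mirrored exactly", {
  set.seed(12)
  v <- stats::runif(4000)
  tr <- IRanges::RleList(S4Vectors::Rle(v)); names(tr) <- "chrS"
  plus <- site_metaprofile(tr, data.frame(chrom = "chrS", strand = "+",
                                          position = 2000), window = 200)
  minus <- site_metaprofile(tr, data.frame(chrom = "chrS", strand = "-",
                                           position = 2000), window = 200)
  expect_equal(minus$per_base, rev(plus$per_base))
  # binned profiles mirror only up to the half-bin phase of the bin grid,
  # so the exact reflection property is asserted per base
  expect_equal(sum(minus$bins), sum(rev(plus$bins)), tolerance = 0.05)
})

test_that("profile equals the mean of independent window extractions", {
  set.seed(13)
  v <- stats::rpois(8000, 3)
  tr <- IRanges::RleList(S4Vectors::Rle(as.numeric(v)))
  names(tr) <- "chrS"
  pos <- c(1000, 2500, 5000, 7000)
  sites <- data.frame(chrom = "chrS", strand = "+", position = pos)
  prof <- site_metaprofile(tr, sites, window = 400)
  oracle <- rowMeans(vapply(pos, function(p)
    v[(p + 1 - 400):(p + 1 + 400)], numeric(801)))
  expect_equal(prof$per_base, oracle)
})

test_that("sites too close to the edge are skipped with a warning", {
  sites <- data.frame(chrom = "chrS", strand = "+", position = c(100, 2500))
  expect_warning(prof <- site_metaprofile(flat_track(), sites, window = 500),
                 "skipped")
  expect_equal(prof$n_sites, 1)
  expect_error(suppressWarnings(site_metaprofile(
    flat_track(), data.frame(chrom = "chrS", strand = "+", position = 100),
    window = 500)), "no usable site")
})

test_that("decay relative expression follows the normalization arithmetic", {
  mk <- function(counts, lib, id) count_table(
    stats::setNames(as.integer(counts), paste0("g", seq_along(counts))),
    lib, id)
  # 100 reads in 1M treated vs 200 in 2M control -> exactly 1 (no pseudocount)
  rel <- decay_relative_expression(list(`3` = mk(c(100, 50), 1e6, "t3")),
                                   mk(c(200, 100), 2e6, "t0"),
                                   pseudocount = 0)
  expect_equal(rel$rel_expr, c(1, 1))
  # identical tables -> all 1 (pseudocount cancels)
  ctl <- mk(c(10, 20, 30), 1e5, "t0")
  rel2 <- decay_relative_expression(list(`3` = ctl), ctl)
  expect_equal(rel2$rel_expr, rep(1, 3))
  # invariance to rescaling counts and library together
  big <- mk(c(1000, 2000, 3000), 1e7, "t3")
  rel3 <- decay_relative_expression(list(`3` = big), ctl, pseudocount = 0)
  rel4 <- decay_relative_expression(list(`3` = mk(c(10, 20, 30), 1e5, "t3")),
                                    ctl, pseudocount = 0)
  expect_equal(rel3$rel_expr, rel4$rel_expr)
})

test_that("simulated first-order decay halves by one half-life", {
  sim <- simulate_decay(classes = c(h3 = 3, stable = Inf),
                        n_per_class = 400, timepoints = 3, seed = 19)
  rel <- decay_relative_expression(sim$treated, sim$control)
  cls <- stats::setNames(sim$truth$class, sim$truth$gene_id)
  anchor <- stats::median(rel$rel_expr[cls[rel$gene_id] == "stable"])
  m3 <- stats::median(rel$rel_expr[cls[rel$gene_id] == "h3"])
  expect_equal(m3 / anchor, 0.5, tolerance = 0.05)
})

test_that("shortening classes follow the 0.5x and steady-band rules", {
  expect_equal(classify_shortening(0.2, 0.5), "decreased")
  expect_equal(classify_shortening(0.3, 0.3), "steady")
  expect_equal(classify_shortening(0.25, 0.5), "other")  # exactly 0.5: strict
  expect_equal(classify_shortening(0.5, 0.25), "other")
  expect_equal(classify_shortening(c(0.2, NA), c(0.5, 0.5)),
               c("decreased", NA))
  expect_true(is.na(classify_shortening(0.3, 0)))
})

test_that("group decay comparison: identical groups, small groups, power", {
  set.seed(23)
  rel <- data.frame(gene_id = rep(sprintf("g%03d", 1:40), 2),
                    timepoint = rep(c(3, 6), each = 40),
                    rel_expr = stats::runif(80))
  grp <- stats::setNames(rep(c("decreased", "steady"), 20),
                         sprintf("g%03d", 1:40))
  # same distribution in both groups: no rejection expected
  out <- compare_decay_groups(rel, grp)
  expect_equal(nrow(out$tests), 2)
  expect_true(all(out$tests$p > 0.01))
  # group smaller than 3 -> NA p
  grp2 <- grp
  grp2[grp2 == "decreased"] <- "steady"
  grp2[1:2] <- "decreased"
  out2 <- compare_decay_groups(rel, grp2)
  expect_true(all(is.na(out2$tests$p)))
  # planted half-life separation is detected
  sim <- simulate_decay(classes = c(decreased = 6, steady = 2),
                        n_per_class = 150, timepoints = c(3, 6), seed = 29)
  rel3 <- decay_relative_expression(sim$treated, sim$control)
  cmp <- compare_decay_groups(rel3,
                              stats::setNames(sim$truth$class,
                                              sim$truth$gene_id))
  expect_true(all(cmp$tests$p < 0.01))
  med <- cmp$medians
  for (tp in c(3, 6))
    expect_gt(med$rel_expr[med$group == "decreased" & med$timepoint == tp],
              med$rel_expr[med$group == "steady" & med$timepoint == tp])
})

test_that("bedGraph round-trips through the coverage reader", {
  ann <- simulate_annotation(n_genes = 6, pa_fraction = 1, seed = 33)
  tr <- simulate_clip(ann, at = "proximal", peak_height = 8)
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  back <- read_coverage_track(path)
  expect_equal(as.numeric(back[[1]]),
               as.numeric(tr[[1]])[seq_len(length(back[[1]]))],
               tolerance = 1e-6)
})
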