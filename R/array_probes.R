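# Probe-level microarray d3'UTR analysis: per-gene probe ratios, per-gene
# direction calls between two conditions, and the genome-wide increase vs
# decrease imbalance chi-squared test.

#' Filter probes expressed above background
#'
#' A probe is retained only if its intensity exceeds the background threshold
#' (the `bg_quantile` quantile of all probe intensities of that sample) in
#' every compared sample.
#'
#' @param probes Probe table: `probe_id`, `gene_id`, `chrom`, `start`, `end`
#'   plus one intensity column per sample (linear scale).
#' @param samples Names of the intensity columns to consider.
#' @param bg_quantile Background quantile (default 0.05).
#' @return The filtered probe table.
#' @export
filter_expressed_probes <- function(probes, samples, bg_quantile = 0.05) {
  keep <- rep(TRUE, nrow(probes))
  for (s in samples) {
    thr <- stats::quantile(probes[[s]], bg_quantile, names = FALSE)
    keep <- keep & probes[[s]] > thr
  }
  probes[keep, , drop = FALSE]
}

#' Map probes to split-annotation regions
#'
#' A probe belongs to a region iff its interval lies within the corresponding
#' feature of its own gene. Probes matching no feature are labelled
#' `"unmapped"`.
#'
#' @param probes Probe table (0-based half-open `start`/`end`).
#' @param features Split-feature data frame.
#' @return `probes` with an added `region` column.
#' @export
assign_probe_region <- function(probes, features) {
  region <- rep("unmapped", nrow(probes))
  key <- split(seq_len(nrow(features)), features$gene_id)
  for (i in seq_len(nrow(probes))) {
    idx <- key[[probes$gene_id[i]]]
    if (is.null(idx)) next
    hit <- idx[features$chrom[idx] == probes$chrom[i] &
               features$start[idx] <= probes$start[i] &
               features$end[idx] >= probes$end[i]]
    if (length(hit)) region[i] <- features$kind[hit[1]]
  }
  probes$region <- region
  probes
}

#' Probe-level d3'UTR ratio of one gene in one sample
#'
#' Mean intensity of the d3'UTR probes divided by the mean intensity of all
#' probes of the transcript (linear scale). Genes with fewer than
#' `min_d3_probes` d3'UTR probes are excluded (`NA`).
#'
#' @param gene_probes Probe rows of one gene, with a `region` column.
#' @param sample Intensity column name.
#' @param min_d3_probes Minimum d3'UTR probes (default 2).
#' @return Ratio, or `NA_real_` when excluded.
#' @export
probe_d3utr_ratio <- function(gene_probes, sample, min_d3_probes = 2) {
  if (nrow(gene_probes) == 0) return(NA_real_)
  d3 <- gene_probes$region == "d3utr"
  if (sum(d3) < min_d3_probes) return(NA_real_)
  mean(gene_probes[[sample]][d3]) / mean(gene_probes[[sample]])
}

#' Row-wise Welch t-tests
#'
#' Vectorized Welch two-sample t-test between the rows of two matrices
#' (replicates in columns). Used for per-gene direction calls and for the
#' null-calibration simulations.
#'
#' @param a,b Numeric matrices with the same number of rows.
#' @return Data frame with `delta` (rowMeans(b) - rowMeans(a)), `t`, `df`,
#'   `p` (two-sided).
#' @export
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- (rowSums(a * a) - na * ma^2) / (na - 1)
  vb <- (rowSums(b * b) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(delta = mb - ma, t = t, df = df, p = p)
}

#' Per-gene d3'UTR ratio change between two conditions
#'
#' With at least two replicate arrays per condition, the per-replicate
#' probe-level ratios are compared by a Welch t-test at level `alpha` and the
#' direction is the sign of the mean ratio change. With a missing replicate
#' the call falls back to a fold-change-only rule
#' (|log2 change| > log2 `fc_fallback`), flagged in `method`.
#'
#' @param probes Probe table with `region` assigned and background-filtered.
#' @param samples_a,samples_b Replicate intensity columns per condition.
#' @param alpha Significance level (default 0.05).
#' @param fc_fallback Fold-change threshold for the fallback (default 1.5).
#' @param min_d3_probes Minimum d3'UTR probes per gene (default 2).
#' @return Data frame: `gene_id`, `n_d3_probes`, `ratio_a`, `ratio_b`, `p`,
#'   `direction` in `{increase, decrease, not_significant, excluded}`,
#'   `method` in `{welch, fold_change}`.
#' @export
array_screen <- function(probes, samples_a, samples_b, alpha = 0.05,
                         fc_fallback = 1.5, min_d3_probes = 2) {
  genes <- sort(unique(probes$gene_id))
  per_gene <- split(probes, probes$gene_id)
  n_a <- length(samples_a); n_b <- length(samples_b)
  ra <- matrix(NA_real_, length(genes), n_a)
  rb <- matrix(NA_real_, length(genes), n_b)
  n_d3 <- integer(length(genes))
  for (i in seq_along(genes)) {
    gp <- per_gene[[genes[i]]]
    n_d3[i] <- sum(gp$region == "d3utr")
    ra[i, ] <- vapply(samples_a, function(s)
      probe_d3utr_ratio(gp, s, min_d3_probes), numeric(1))
    rb[i, ] <- vapply(samples_b, function(s)
      probe_d3utr_ratio(gp, s, min_d3_probes), numeric(1))
  }
  ratio_a <- rowMeans(ra); ratio_b <- rowMeans(rb)
  excluded <- is.na(ratio_a) | is.na(ratio_b)
  use_welch <- n_a >= 2 && n_b >= 2
  if (use_welch) {
    w <- welch_rows(ra, rb)
    p <- w$p; delta <- w$delta
    sig <- !is.na(p) & p < alpha
    method <- "welch"
  } else {
    delta <- ratio_b - ratio_a
    p <- NA_real_
    sig <- abs(log2(ratio_b / ratio_a)) > log2(fc_fallback)
    method <- "fold_change"
  }
  direction <- ifelse(excluded, "excluded",
                ifelse(sig & delta > 0, "increase",
                 ifelse(sig & delta < 0, "decrease", "not_significant")))
  data.frame(gene_id = genes, n_d3_probes = n_d3, ratio_a = ratio_a,
             ratio_b = ratio_b, p = p, direction = direction,
             method = method, stringsAsFactors = FALSE)
}

#' Increase vs decrease imbalance test between two screens
#'
#' 2x2 chi-squared (without continuity correction) on the {increase, decrease}
#' counts of the candidate and control comparisons. When any margin is zero
#' the test falls back to Fisher's exact test, flagged in `method`. Star
#' labels follow `*` p < 1e-4, `**` p < 1e-9.
#'
#' @param candidate,control Direction vectors (or data frames with a
#'   `direction` column).
#' @return List: `table` (2x2 counts), `statistic`, `p`, `stars`, `method`.
#' @export
ratio_imbalance_test <- function(candidate, control) {
  dirs <- function(x) if (is.data.frame(x)) x$direction else x
  cnt <- function(x) c(increase = sum(dirs(x) == "increase"),
                       decrease = sum(dirs(x) == "decrease"))
  m <- rbind(candidate = cnt(candidate), control = cnt(control))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    p <- stats::fisher.test(m + 0L)$p.value
    stat <- NA_real_
    method <- "fisher"
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    p <- ct$p.value
    stat <- unname(ct$statistic)
    method <- "chisq"
  }
  stars <- if (p < 1e-9) "**" else if (p < 1e-4) "*" else ""
  list(table = m, statistic = stat, p = p, stars = stars, method = method)
}

#' Read a probe intensity table
#'
#' @param path Tab-delimited file: `probe_id`, `gene_id`, `chrom`, `start`,
#'   `end`, one column per sample.
#' @return Data frame.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "gene_id", "chrom", "start", "end")
  if (!all(req %in% names(df)))
    stop("probe table must start with columns: ", paste(req, collapse = ", "))
  df
}
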