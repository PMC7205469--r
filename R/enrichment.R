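# Classic-scheme (unweighted Kolmogorov-Smirnov) gene set enrichment analysis,
# leading-edge summarization, and miRNA conserved-site filtering against
# d3'UTR regions.

#' Rank a metric vector for GSEA
#'
#' Zero-metric genes are removed; the rest are sorted by decreasing metric,
#' ties broken by gene id (lexicographic) for determinism.
#'
#' @param metric Named numeric vector (e.g. log2 fold-change of normalized
#'   counts).
#' @return Named numeric vector, ranked.
#' @export
rank_metric <- function(metric) {
  metric <- metric[metric != 0 & !is.na(metric)]
  metric[order(-metric, names(metric), method = "radix")]
}

#' Classic enrichment score of one gene set
#'
#' Unweighted running sum over the ranked list: each hit adds `1/N_hit`, each
#' miss subtracts `1/(N - N_hit)`. The enrichment score is the running-sum
#' value of largest magnitude, so `|es| <= 1`; when the positive and negative
#' extrema tie exactly, the positive one is taken. The running sum is scored
#' in exact integer arithmetic (`h*N - i*N_hit` over `N_hit*(N - N_hit)`), so
#' ties are resolved deterministically, free of floating-point noise.
#'
#' @param hit_positions Integer ranks (1-based) of the set members in the
#'   ranked list.
#' @param n Length of the ranked list.
#' @return List: `es`, `arg` (rank where the extremum is attained).
#' @export
gsea_es <- function(hit_positions, n) {
  k <- length(hit_positions)
  if (k == 0 || k >= n) stop("set must be a proper non-empty subset")
  step <- rep(-k, n)
  step[hit_positions] <- n - k
  s <- cumsum(step)            # integer-valued numerator, exact in doubles
  mx <- max(s); mn <- min(s)
  if (mx >= -mn) list(es = mx / (k * (n - k)), arg = which.max(s))
  else list(es = mn / (k * (n - k)), arg = which.min(s))
}

#' Classic-scheme GSEA over a gene set collection
#'
#' Sets are restricted to members present in the ranked universe and kept only
#' if their effective size lies in `set_range` (default 15 to 5000). p-values
#' and NES come from gene-set label permutations: for each set, `n_perm`
#' random same-size sets are scored; the p-value is the same-sign tail
#' fraction and NES divides the observed score by the mean same-sign permuted
#' score. FDR q-values follow the standard NES-based procedure (pooled
#' permuted NES, ratio of tail fractions, clipped to \[0, 1\]).
#'
#' @param metric Named metric vector (see [rank_metric()]); ranked internally.
#' @param sets Named list of character vectors (gene sets).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param set_range Length-2 inclusive size window (default `c(15, 5000)`).
#' @return Data frame: `set_id`, `size`, `es`, `nes`, `p`, `fdr_q`, plus a
#'   `leading_edge` list-column of gene ids.
#' @export
gsea_classic <- function(metric, sets, n_perm = 1000, seed = 1,
                         set_range = c(15, 5000)) {
  ranked <- rank_metric(metric)
  universe <- names(ranked)
  n <- length(universe)
  members <- lapply(sets, intersect, y = universe)
  empty <- lengths(members) == 0 & lengths(sets) > 0
  if (any(empty))
    warning("sets with no member in the ranked universe skipped: ",
            paste(names(sets)[empty], collapse = ", "))
  keep <- lengths(members) >= set_range[1] & lengths(members) <= set_range[2]
  members <- members[keep]
  if (length(members) == 0)
    return(data.frame(set_id = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      fdr_q = numeric(0)))
  obs <- lapply(members, function(g) gsea_es(match(g, universe), n))
  es <- vapply(obs, `[[`, numeric(1), "es")
  sizes <- lengths(members)
  le <- lapply(seq_along(members), function(i) {
    pos <- match(members[[i]], universe)
    if (es[i] >= 0) members[[i]][pos <= obs[[i]]$arg]
    else members[[i]][pos >= obs[[i]]$arg]
  })
  set.seed(seed)
  perm <- matrix(NA_real_, length(members), n_perm)
  for (sz in unique(sizes)) {
    rows <- which(sizes == sz)
    pm <- vapply(seq_len(n_perm), function(b)
      gsea_es(sample.int(n, sz), n)$es, numeric(1))
    for (r in rows) perm[r, ] <- pm
  }
  p <- nes <- numeric(length(es))
  nes_perm <- matrix(NA_real_, length(es), n_perm)
  for (i in seq_along(es)) {
    pm <- perm[i, ]
    pos <- pm[pm >= 0]; neg <- pm[pm < 0]
    mpos <- if (length(pos)) mean(pos) else NA_real_
    mneg <- if (length(neg)) mean(abs(neg)) else NA_real_
    nes_perm[i, ] <- ifelse(pm >= 0, pm / mpos, pm / mneg)
    if (es[i] >= 0) {
      p[i] <- (1 + sum(pos >= es[i])) / (1 + length(pos))
      nes[i] <- es[i] / mpos
    } else {
      p[i] <- (1 + sum(neg <= es[i])) / (1 + length(neg))
      nes[i] <- -abs(es[i]) / mneg
    }
  }
  pooled <- as.vector(nes_perm)
  fdr_q <- vapply(seq_along(nes), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num_pool <- pooled[pooled >= 0]
      num <- mean(num_pool >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num_pool <- pooled[pooled < 0]
      num <- mean(num_pool <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(1, num / den)
  }, numeric(1))
  out <- data.frame(set_id = names(members), size = sizes, es = es,
                    nes = nes, p = p, fdr_q = fdr_q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- le
  out
}

#' Leading-edge gene summary over significant sets
#'
#' Counts, for every gene, the number of significant sets (FDR q <
#' `fdr_cut`) whose leading edge contains it, and selects genes reaching
#' `min_count` (default: targeted by at least 5 miRNA sets).
#'
#' @param results Output of [gsea_classic()].
#' @param fdr_cut FDR threshold defining significant sets (default 0.05).
#' @param min_count Minimum number of leading edges (default 5).
#' @return Data frame: `gene_id`, `n_sets`, `selected`.
#' @export
leading_edge_summary <- function(results, fdr_cut = 0.05, min_count = 5) {
  sig <- results[!is.na(results$fdr_q) & results$fdr_q < fdr_cut, ,
                 drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(gene_id = character(0), n_sets = integer(0),
                      selected = logical(0)))
  tab <- table(unlist(sig$leading_edge))
  data.frame(gene_id = names(tab), n_sets = as.integer(tab),
             selected = as.integer(tab) >= min_count,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-fraction gene set from a sensitivity metric
#'
#' Builds the set of the `fraction` most responsive genes (e.g. the top 30%
#' most sensitive), ranked by decreasing metric with id tie-break.
#'
#' @param metric Named metric vector.
#' @param fraction Fraction of genes to keep (default 0.3).
#' @return Character vector of gene ids.
#' @export
top_fraction_set <- function(metric, fraction = 0.3) {
  ranked <- metric[order(-metric, names(metric), method = "radix")]
  names(ranked)[seq_len(ceiling(fraction * length(ranked)))]
}

#' Filter miRNA conserved sites to cleavable d3'UTRs
#'
#' A site counts iff its interval lies within its gene's d3'UTR feature.
#' Genes without a d3'UTR feature contribute to the denominator only.
#'
#' @param sites Data frame: `mirna`, `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param features Split-feature data frame.
#' @param gene_subset Genes over which the proportion is computed.
#' @return List: `genes_with_site`, `proportion`, `sites` (the retained site
#'   rows).
#' @export
filter_d3utr_mirna_sites <- function(sites, features, gene_subset) {
  d3 <- features[features$kind == "d3utr", , drop = FALSE]
  idx <- match(sites$gene_id, d3$gene_id)
  inside <- !is.na(idx) &
    sites$chrom == d3$chrom[idx] &
    sites$start >= d3$start[idx] &
    sites$end <= d3$end[idx]
  kept <- sites[inside, , drop = FALSE]
  with_site <- intersect(gene_subset, unique(kept$gene_id))
  list(genes_with_site = with_site,
       proportion = length(with_site) / length(gene_subset),
       sites = kept)
}

#' Build miRNA target gene sets from a site table
#'
#' @param sites Site data frame (see [filter_d3utr_mirna_sites()]).
#' @return Named list: miRNA family -> unique target gene ids.
#' @export
mirna_target_sets <- function(sites) {
  lapply(split(sites$gene_id, sites$mirna), unique)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set id, description, then member genes, tab-sep).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- lapply(lines, function(x) x[-(1:2)])
  names(sets) <- vapply(lines, `[[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id)
    paste(c(id, "na", sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
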