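# Coverage metaprofiles around polyA sites, transcription-shutoff decay
# ratios, shortening classification and group decay comparison.

#' Read a coverage track
#'
#' bedGraph (or wig) read with rtracklayer and converted to per-base
#' run-length vectors.
#'
#' @param path bedGraph/wig file.
#' @param format Passed to `rtracklayer::import` (default `"bedGraph"`).
#' @return An `RleList` of per-chromosome densities.
#' @export
read_coverage_track <- function(path, format = "bedGraph") {
  gr <- rtracklayer::import(path, format = format)
  GenomicRanges::coverage(gr, weight = "score")
}

#' Average coverage metaprofile around sites
#'
#' For each site a window of `window` bases either side is extracted
#' (minus-strand windows are reversed so bins run 5'->3' in transcript
#' direction), per-base profiles are averaged over sites, and averaged again
#' into bins of `binsize` bases centred on offsets `-window, ...,
#' -binsize, 0, binsize, ..., window` (so `2*window/binsize + 1` bins, the
#' central bin at the site). Sites whose window leaves the chromosome are
#' skipped with a warning.
#'
#' @param track `RleList` coverage (see [read_coverage_track()]).
#' @param sites Data frame: `chrom`, `strand`, `position` (0-based).
#' @param window Half-width in bases (default 1000).
#' @param binsize Bin width in bases (default 10); must divide `window`.
#' @return List: `offsets`, `bins` (mean density per bin), `per_base`,
#'   `window`, `binsize`, `n_sites`.
#' @export
site_metaprofile <- function(track, sites, window = 1000, binsize = 10) {
  if (window %% binsize != 0) stop("binsize must divide window")
  acc <- numeric(2 * window + 1)
  used <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(track)) { skipped <- skipped + 1L; next }
    vec <- track[[chrom]]
    centre <- sites$position[i] + 1    # Rle vectors are 1-based
    lo <- centre - window; hi <- centre + window
    if (lo < 1 || hi > length(vec)) { skipped <- skipped + 1L; next }
    w <- as.numeric(S4Vectors::window(vec, lo, hi))
    if (sites$strand[i] == "-") w <- rev(w)
    acc <- acc + w
    used <- used + 1L
  }
  if (skipped > 0)
    warning(skipped, " site(s) skipped (outside chromosome bounds)")
  if (used == 0) stop("no usable site")
  per_base <- acc / used
  offset <- -window:window
  bin_idx <- as.integer(floor((offset + binsize / 2) / binsize)) +
    window %/% binsize + 1L
  bins <- as.numeric(tapply(per_base, bin_idx, mean))
  offsets <- seq(-window, window, by = binsize)
  list(offsets = offsets, bins = bins, per_base = per_base,
       window = window, binsize = binsize, n_sites = used)
}

#' Total-count-normalized decay relative expression
#'
#' For each gene and timepoint,
#' `rel_expr = ((count_t + c)/library_t) / ((count_ctrl + c)/library_ctrl)`
#' with pseudocount `c` on raw counts: the expression fold-change of the
#' transcription-inhibited sample versus the untreated control, a proxy for
#' transcript stability.
#'
#' @param treated Named list of gene-level `count_table`s, names are
#'   timepoints (hours).
#' @param control Gene-level `count_table` of the untreated sample.
#' @param pseudocount Pseudocount on raw counts (default 0.5).
#' @return Data frame: `gene_id`, `timepoint`, `rel_expr`.
#' @export
decay_relative_expression <- function(treated, control, pseudocount = 0.5) {
  if (control$library_size <= 0) stop("control library size must be positive")
  genes <- names(control$counts)
  ctrl_rate <- (as.numeric(control$counts) + pseudocount) /
    control$library_size
  out <- lapply(names(treated), function(tp) {
    tab <- treated[[tp]]
    if (tab$library_size <= 0) stop("treated library size must be positive")
    stopifnot(identical(names(tab$counts), genes))
    rate <- (as.numeric(tab$counts) + pseudocount) / tab$library_size
    data.frame(gene_id = genes, timepoint = as.numeric(tp),
               rel_expr = rate / ctrl_rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify 3'UTR shortening between control and knockdown
#'
#' `decreased` iff `ratio_ctr / ratio_kd < decrease_cut` (default 0.5, i.e.
#' more than 2-fold lower d3'UTR ratio in control; strict inequality at the
#' boundary); `steady` iff `|log2(ratio_ctr/ratio_kd)| <= log2(steady_band)`
#' (default within 1.2-fold); otherwise `other`. `NA` ratios yield `NA`.
#'
#' @param ratio_ctr,ratio_kd d3'UTR ratios in control and knockdown.
#' @param decrease_cut Shortening threshold (default 0.5).
#' @param steady_band Steady band fold-change (default 1.2).
#' @return Character vector in `{decreased, steady, other}` (or `NA`).
#' @export
classify_shortening <- function(ratio_ctr, ratio_kd, decrease_cut = 0.5,
                                steady_band = 1.2) {
  r <- ratio_ctr / ratio_kd
  out <- ifelse(r < decrease_cut, "decreased",
          ifelse(abs(log2(r)) <= log2(steady_band), "steady", "other"))
  out[!is.finite(r)] <- NA_character_
  out
}

#' Compare decay between shortening groups per timepoint
#'
#' Two-sided Wilcoxon rank-sum test of `rel_expr` between two groups at every
#' timepoint (`NA` when a group has fewer than `min_n` genes), plus
#' descriptive loess curves of `rel_expr` against timepoint per group
#' (visualization only).
#'
#' @param decay Data frame from [decay_relative_expression()].
#' @param group Named character vector: gene_id -> group label.
#' @param groups The two labels to compare
#'   (default `c("decreased", "steady")`).
#' @param min_n Minimum group size per timepoint (default 3).
#' @param loess_span,loess_degree Loess parameters (defaults 0.75, 2).
#' @return List: `tests` (data frame `timepoint`, `n_1`, `n_2`, `p`),
#'   `medians` (per group and timepoint), `loess` (per-group fits or `NULL`).
#' @export
compare_decay_groups <- function(decay, group,
                                 groups = c("decreased", "steady"),
                                 min_n = 3, loess_span = 0.75,
                                 loess_degree = 2) {
  decay$group <- unname(group[decay$gene_id])
  decay <- decay[!is.na(decay$group) & decay$group %in% groups, , drop = FALSE]
  tps <- sort(unique(decay$timepoint))
  tests <- lapply(tps, function(tp) {
    d <- decay[decay$timepoint == tp, ]
    x <- d$rel_expr[d$group == groups[1]]
    y <- d$rel_expr[d$group == groups[2]]
    p <- if (length(x) < min_n || length(y) < min_n) NA_real_
         else stats::wilcox.test(x, y, exact = FALSE)$p.value
    data.frame(timepoint = tp, n_1 = length(x), n_2 = length(y), p = p)
  })
  medians <- stats::aggregate(rel_expr ~ group + timepoint, decay,
                              stats::median)
  fits <- NULL
  if (length(tps) >= 3) {
    fits <- lapply(split(decay, decay$group), function(d)
      suppressWarnings(
        try(stats::loess(rel_expr ~ timepoint, data = d, span = loess_span,
                         degree = loess_degree), silent = TRUE)))
  }
  list(tests = do.call(rbind, tests), medians = medians, loess = fits)
}
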