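# Tissue restriction: cosine SPM/CTM statistics over a multi-tissue expression
# matrix, per-gene tissue reduction, and the correlation of per-tissue median
# d3'UTR ratios with a regulator's expression.

#' Reduce a gene's tissue vector before SPM/CTM scoring
#'
#' Tissues with zero expression are excluded from the comparison; within each
#' similarity group (e.g. the brain-derived tissues) only the member with the
#' highest expression for this gene is retained.
#'
#' @param row Named non-negative expression vector (one gene, all tissues).
#' @param groups Optional list of character vectors partitioning a subset of
#'   tissue names into similarity groups.
#' @return The retained named vector (possibly empty).
#' @export
reduce_tissues <- function(row, groups = NULL) {
  if (any(row < 0)) stop("negative expression")
  row <- row[row > 0]
  if (!is.null(groups)) {
    for (grp in groups) {
      members <- intersect(grp, names(row))
      if (length(members) > 1) {
        best <- members[which.max(row[members])]
        row <- row[!(names(row) %in% setdiff(members, best))]
      }
    }
  }
  row
}

#' SPM and CTM of an expression vector
#'
#' SPM_i is the cosine of the vector with the i-th basis vector,
#' `x_i / ||x||2`; CTM of a tissue subset S is `||x_S||2 / ||x||2`. Both lie
#' in \[0, 1\], `sum(spm^2) == 1`, and `ctm(all) == 1`.
#'
#' @param row Named positive expression vector (after [reduce_tissues()]).
#' @param subset Tissue names (or indices) of the candidate subset; default
#'   all tissues.
#' @return List with `spm` (named vector) and `ctm` (scalar).
#' @export
compute_spm_ctm <- function(row, subset = names(row)) {
  if (length(row) == 0 || all(row == 0)) stop("zero expression vector")
  nrm <- sqrt(sum(row^2))
  spm <- row / nrm
  ctm <- sqrt(sum(row[subset]^2)) / nrm
  list(spm = spm, ctm = ctm)
}

#' Classify a gene as tissue-specific, tissue-selective or unassigned
#'
#' Specific: some tissue has SPM > `spm_specific` (default 0.9). Otherwise
#' selective: exactly 2 to 4 tissues have SPM > `spm_selective` (default 0.3)
#' and the CTM of those tissues exceeds `ctm_selective` (default 0.9).
#' Otherwise unassigned.
#'
#' @param row Named expression vector for one gene (pre-reduction).
#' @param groups Similarity groups, see [reduce_tissues()].
#' @param spm_specific,spm_selective,ctm_selective Thresholds.
#' @return List: `label` (`"specific"`, `"selective"`, `"unassigned"`),
#'   `tissues` (character vector of tagged tissues), `spm`, `ctm`,
#'   `retained_tissues`.
#' @export
classify_restriction <- function(row, groups = NULL, spm_specific = 0.9,
                                 spm_selective = 0.3, ctm_selective = 0.9) {
  row <- reduce_tissues(row, groups)
  if (length(row) == 0)
    return(list(label = "unassigned", tissues = character(0),
                spm = numeric(0), ctm = NA_real_,
                retained_tissues = character(0)))
  sc <- compute_spm_ctm(row)
  spm <- sc$spm
  if (max(spm) > spm_specific) {
    top <- names(spm)[which.max(spm)]
    return(list(label = "specific", tissues = top, spm = spm, ctm = max(spm),
                retained_tissues = names(row)))
  }
  cand <- names(spm)[spm > spm_selective]
  if (length(cand) >= 2 && length(cand) <= 4) {
    ctm <- compute_spm_ctm(row, cand)$ctm
    if (ctm > ctm_selective)
      return(list(label = "selective", tissues = cand, spm = spm, ctm = ctm,
                  retained_tissues = names(row)))
  }
  list(label = "unassigned", tissues = character(0), spm = spm, ctm = NA_real_,
       retained_tissues = names(row))
}

#' Classify every gene of a tissue expression matrix
#'
#' @param mat Genes x tissues matrix of non-negative expression (RPKM), with
#'   row and column names.
#' @param groups Similarity groups, see [reduce_tissues()].
#' @param ... Thresholds passed to [classify_restriction()].
#' @return Data frame: `gene_id`, `label`, `tissues` (comma-separated).
#' @export
classify_tissue_matrix <- function(mat, groups = NULL, ...) {
  res <- lapply(rownames(mat), function(g) {
    cl <- classify_restriction(mat[g, ], groups = groups, ...)
    data.frame(gene_id = g, label = cl$label,
               tissues = paste(cl$tissues, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pick the peripheral tissue for ratio comparison
#'
#' Tissue-specific genes use their unique tagged tissue; tissue-selective
#' genes draw one of their tagged tissues uniformly at random (seeded).
#'
#' @param labels Output of [classify_tissue_matrix()].
#' @param seed Integer seed for the random draws.
#' @return `labels` with an added `ratio_tissue` column (`NA` if unassigned).
#' @export
pick_peripheral_tissue <- function(labels, seed = 1) {
  set.seed(seed)
  labels$ratio_tissue <- vapply(seq_len(nrow(labels)), function(i) {
    ts <- strsplit(labels$tissues[i], ",", fixed = TRUE)[[1]]
    ts <- ts[nzchar(ts)]
    if (length(ts) == 0) NA_character_
    else if (length(ts) == 1) ts
    else sample(ts, 1)
  }, character(1))
  labels
}

#' Correlate per-tissue median d3'UTR ratios with regulator expression
#'
#' Pearson correlation of log10 regulator expression against the per-tissue
#' median ratio, with a two-sided p-value.
#'
#' @param expression Named positive vector of regulator expression per tissue.
#' @param median_ratios Named vector of per-tissue median d3'UTR ratios.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_ratio_expression <- function(expression, median_ratios) {
  tissues <- intersect(names(expression), names(median_ratios))
  x <- log10(expression[tissues]); y <- median_ratios[tissues]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired tissues")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
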