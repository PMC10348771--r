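# Differential expression between cell groups (expanded vs unexpanded
# clonotypes, treatment arms, time points): Wilcoxon rank-sum per gene with
# an exact small-sample path, fold-change/percent-expression prefilters and
# multiple-testing adjustment, following the conventions of the standard
# single-cell marker tools.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration over all C(n1+n2, n1) group assignments when
#' min(n1, n2) <= 8 (valid under ties; two-sidedness is |W - E W| >=
#' |W_obs - E W|); otherwise the normal approximation with tie-corrected
#' variance and no continuity correction.
#'
#' @param values_1,values_2 numeric vectors, both nonempty
#' @return two-sided p-value
#' @export
rank_sum_test <- function(values_1, values_2) {
  n1 <- length(values_1); n2 <- length(values_2)
  if (n1 == 0 || n2 == 0) stopf("both groups must be nonempty")
  pooled <- c(values_1, values_2)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  if (min(n1, n2) <= 8) {
    combos <- utils::combn(n1 + n2, min(n1, n2))
    w_all <- colSums(matrix(r[combos], nrow = min(n1, n2)))
    if (n2 < n1) {                       # enumerated the smaller group
      w_all <- sum(r) - w_all
    }
    mu <- mean(w_all)
    eps <- 1e-9
    return(mean(abs(w_all - mu) >= abs(w_obs - mu) - eps))
  }
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)            # all values tied
  z <- (w_obs - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Log2 fold change and percent expression for one gene
#'
#' `pct_i` is the fraction of group-i cells detecting the gene (count > 0;
#' log-normalization preserves zeros, so normalized > 0 is equivalent).
#' The fold change de-logs the normalized means and adds a pseudocount:
#' `log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))`.
#'
#' @param normalized genes x cells log-normalized matrix
#' @param group1,group2 disjoint, nonempty barcode vectors
#' @param gene feature id
#' @return list: `log_fc, pct_1, pct_2`
#' @export
fold_change <- function(normalized, group1, group2, gene) {
  if (!gene %in% rownames(normalized)) stopf("gene not in features: %s", gene)
  .check_groups(normalized, group1, group2)
  x1 <- normalized[gene, group1]
  x2 <- normalized[gene, group2]
  list(
    log_fc = log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1)),
    pct_1 = mean(x1 > 0),
    pct_2 = mean(x2 > 0)
  )
}

.check_groups <- function(normalized, group1, group2) {
  if (length(group1) == 0 || length(group2) == 0) {
    stopf("both groups must be nonempty")
  }
  if (length(intersect(group1, group2)) > 0) stopf("groups must be disjoint")
  missing <- setdiff(c(group1, group2), colnames(normalized))
  if (length(missing) > 0) {
    stopf("%d group barcode(s) not in matrix", length(missing))
  }
  invisible(TRUE)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement, over an explicit family size `m` (which may
#' exceed the number of p-values supplied, e.g. all genes in the matrix
#' when only a filtered subset was tested).
#'
#' @param p numeric vector of p-values in [0, 1]
#' @param method `"bonferroni"` (default) or `"bh"`
#' @param m family size (default `length(p)`)
#' @return adjusted p-values, same order as `p`
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), m = length(p)) {
  method <- match.arg(method)
  if (length(p) > 0 && (any(is.na(p)) || any(p < 0 | p > 1))) {
    stopf("p-values must lie in [0, 1]")
  }
  if (m < length(p)) stopf("family size m cannot be below length(p)")
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni",
                  n = m)
}

#' Differentially expressed genes between two cell groups
#'
#' Genes are tested only if detected in at least `min_pct` of either group
#' and showing `|log2 FC| >= logfc_threshold` (both-direction threshold);
#' p-values come from [rank_sum_test()] on normalized expression, adjusted
#' over `m` = all genes in the matrix by default (the marker-tool convention;
#' set `adjust_over = "tested"` to adjust over the tested set only).
#' A gene is significant iff its adjusted p-value is below `alpha`.
#'
#' @param normalized genes x cells log-normalized matrix
#' @param group1,group2 disjoint, nonempty barcode vectors
#' @param logfc_threshold minimum |log2 fold change| to test (default 1)
#' @param min_pct minimum detection fraction in the better group (default 0.2)
#' @param alpha significance cutoff on adjusted p (default 0.05)
#' @param adjust `"bonferroni"` (default) or `"bh"`
#' @param adjust_over `"all"` genes (default) or the `"tested"` set
#' @return data.frame of tested genes: `gene, log_fc, pct_1, pct_2, p_value,
#'   p_adjusted, significant`, sorted by p then |log_fc| decreasing then gene
#' @export
find_markers <- function(normalized, group1, group2,
                         logfc_threshold = 1, min_pct = 0.2, alpha = 0.05,
                         adjust = c("bonferroni", "bh"),
                         adjust_over = c("all", "tested")) {
  adjust <- match.arg(adjust)
  adjust_over <- match.arg(adjust_over)
  .check_groups(normalized, group1, group2)
  m1 <- normalized[, group1, drop = FALSE]
  m2 <- normalized[, group2, drop = FALSE]
  pct_1 <- Matrix::rowMeans(m1 > 0)
  pct_2 <- Matrix::rowMeans(m2 > 0)
  mean1 <- Matrix::rowMeans(expm1(m1))
  mean2 <- Matrix::rowMeans(expm1(m2))
  log_fc <- log2((mean1 + 1) / (mean2 + 1))
  tested <- pmax(pct_1, pct_2) >= min_pct & abs(log_fc) >= logfc_threshold
  genes <- rownames(normalized)[tested]
  if (length(genes) == 0) {
    message("find_markers: no genes pass the pct/log-FC filters")
    return(data.frame(gene = character(0), log_fc = numeric(0),
                      pct_1 = numeric(0), pct_2 = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  p <- vapply(genes, function(g) {
    rank_sum_test(as.numeric(m1[g, ]), as.numeric(m2[g, ]))
  }, numeric(1))
  m <- if (adjust_over == "all") nrow(normalized) else length(genes)
  p_adj <- adjust_pvalues(p, method = adjust, m = m)
  out <- data.frame(gene = genes, log_fc = log_fc[tested],
                    pct_1 = pct_1[tested], pct_2 = pct_2[tested],
                    p_value = p, p_adjusted = p_adj,
                    significant = p_adj < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -abs(out$log_fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
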