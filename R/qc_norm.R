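# Per-cell QC and log-normalization. The QC rule is read literally: a cell
# fails if it expresses MORE than 25% mitochondrial transcripts (0.25 passes,
# 0.2501 fails) or FEWER than 200 genes (200 passes, 199 fails).

#' Default mitochondrial gene set for a feature list
#'
#' Features prefixed `MT-` (the human GENCODE convention). Supplied as a
#' default only; the set is always configurable because annotations differ.
#'
#' @param features character vector of feature ids
#' @return character vector of mitochondrial feature ids
#' @export
mito_genes_default <- function(features) {
  features[startsWith(features, "MT-")]
}

#' Compute per-cell QC metrics
#'
#' @param counts genes x cells count matrix (sparse or dense) with dimnames
#' @param mito_genes feature ids counted as mitochondrial; must all be
#'   present in `rownames(counts)`
#' @param max_mito maximum tolerated mitochondrial fraction (default 0.25;
#'   cells strictly above fail)
#' @param min_genes minimum number of detected genes (default 200; cells
#'   strictly below fail)
#' @param blacklist optional barcodes failed unconditionally (hook for
#'   additional low-quality cells identified outside these two rules)
#' @return data.frame with columns `barcode, total_counts, n_genes,
#'   mito_fraction, pass_qc`
#' @export
compute_qc <- function(counts, mito_genes = mito_genes_default(rownames(counts)),
                       max_mito = 0.25, min_genes = 200,
                       blacklist = character(0)) {
  unknown <- setdiff(mito_genes, rownames(counts))
  if (length(unknown) > 0) {
    stopf("mito gene(s) not in features: %s", paste(unknown, collapse = ", "))
  }
  total <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- if (length(mito_genes) > 0) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  mito_fraction <- ifelse(total > 0, mito / total, 0)
  pass <- mito_fraction <= max_mito & n_genes >= min_genes &
    !(colnames(counts) %in% blacklist)
  data.frame(
    barcode = colnames(counts),
    total_counts = as.integer(total),
    n_genes = as.integer(n_genes),
    mito_fraction = as.numeric(mito_fraction),
    pass_qc = as.logical(pass),
    stringsAsFactors = FALSE
  )
}

#' Restrict a count matrix to QC-passing cells
#'
#' @param counts genes x cells count matrix
#' @param qc QC table from [compute_qc()], covering all barcodes of `counts`
#' @return the matrix restricted to passing barcodes, column order preserved
#' @export
filter_cells <- function(counts, qc) {
  missing <- setdiff(colnames(counts), qc$barcode)
  if (length(missing) > 0) {
    stopf("QC table does not cover %d barcode(s)", length(missing))
  }
  pass <- qc$barcode[qc$pass_qc]
  keep <- colnames(counts) %in% pass
  if (!any(keep)) warnf("no cells pass QC")
  counts[, keep, drop = FALSE]
}

#' Log-normalize counts
#'
#' value(g, c) = ln(1 + count(g, c) * scale_factor / total(c)) -- the
#' standard per-cell library-size log-normalization. Zeros map to zeros, so
#' the sparsity pattern is preserved.
#'
#' @param counts genes x cells count matrix, already QC-filtered
#' @param scale_factor library-size scale (default 10,000)
#' @return normalized sparse matrix, same dimnames
#' @export
lognormalize <- function(counts, scale_factor = 10000) {
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  total <- Matrix::colSums(m)
  if (any(total == 0)) {
    stopf("%d cell(s) have zero total counts; filter before normalizing",
          sum(total == 0))
  }
  percol <- diff(m@p)                    # nonzeros per column
  m@x <- log1p(m@x * scale_factor / rep.int(total, percol))
  m
}

#' Average expression of a gene panel per cell group
#'
#' Supervised panel summary: the arithmetic mean of normalized expression per
#' (group, gene), optionally z-scaled per gene across groups for heatmap
#' export (e.g. an mTOR-pathway panel of MTOR, RPTOR, RICTOR, TSC1, TSC2,
#' FKBP1A averaged within expanded clonotypes per treatment arm).
#'
#' @param normalized genes x cells normalized matrix
#' @param groups named character vector or factor: barcode -> group label,
#'   covering every column of `normalized`
#' @param panel character vector of feature ids, all present in the matrix
#' @param zscale if TRUE, z-scale each gene's means across groups
#' @return data.frame, one row per group label, one column per panel gene
#' @export
panel_average <- function(normalized, groups, panel, zscale = FALSE) {
  missing <- setdiff(panel, rownames(normalized))
  if (length(missing) > 0) {
    stopf("panel gene(s) not in features: %s", paste(missing, collapse = ", "))
  }
  bc <- colnames(normalized)
  if (!all(bc %in% names(groups))) stopf("every barcode must be labeled")
  g <- as.character(groups[bc])
  labels <- sort(unique(as.character(groups)))
  sub <- normalized[panel, , drop = FALSE]
  out <- matrix(NA_real_, nrow = length(labels), ncol = length(panel),
                dimnames = list(labels, panel))
  for (lab in labels) {
    idx <- which(g == lab)
    if (length(idx) == 0) {
      warnf("group '%s' has no cells; row is NaN", lab)
      out[lab, ] <- NaN
    } else {
      out[lab, ] <- Matrix::rowMeans(sub[, idx, drop = FALSE])
    }
  }
  if (zscale) {
    out <- apply(out, 2, function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    if (is.null(dim(out))) out <- matrix(out, nrow = length(labels),
                                         dimnames = list(labels, panel))
  }
  data.frame(group = labels, out, check.names = FALSE, row.names = NULL)
}
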