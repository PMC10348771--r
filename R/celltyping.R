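# Lineage assignment by marker-score gating. Each lineage rule names a
# required-positive and required-negative gene set; a cell's score for a
# lineage is mean(normalized positives) - mean(normalized negatives), and the
# cell takes the best-scoring lineage whose score clears the rule threshold.
# Gating replaces graph clustering + cluster annotation deliberately: it keeps
# the CD8 selection rule (the part clonality analysis depends on) deterministic
# and auditable without an embedding stack.

#' Default marker rule set
#'
#' Canonical-marker rules covering the lineage vocabulary used downstream.
#' Label order is the fixed tie-break priority. Editable: pass your own list
#' of the same shape, or load one from YAML with [read_marker_rules()].
#'
#' @return named list: label -> list(positive, negative, threshold)
#' @export
default_marker_rules <- function() {
  list(
    CD8_T   = list(positive = c("PTPRC", "CD3E", "CD8A"),
                   negative = c("CD4", "TRDC", "CD19", "CD14"),
                   threshold = 0.5),
    CD4_T   = list(positive = c("PTPRC", "CD3E", "CD4"),
                   negative = c("CD8A", "TRDC", "CD19", "CD14"),
                   threshold = 0.5),
    gd_T    = list(positive = c("PTPRC", "CD3E", "TRDC"),
                   negative = c("CD19", "CD14"),
                   threshold = 0.5),
    B       = list(positive = c("PTPRC", "CD19"),
                   negative = c("CD3E", "CD14"),
                   threshold = 0.5),
    myeloid = list(positive = c("PTPRC", "CD14", "CD68", "ITGAX"),
                   negative = c("CD3E", "CD19"),
                   threshold = 0.5)
  )
}

#' Read a marker rule set from YAML
#'
#' @param path YAML file: one entry per label with `positive`, `negative`
#'   (optional) and `threshold` (optional, default 0.5)
#' @return rule list as for [default_marker_rules()]
#' @export
read_marker_rules <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(r) {
    list(positive = as.character(r$positive),
         negative = as.character(r$negative %||% character(0)),
         threshold = as.numeric(r$threshold %||% 0.5))
  })
}

.validate_rules <- function(rules, features) {
  if (length(rules) == 0) stopf("marker rule set is empty")
  for (lab in names(rules)) {
    r <- rules[[lab]]
    if (length(r$positive) == 0) stopf("rule '%s' has no positive genes", lab)
    bad <- setdiff(c(r$positive, r$negative), features)
    if (length(bad) > 0) {
      stopf("rule '%s' names unknown feature(s): %s",
            lab, paste(bad, collapse = ", "))
    }
    if (r$threshold < 0) stopf("rule '%s' has a negative threshold", lab)
  }
  invisible(rules)
}

#' Score cells against marker rules and assign lineages
#'
#' A cell is assigned the label with the highest score among labels whose
#' score meets the rule threshold; cells clearing no threshold are
#' `unassigned`. Ties are broken by the (fixed) order of the rule list.
#'
#' @param normalized genes x cells normalized matrix
#' @param rules marker rule set, e.g. [default_marker_rules()]
#' @return data.frame with columns `barcode, lineage, score`
#' @export
score_and_assign <- function(normalized, rules = default_marker_rules()) {
  .validate_rules(rules, rownames(normalized))
  labels <- names(rules)
  scores <- sapply(labels, function(lab) {
    r <- rules[[lab]]
    pos <- Matrix::colMeans(normalized[r$positive, , drop = FALSE])
    neg <- if (length(r$negative) > 0) {
      Matrix::colMeans(normalized[r$negative, , drop = FALSE])
    } else 0
    pos - neg
  })
  scores <- matrix(scores, ncol = length(labels),
                   dimnames = list(colnames(normalized), labels))
  thr <- vapply(rules, function(r) r$threshold, numeric(1))
  qualifies <- sweep(scores, 2, thr, ">=")
  masked <- ifelse(qualifies, scores, -Inf)
  best <- apply(masked, 1, function(v) {
    if (all(!is.finite(v))) NA_integer_ else which.max(v)  # first max = priority
  })
  lineage <- ifelse(is.na(best), "unassigned", labels[best])
  top <- scores[cbind(seq_len(nrow(scores)),
                      ifelse(is.na(best), 1L, best))]
  data.frame(barcode = colnames(normalized), lineage = lineage,
             score = ifelse(is.na(best), NA_real_, top),
             stringsAsFactors = FALSE)
}

#' Select the CD8+ T-cell compartment
#'
#' CD8+ cells are the barcodes gated as CD8_T with subsequent removal of any
#' cell expressing CD4, TRDC or CD68. "Expressing" defaults to raw count > 0,
#' the strictest literal reading; pass a normalized matrix and a nonzero
#' `threshold` to use a normalized-value cutoff instead.
#'
#' @param annotations output of [score_and_assign()]
#' @param counts genes x cells matrix used to evaluate exclusion expression
#'   (raw counts by default)
#' @param exclusion_genes genes whose expression removes a cell
#' @param threshold values strictly above this count as "expressing"
#' @return character vector of selected barcodes
#' @export
select_cd8 <- function(annotations, counts,
                       exclusion_genes = c("CD4", "TRDC", "CD68"),
                       threshold = 0) {
  missing <- setdiff(exclusion_genes, rownames(counts))
  if (length(missing) > 0) {
    stopf("exclusion gene(s) not in features: %s",
          paste(missing, collapse = ", "))
  }
  cd8 <- annotations$barcode[annotations$lineage == "CD8_T"]
  cd8 <- intersect(cd8, colnames(counts))
  if (length(cd8) == 0) return(character(0))
  excl <- counts[exclusion_genes, cd8, drop = FALSE]
  expressing <- Matrix::colSums(excl > threshold) > 0
  cd8[!expressing]
}
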