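# Clonotype assembly and expansion classification.
#
# A clonotype is the set of cells sharing identical CDR3 alpha/beta
# sequences: receptors with >= 1 alpha chain and exactly 1 beta chain are
# keyed on (sorted alpha CDR3 set, beta CDR3); cells sharing a key form one
# clonotype, expanded iff it holds more than 2 cells. Receptors carrying
# 2 beta chains, or only a single chain type, are unexpanded by definition
# and never form keys ("keyless units"). Keys default to nucleotide CDR3s
# (the stricter identity) with an amino-acid mode available.

.locus_from_gene <- function(gene) {
  ifelse(startsWith(gene, "TRA"), "TRA",
  ifelse(startsWith(gene, "TRB"), "TRB",
  ifelse(startsWith(gene, "TRD"), "TRD",
  ifelse(startsWith(gene, "TRG"), "TRG", ""))))
}

#' Collapse TCR gene variants onto their locus
#'
#' Gene variants (allele suffixes such as `TRAV12-2*01`, duplicate-gene `/DV`
#' designations) are collapsed so that every alpha-locus contig carries chain
#' `TRA` and every beta-locus contig `TRB`; V/J gene names are stripped of
#' allele suffixes. CDR3 strings are untouched. Contigs whose chain cannot be
#' resolved to a TRA/TRB/TRD/TRG locus are flagged (`chain_flagged`) and pass
#' through for downstream exclusion.
#'
#' @param contigs contig data.frame from [read_contigs()]
#' @return the contig table with normalized `chain`, allele-stripped gene
#'   names, and a logical `chain_flagged` column
#' @export
collapse_variants <- function(contigs) {
  out <- contigs
  chain <- as.character(out$chain)
  known <- c("TRA", "TRB", "TRD", "TRG")
  # resolve via chain label first, then V gene, then J gene
  locus <- ifelse(chain %in% known, chain, .locus_from_gene(chain))
  for (col in c("v_gene", "j_gene")) {
    if (col %in% names(out)) {
      g <- .locus_from_gene(as.character(out[[col]]))
      locus <- ifelse(locus == "" & g != "", g, locus)
    }
  }
  out$chain <- ifelse(locus != "", locus, chain)
  out$chain_flagged <- locus == ""
  for (col in c("v_gene", "d_gene", "j_gene")) {
    if (col %in% names(out)) out[[col]] <- sub("\\*.*$", "", out[[col]])
  }
  out
}

#' Assemble per-barcode receptors from contigs
#'
#' Contigs are usable iff productive, full-length, high-confidence and on the
#' TRA or TRB locus (after [collapse_variants()]). One receptor is built per
#' requested barcode holding at least one usable contig; duplicate CDR3s
#' within a chain are deduplicated; barcodes with more than 2 alpha or more
#' than 2 beta chains are flagged malformed.
#'
#' @param contigs collapsed contig table
#' @param barcodes barcodes to assemble (e.g. the CD8-selected set); contigs
#'   on other barcodes are ignored
#' @return data.frame, one row per receptor: `barcode, alpha_nt, beta_nt,
#'   alpha_aa, beta_aa` (chain sets as `;`-joined strings, alpha sorted by
#'   nt sequence), `n_alpha, n_beta, malformed`
#' @export
build_receptors <- function(contigs, barcodes) {
  usable <- contigs[
    contigs$productive & contigs$full_length & contigs$high_confidence &
      contigs$chain %in% c("TRA", "TRB") &
      contigs$barcode %in% barcodes &
      contigs$cdr3_nt != "",
    , drop = FALSE
  ]
  if (nrow(usable) == 0) {
    return(data.frame(barcode = character(0), alpha_nt = character(0),
                      beta_nt = character(0), alpha_aa = character(0),
                      beta_aa = character(0), n_alpha = integer(0),
                      n_beta = integer(0), malformed = logical(0),
                      stringsAsFactors = FALSE))
  }
  u <- usable[order(usable$barcode, usable$chain, usable$cdr3_nt), ,
              drop = FALSE]
  u <- u[!duplicated(u[, c("barcode", "chain", "cdr3_nt")]), , drop = FALSE]
  bcs <- unique(u$barcode)                 # sorted
  chain_agg <- function(ch, col) {
    sub <- u[u$chain == ch, , drop = FALSE]
    v <- tapply(sub[[col]], factor(sub$barcode, levels = bcs),
                paste, collapse = ";")
    ifelse(is.na(v), "", unname(v))
  }
  n_by <- function(ch) {
    sub <- u[u$chain == ch, , drop = FALSE]
    v <- tapply(rep(1L, nrow(sub)), factor(sub$barcode, levels = bcs), sum)
    as.integer(ifelse(is.na(v), 0L, v))
  }
  n_alpha <- n_by("TRA"); n_beta <- n_by("TRB")
  out <- data.frame(
    barcode = bcs,
    alpha_nt = chain_agg("TRA", "cdr3_nt"),
    beta_nt = chain_agg("TRB", "cdr3_nt"),
    alpha_aa = chain_agg("TRA", "cdr3"),
    beta_aa = chain_agg("TRB", "cdr3"),
    n_alpha = n_alpha, n_beta = n_beta,
    malformed = n_alpha > 2 | n_beta > 2,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Serialize a clonotype key
#'
#' Canonical string form `TRA:a1;TRA:a2|TRB:b` with the alpha set sorted.
#'
#' @param alpha character vector of alpha CDR3 sequences (1 or 2)
#' @param beta single beta CDR3 sequence
#' @return key string
#' @export
clonotype_key <- function(alpha, beta) {
  paste0(paste0("TRA:", sort(alpha), collapse = ";"), "|TRB:", beta)
}

#' Call clonotypes and classify expansion
#'
#' Receptors with 1-2 alpha chains and exactly 1 beta chain are keyed on
#' (alpha CDR3 set, beta CDR3) and grouped; a clonotype is `expanded` iff its
#' key is present in more than `min_expanded_size - 1` cells (default: more
#' than 2). Receptors with 2 beta chains or only one chain type become
#' keyless units, each its own unexpanded unit regardless of multiplicity.
#' Dual-alpha receptors join a clonotype only on exact equality of the full
#' alpha set plus beta; partial alpha overlap never merges clones.
#'
#' @param receptors receptor table from [build_receptors()]
#' @param key_level `"nt"` (default) or `"aa"`: which CDR3 representation
#'   defines clonotype identity
#' @param min_expanded_size smallest clonotype size called expanded
#'   (default 3)
#' @return list with elements
#'   \describe{
#'     \item{clonotypes}{data.frame `key, size, status, n_dual_alpha,
#'       barcodes` (`,`-joined)}
#'     \item{keyless}{data.frame `barcode, reason, n_alpha, n_beta, status`}
#'     \item{log}{named counts: receptors in, keyed, keyless, malformed}
#'   }
#' @export
call_clonotypes <- function(receptors, key_level = c("nt", "aa"),
                            min_expanded_size = 3) {
  key_level <- match.arg(key_level)
  acol <- paste0("alpha_", key_level)
  bcol <- paste0("beta_", key_level)
  r <- receptors[!receptors$malformed, , drop = FALSE]
  n_malformed <- sum(receptors$malformed)
  if (n_malformed > 0) {
    warnf("%d malformed receptor(s) (>2 chains of one type) excluded",
          n_malformed)
  }
  keyed <- r$n_alpha >= 1 & r$n_alpha <= 2 & r$n_beta == 1
  kr <- r[keyed, , drop = FALSE]
  ur <- r[!keyed, , drop = FALSE]

  clonotypes <- data.frame(key = character(0), size = integer(0),
                           status = character(0), n_dual_alpha = integer(0),
                           barcodes = character(0), stringsAsFactors = FALSE)
  if (nrow(kr) > 0) {
    alpha_sets <- strsplit(kr[[acol]], ";", fixed = TRUE)
    key <- vapply(seq_len(nrow(kr)), function(i) {
      paste0(paste0("TRA:", alpha_sets[[i]], collapse = ";"),
             "|TRB:", kr[[bcol]][i])
    }, character(1))
    kf <- factor(key)
    size <- as.integer(tapply(rep(1L, nrow(kr)), kf, sum))
    clonotypes <- data.frame(
      key = levels(kf), size = size,
      status = ifelse(size >= min_expanded_size, "expanded", "unexpanded"),
      n_dual_alpha = as.integer(tapply(kr$n_alpha == 2, kf, sum)),
      barcodes = unname(tapply(kr$barcode, kf, function(b)
        paste(sort(b), collapse = ","))),
      stringsAsFactors = FALSE)
    clonotypes <- clonotypes[order(-clonotypes$size, clonotypes$key), ,
                             drop = FALSE]
    rownames(clonotypes) <- NULL
  }

  keyless <- data.frame(barcode = character(0), reason = character(0),
                        n_alpha = integer(0), n_beta = integer(0),
                        status = character(0), stringsAsFactors = FALSE)
  if (nrow(ur) > 0) {
    reason <- ifelse(ur$n_beta >= 2, "dual_beta",
              ifelse(ur$n_beta == 0, "alpha_only", "beta_only"))
    keyless <- data.frame(barcode = ur$barcode, reason = reason,
                          n_alpha = ur$n_alpha, n_beta = ur$n_beta,
                          status = "unexpanded", stringsAsFactors = FALSE)
    keyless <- keyless[order(keyless$barcode), , drop = FALSE]
    rownames(keyless) <- NULL
  }

  list(clonotypes = clonotypes, keyless = keyless,
       log = c(receptors_in = nrow(receptors), keyed = nrow(kr),
               keyless = nrow(ur), malformed = n_malformed))
}

#' Dual TCR-alpha frequencies in expanded vs unexpanded cells
#'
#' Cell-level percentages of receptors carrying two alpha chains, computed
#' separately within cells belonging to expanded clonotypes and within all
#' other receptor-bearing cells (unexpanded clonotype members plus keyless
#' units), with a two-proportion z-test of their difference.
#'
#' @param calls result of [call_clonotypes()]
#' @param receptors receptor table the calls were made from
#' @return list: `pct_dual_alpha_expanded`, `pct_dual_alpha_unexpanded`
#'   (percent, NaN for an empty stratum), `n_expanded_cells`,
#'   `n_unexpanded_cells`, `p_value`
#' @export
dual_alpha_stats <- function(calls, receptors) {
  cl <- calls$clonotypes
  exp_bc <- if (nrow(cl) > 0) {
    unlist(strsplit(cl$barcodes[cl$status == "expanded"], ",", fixed = TRUE))
  } else character(0)
  r <- receptors[!receptors$malformed, , drop = FALSE]
  is_exp <- r$barcode %in% exp_bc
  dual <- r$n_alpha == 2
  n1 <- sum(is_exp); n2 <- sum(!is_exp)
  x1 <- sum(dual & is_exp); x2 <- sum(dual & !is_exp)
  pct1 <- if (n1 > 0) 100 * x1 / n1 else NaN
  pct2 <- if (n2 > 0) 100 * x2 / n2 else NaN
  if (n1 == 0 || n2 == 0) {
    warnf("empty stratum in dual-alpha comparison")
    p <- NaN
  } else if (x1 + x2 == 0 || x1 + x2 == n1 + n2) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
  }
  list(pct_dual_alpha_expanded = pct1, pct_dual_alpha_unexpanded = pct2,
       n_expanded_cells = n1, n_unexpanded_cells = n2, p_value = p)
}

#' Per-sample clonal summary
#'
#' Totals follow the convention that makes published denominators auditable:
#' `n_clonotypes_total` counts distinct keys plus one unit per keyless
#' receptor, so unexpanded single-chain and dual-beta cells are part of the
#' total (e.g. 26 expanded of 336 total clonotypes -> 7.7%).
#'
#' @param calls result of [call_clonotypes()]
#' @param sample_id sample identifier carried into the summary
#' @return data.frame with one row: `sample_id, n_cd8_cells_with_receptor,
#'   n_clonotypes_total, n_expanded, n_unexpanded, pct_expanded`
#'   (half-up, 1 decimal), `expanded_sizes` (`,`-joined, decreasing)
#' @export
summarize_sample <- function(calls, sample_id) {
  cl <- calls$clonotypes
  n_keyless <- nrow(calls$keyless)
  n_cells <- sum(cl$size) + n_keyless
  n_total <- nrow(cl) + n_keyless
  n_exp <- sum(cl$status == "expanded")
  n_unexp <- n_total - n_exp
  if (n_total == 0) {
    warnf("sample %s has no clonotypes; pct_expanded is NaN", sample_id)
    pct <- NaN
  } else {
    pct <- round_half_up(100 * n_exp / n_total, 1)
  }
  sizes <- sort(cl$size[cl$status == "expanded"], decreasing = TRUE)
  data.frame(
    sample_id = sample_id,
    n_cd8_cells_with_receptor = n_cells,
    n_clonotypes_total = n_total,
    n_expanded = n_exp,
    n_unexpanded = n_unexp,
    pct_expanded = pct,
    expanded_sizes = paste(sizes, collapse = ","),
    stringsAsFactors = FALSE
  )
}
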