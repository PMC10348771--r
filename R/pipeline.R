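# End-to-end orchestration: manifest + config in, per-sample clonal
# summaries, cohort clone tracks, persistence, biopsy-urine overlaps, DEG
# and panel-average tables plus a run report out. Stage order: QC ->
# normalization -> lineage gating -> CD8 selection -> clonotype calling ->
# tracking -> differential expression.

#' Pipeline run configuration
#'
#' Every decided default is recorded verbatim in the run report so
#' denominators and thresholds are auditable.
#'
#' @param max_mito QC: maximum mitochondrial fraction (cells strictly above
#'   fail; default 0.25)
#' @param min_genes QC: minimum detected genes (cells strictly below fail;
#'   default 200)
#' @param qc_blacklist optional barcodes excluded unconditionally
#' @param scale_factor normalization library-size scale (default 10,000)
#' @param marker_rules lineage gating rules (default
#'   [default_marker_rules()])
#' @param exclusion_genes genes whose expression removes a gated CD8 cell
#'   (default CD4, TRDC, CD68)
#' @param exclusion_threshold raw counts strictly above this count as
#'   "expressing" (default 0)
#' @param key_level clonotype identity on `"nt"` (default) or `"aa"` CDR3
#' @param min_expanded_size smallest expanded clonotype (default 3, i.e.
#'   more than 2 cells)
#' @param tracking_scope `"expanded_any"` (default) or `"all"`
#' @param prior persistence counts prior-seen as `"expanded"` (default) or
#'   `"present"`
#' @param deg_logfc,deg_min_pct,deg_alpha,deg_adjust,deg_adjust_over
#'   differential-expression settings (defaults 1, 0.2, 0.05, bonferroni,
#'   all genes)
#' @param deg_min_cells smallest group size worth testing (default 10)
#' @param panel gene panel for supervised group averages (default the mTOR
#'   pathway panel MTOR, RPTOR, RICTOR, TSC1, TSC2, FKBP1A)
#' @param seed seed recorded in the run report
#' @return a `run_config` list
#' @export
run_config <- function(max_mito = 0.25, min_genes = 200,
                       qc_blacklist = character(0),
                       scale_factor = 10000,
                       marker_rules = default_marker_rules(),
                       exclusion_genes = c("CD4", "TRDC", "CD68"),
                       exclusion_threshold = 0,
                       key_level = "nt", min_expanded_size = 3,
                       tracking_scope = "expanded_any",
                       prior = "expanded",
                       deg_logfc = 1, deg_min_pct = 0.2, deg_alpha = 0.05,
                       deg_adjust = "bonferroni", deg_adjust_over = "all",
                       deg_min_cells = 10,
                       panel = c("MTOR", "RPTOR", "RICTOR", "TSC1", "TSC2",
                                 "FKBP1A"),
                       seed = 1L) {
  if (max_mito < 0 || max_mito > 1) stopf("max_mito must be in [0, 1]")
  if (min_genes < 0) stopf("min_genes must be >= 0")
  if (!key_level %in% c("nt", "aa")) stopf("key_level must be nt or aa")
  if (min_expanded_size < 2) stopf("min_expanded_size must be >= 2")
  structure(as.list(environment()), class = "run_config")
}

#' Validate a manifest against a configuration
#'
#' Lists (without stopping) every issue found: missing files, duplicate
#' sample ids, inconsistent days, unknown compartments or arms. A non-empty
#' report blocks [run_pipeline()] unless forced.
#'
#' @param manifest manifest data.frame or path to a manifest YAML
#' @param config a [run_config()]
#' @return data.frame with columns `sample_id, issue`; zero rows when clean
#' @export
validate_cohort <- function(manifest, config = run_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  issues <- list()
  note <- function(sid, msg) {
    issues[[length(issues) + 1]] <<- data.frame(
      sample_id = sid, issue = msg, stringsAsFactors = FALSE)
  }
  dup <- manifest$sample_id[duplicated(manifest$sample_id)]
  for (d in unique(dup)) note(d, "duplicate sample_id")
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    if (!m$compartment %in% c("biopsy", "urine")) {
      note(m$sample_id, sprintf("unknown compartment '%s'", m$compartment))
    }
    if (!m$is_arm %in% c("tacrolimus", "belatacept", "iscalimab", "none")) {
      note(m$sample_id, sprintf("unknown is_arm '%s'", m$is_arm))
    }
    if (is.na(m$post_transplant_day) || m$post_transplant_day < 0) {
      note(m$sample_id, "post_transplant_day must be >= 0")
    }
    contig <- file.path(m$vdj_dir, "filtered_contig_annotations.csv")
    if (!file.exists(contig)) note(m$sample_id, paste("missing", contig))
    for (f in c("matrix.mtx", "barcodes.tsv", "features.tsv")) {
      path <- file.path(m$gex_dir, f)
      if (!file.exists(path)) note(m$sample_id, paste("missing", path))
    }
  }
  if (length(issues) == 0) {
    return(data.frame(sample_id = character(0), issue = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[stage:%s] %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline over a cohort
#'
#' @param manifest manifest data.frame or path to a manifest YAML
#' @param config a [run_config()]
#' @param outdir output directory for tables and the run report; `NULL`
#'   skips writing
#' @param force run despite validation issues (default FALSE)
#' @return invisibly, a list: `summaries`, `clonotypes` (per-sample calls),
#'   `dual_alpha`, `tracks`, `persistence`, `overlaps`, `deg`
#'   (per-sample expanded-vs-unexpanded tables), `deg_arms` (pairwise arm
#'   contrasts on expanded cells), `panel_means`, `accounting`, `issues`
#' @export
run_pipeline <- function(manifest, config = run_config(), outdir = NULL,
                         force = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  issues <- validate_cohort(manifest, config)
  if (nrow(issues) > 0 && !force) {
    stopf("[stage:validate] %d manifest issue(s); first: %s (%s)",
          nrow(issues), issues$issue[1], issues$sample_id[1])
  }
  sample_calls <- list()
  summaries <- list()
  dual <- list()
  accounting <- list()
  deg <- list()
  panel_means <- list()
  exp_cells_by_arm <- list()   # pooled normalized expanded-cell columns

  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    sid <- m$sample_id
    counts <- .stage("read", read_mtx(m$gex_dir))
    qc <- .stage("qc", compute_qc(
      counts, mito_genes = mito_genes_default(rownames(counts)),
      max_mito = config$max_mito, min_genes = config$min_genes,
      blacklist = config$qc_blacklist))
    filtered <- .stage("qc", filter_cells(counts, qc))
    norm <- .stage("normalize", lognormalize(filtered, config$scale_factor))
    ann <- .stage("celltyping", score_and_assign(norm, config$marker_rules))
    cd8 <- .stage("celltyping", select_cd8(
      ann, filtered, exclusion_genes = config$exclusion_genes,
      threshold = config$exclusion_threshold))
    contigs <- .stage("read", read_contigs(
      file.path(m$vdj_dir, "filtered_contig_annotations.csv")))
    contigs <- .stage("clonotype", collapse_variants(contigs))
    receptors <- .stage("clonotype", build_receptors(contigs, cd8))
    calls <- .stage("clonotype", call_clonotypes(
      receptors, key_level = config$key_level,
      min_expanded_size = config$min_expanded_size))
    sample_calls[[sid]] <- calls
    summaries[[sid]] <- summarize_sample(calls, sid)
    da <- dual_alpha_stats(calls, receptors)
    dual[[sid]] <- data.frame(sample_id = sid,
                              pct_dual_alpha_expanded = da$pct_dual_alpha_expanded,
                              pct_dual_alpha_unexpanded = da$pct_dual_alpha_unexpanded,
                              p_value = da$p_value, stringsAsFactors = FALSE)
    accounting[[sid]] <- data.frame(
      sample_id = sid, cells_in = ncol(counts),
      cells_pass_qc = ncol(filtered),
      cells_fail_qc = ncol(counts) - ncol(filtered),
      cells_cd8 = length(cd8), contigs_in = nrow(contigs),
      receptors = nrow(receptors),
      receptors_malformed = unname(calls$log["malformed"]),
      stringsAsFactors = FALSE)

    # expanded vs unexpanded differential expression within the sample
    cl <- calls$clonotypes
    exp_bc <- unlist(strsplit(cl$barcodes[cl$status == "expanded"], ",",
                              fixed = TRUE))
    unexp_bc <- setdiff(c(
      unlist(strsplit(cl$barcodes[cl$status == "unexpanded"], ",",
                      fixed = TRUE)),
      calls$keyless$barcode), exp_bc)
    exp_bc <- intersect(exp_bc, colnames(norm))
    unexp_bc <- intersect(unexp_bc, colnames(norm))
    if (length(exp_bc) >= config$deg_min_cells &&
        length(unexp_bc) >= config$deg_min_cells) {
      tab <- .stage("deg", find_markers(
        norm, exp_bc, unexp_bc, logfc_threshold = config$deg_logfc,
        min_pct = config$deg_min_pct, alpha = config$deg_alpha,
        adjust = config$deg_adjust, adjust_over = config$deg_adjust_over))
      if (nrow(tab) > 0) {
        deg[[sid]] <- cbind(sample_id = sid, contrast = "expanded_vs_unexpanded",
                            tab, stringsAsFactors = FALSE)
      }
    }
    if (length(exp_bc) + length(unexp_bc) > 0) {
      grp <- stats::setNames(
        rep(c("expanded", "unexpanded"),
            c(length(exp_bc), length(unexp_bc))), c(exp_bc, unexp_bc))
      sub <- norm[, names(grp), drop = FALSE]
      pm <- .stage("panel", panel_average(sub, grp, config$panel))
      panel_means[[sid]] <- cbind(sample_id = sid, pm,
                                  stringsAsFactors = FALSE)
    }
    if (length(exp_bc) > 0) {
      arm <- m$is_arm
      exp_cells_by_arm[[arm]] <- cbind(
        exp_cells_by_arm[[arm]],
        norm[, exp_bc, drop = FALSE])
    }
  }

  tracks <- .stage("tracking", build_tracks(sample_calls, manifest,
                                            scope = config$tracking_scope))
  persistence <- do.call(rbind, lapply(manifest$sample_id, function(s) {
    p <- persistence_counts(tracks, s, prior = config$prior)
    data.frame(sample_id = s, n_expanded_total = p$n_expanded_total,
               n_seen_prior = p$n_seen_prior, pct_prior = p$pct_prior,
               stringsAsFactors = FALSE)
  }))

  # biopsy-urine overlap for pairs sharing (participant, day)
  overlaps <- list()
  bx <- manifest[manifest$compartment == "biopsy", , drop = FALSE]
  ur <- manifest[manifest$compartment == "urine", , drop = FALSE]
  for (i in seq_len(nrow(bx))) {
    match_ur <- ur[ur$participant_id == bx$participant_id[i] &
                     ur$post_transplant_day == bx$post_transplant_day[i], ,
                   drop = FALSE]
    for (j in seq_len(nrow(match_ur))) {
      ka <- with(sample_calls[[bx$sample_id[i]]]$clonotypes,
                 key[status == "expanded"])
      kb <- with(sample_calls[[match_ur$sample_id[j]]]$clonotypes,
                 key[status == "expanded"])
      ov <- overlap(ka, kb, bx$sample_id[i], match_ur$sample_id[j])
      overlaps[[length(overlaps) + 1]] <- data.frame(
        sample_a = ov$sample_a, sample_b = ov$sample_b,
        n_shared_expanded = ov$n_shared_expanded,
        n_a_only = ov$n_a_only, n_b_only = ov$n_b_only,
        shared_keys = paste(ov$shared_keys, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  # pairwise arm contrasts on pooled expanded cells
  deg_arms <- list()
  arms <- names(exp_cells_by_arm)
  if (length(arms) >= 2) {
    for (a in seq_along(arms)) for (b in seq_along(arms)) {
      if (a >= b) next
      g1 <- exp_cells_by_arm[[arms[a]]]
      g2 <- exp_cells_by_arm[[arms[b]]]
      if (ncol(g1) < config$deg_min_cells || ncol(g2) < config$deg_min_cells)
        next
      pooled <- cbind(g1, g2)
      tab <- .stage("deg", find_markers(
        pooled, colnames(g1), colnames(g2),
        logfc_threshold = config$deg_logfc, min_pct = config$deg_min_pct,
        alpha = config$deg_alpha, adjust = config$deg_adjust,
        adjust_over = config$deg_adjust_over))
      if (nrow(tab) > 0) {
        deg_arms[[length(deg_arms) + 1]] <- cbind(
          contrast = paste(arms[a], "vs", arms[b]), tab,
          stringsAsFactors = FALSE)
      }
    }
  }

  results <- list(
    summaries = do.call(rbind, summaries),
    dual_alpha = do.call(rbind, dual),
    tracks = tracks,
    persistence = persistence,
    overlaps = if (length(overlaps) > 0) do.call(rbind, overlaps) else
      data.frame(sample_a = character(0), sample_b = character(0),
                 n_shared_expanded = integer(0), n_a_only = integer(0),
                 n_b_only = integer(0), shared_keys = character(0)),
    deg = if (length(deg) > 0) do.call(rbind, deg) else NULL,
    deg_arms = if (length(deg_arms) > 0) do.call(rbind, deg_arms) else NULL,
    panel_means = do.call(rbind, panel_means),
    accounting = do.call(rbind, accounting)
  )
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) rownames(results[[nm]]) <- NULL
  }
  results$clonotypes <- sample_calls
  results$issues <- issues

  if (!is.null(outdir)) {
    tables <- results[c("summaries", "dual_alpha", "tracks", "persistence",
                        "overlaps", "deg", "deg_arms", "panel_means",
                        "accounting")]
    report <- list(
      seed = config$seed,
      thresholds = list(
        max_mito = config$max_mito, min_genes = config$min_genes,
        scale_factor = config$scale_factor,
        exclusion_genes = config$exclusion_genes,
        exclusion_threshold = config$exclusion_threshold,
        key_level = config$key_level,
        min_expanded_size = config$min_expanded_size,
        tracking_scope = config$tracking_scope, prior = config$prior,
        deg_logfc = config$deg_logfc, deg_min_pct = config$deg_min_pct,
        deg_alpha = config$deg_alpha, deg_adjust = config$deg_adjust,
        deg_adjust_over = config$deg_adjust_over,
        panel = config$panel))
    .stage("write", write_tables(tables, outdir, report))
  }
  invisible(results)
}
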