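# Synthetic multi-sample, multi-compartment, longitudinal cohort generator.
# Emits 10x-style files (filtered contig annotations, clonotypes.csv,
# MatrixMarket counts with sidecars) with planted clonal ground truth so the
# whole pipeline is testable without patient data. One global integer seed;
# each sample draws from its own derived stream, so regeneration under a
# fixed seed is byte-identical.

# -- configuration objects ---------------------------------------------------

#' Cohort generator configuration
#'
#' @param participants list of [participant_spec()] objects
#' @param seed global integer seed; all per-sample streams derive from it
#' @param chain_recovery_rate probability a T cell yields a full paired
#'   receptor (default 0.90, the fraction of transcriptionally defined
#'   T cells from which full-length paired CDR3s are typically recovered)
#' @param dual_alpha_rate probability a T cell (or planted clone) carries two
#'   productive alpha chains (default 0.08, the normal 5-10% range)
#' @param doublet_rate probability a barcode receives a second beta chain
#'   from another cell (default 0.01)
#' @param mito_outlier_rate fraction of cells pushed above the 25%
#'   mitochondrial QC threshold (default 0.03)
#' @param low_gene_rate fraction of cells expressing fewer than 200 genes
#'   (default 0.03)
#' @param corrupt_rate fraction of contigs emitted with productive = FALSE
#'   (default 0)
#' @param cells_per_sample cells emitted per sample (default 3000)
#' @return a `cohort_config` list, validated
#' @export
cohort_config <- function(participants, seed,
                          chain_recovery_rate = 0.90,
                          dual_alpha_rate = 0.08,
                          doublet_rate = 0.01,
                          mito_outlier_rate = 0.03,
                          low_gene_rate = 0.03,
                          corrupt_rate = 0,
                          cells_per_sample = 3000) {
  cfg <- list(participants = participants, seed = as.integer(seed),
              chain_recovery_rate = chain_recovery_rate,
              dual_alpha_rate = dual_alpha_rate,
              doublet_rate = doublet_rate,
              mito_outlier_rate = mito_outlier_rate,
              low_gene_rate = low_gene_rate,
              corrupt_rate = corrupt_rate,
              cells_per_sample = as.integer(cells_per_sample))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Participant specification
#'
#' @param participant_id identifier
#' @param is_arm immunosuppression arm: tacrolimus, belatacept, iscalimab
#'   or none
#' @param samples data.frame with columns `sample_id, compartment
#'   (biopsy|urine), post_transplant_day`
#' @param clones list of [clone_spec()] objects
#' @return a `participant_spec` list
#' @export
participant_spec <- function(participant_id, is_arm, samples, clones) {
  structure(list(participant_id = participant_id, is_arm = is_arm,
                 samples = samples, clones = clones),
            class = "participant_spec")
}

#' Planted clone specification
#'
#' @param clone_id identifier, unique within a participant
#' @param alpha_cdr3_nt one or two alpha CDR3 nucleotide strings
#' @param beta_cdr3_nt beta CDR3 nucleotide string
#' @param size_by_sample named integer vector: sample_id -> planted cell
#'   count (absent samples default to 0)
#' @param phenotype_program one of `none, activated, exhausted,
#'   resident_memory`: the expression shift applied to member cells
#' @param lineage `CD8`, `CD4` or `gdT`
#' @return a `clone_spec` list
#' @export
clone_spec <- function(clone_id, alpha_cdr3_nt, beta_cdr3_nt, size_by_sample,
                       phenotype_program = "none", lineage = "CD8") {
  structure(list(clone_id = clone_id,
                 alpha_cdr3_nt = alpha_cdr3_nt,
                 beta_cdr3_nt = beta_cdr3_nt,
                 size_by_sample = size_by_sample,
                 phenotype_program = phenotype_program,
                 lineage = lineage),
            class = "clone_spec")
}

.check_cdr3 <- function(x, clone_id) {
  for (s in x) {
    if (nchar(s) == 0 || nchar(s) %% 3 != 0 ||
        grepl("[^ACGT]", s)) {
      stopf("clone '%s': CDR3 '%s' must be nonempty ACGT with length %% 3 == 0",
            clone_id, s)
    }
  }
}

#' Validate a cohort configuration
#'
#' @param config a [cohort_config()]
#' @return invisibly, the config; errors name the offending field
#' @export
validate_cohort_config <- function(config) {
  for (f in c("chain_recovery_rate", "dual_alpha_rate", "doublet_rate",
              "mito_outlier_rate", "low_gene_rate", "corrupt_rate")) {
    check_prob(config[[f]], f)
  }
  if (config$cells_per_sample < 1) stopf("cells_per_sample must be >= 1")
  if (length(config$participants) == 0) stopf("participants must be nonempty")
  all_sample_ids <- character(0)
  for (p in config$participants) {
    s <- p$samples
    if (!all(c("sample_id", "compartment", "post_transplant_day") %in%
             names(s))) {
      stopf("participant '%s': samples must have sample_id, compartment, post_transplant_day",
            p$participant_id)
    }
    if (!all(s$compartment %in% c("biopsy", "urine"))) {
      stopf("participant '%s': compartment must be biopsy or urine",
            p$participant_id)
    }
    if (any(s$post_transplant_day < 0)) {
      stopf("participant '%s': post_transplant_day must be >= 0",
            p$participant_id)
    }
    for (comp in unique(s$compartment)) {
      d <- s$post_transplant_day[s$compartment == comp]
      if (any(diff(d) <= 0)) {
        stopf("participant '%s': post_transplant_day must be strictly increasing within compartment '%s'",
              p$participant_id, comp)
      }
    }
    all_sample_ids <- c(all_sample_ids, s$sample_id)
    keys <- character(0)
    for (cl in p$clones) {
      .check_cdr3(c(cl$alpha_cdr3_nt, cl$beta_cdr3_nt), cl$clone_id)
      if (length(cl$alpha_cdr3_nt) < 1 || length(cl$alpha_cdr3_nt) > 2) {
        stopf("clone '%s': alpha_cdr3_nt must hold 1 or 2 sequences",
              cl$clone_id)
      }
      if (any(cl$size_by_sample < 0)) {
        stopf("clone '%s': sizes must be >= 0", cl$clone_id)
      }
      if (!cl$lineage %in% c("CD8", "CD4", "gdT")) {
        stopf("clone '%s': lineage must be CD8, CD4 or gdT", cl$clone_id)
      }
      keys <- c(keys, clonotype_key(cl$alpha_cdr3_nt, cl$beta_cdr3_nt))
    }
    if (anyDuplicated(keys)) {
      stopf("participant '%s': clone (alpha set, beta) keys must be unique",
            p$participant_id)
    }
    # planted cells must fit the sample
    for (sid in s$sample_id) {
      planted <- sum(vapply(p$clones, function(cl)
        as.integer(cl$size_by_sample[sid] %||% 0L) %||% 0L, integer(1)),
        na.rm = TRUE)
      if (planted > config$cells_per_sample) {
        stopf("sample '%s': planted clone cells (%d) exceed cells_per_sample (%d)",
              sid, planted, config$cells_per_sample)
      }
    }
  }
  if (anyDuplicated(all_sample_ids)) stopf("sample_ids must be unique")
  invisible(config)
}

# -- sequence helpers --------------------------------------------------------

.codons <- local({
  b <- c("T", "C", "A", "G")
  cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  names(aa) <- cod
  aa
})

.sense_codons <- names(.codons)[.codons != "*"]

translate_cdr3 <- function(nt) {
  vapply(nt, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(.codons[cods], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Draw a random CDR3 nucleotide sequence
#'
#' Uniform over sense codons, length uniform over 36-54 nt in codon steps.
#' Keys only need uniqueness and identity semantics; no V(D)J-recombination
#' realism is attempted.
#'
#' @param n number of sequences
#' @return character vector of CDR3 nucleotide strings
#' @export
random_cdr3 <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    len <- sample(seq(12, 18), 1)   # codons
    paste(sample(.sense_codons, len, replace = TRUE), collapse = "")
  }, character(1))
}

.random_barcodes <- function(n) {
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste0(paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE),
                   collapse = ""), "-1")
    }, character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

# -- gene panel and expression model -----------------------------------------

.mito_names <- paste0("MT-", c(
  "ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND3", "ND4L", "ND4",
  "ND5", "ND6", "CYB", "RNR1", "RNR2", "TL1", "TV", "TL2", "TS1", "TQ"))

.marker_names <- c(
  "PTPRC", "CD3E", "CD8A", "CD4", "TRDC", "CD68", "CD19", "CD14", "ITGAX",
  "MKI67", "GZMB", "GZMK", "IFNG", "GNLY", "PRF1", "PDCD1", "HAVCR2",
  "LAG3", "TIGIT", "ZNF683", "CD69", "ITGAE", "S1PR1", "CXCR6",
  "MTOR", "RPTOR", "RICTOR", "TSC1", "TSC2", "FKBP1A")

#' The simulated gene panel
#'
#' Lineage and phenotype markers, 20 mitochondrial genes (`MT-` prefixed) and
#' background filler genes sized so a normal cell detects well over 200 genes.
#'
#' @param n_filler number of background genes (default 430)
#' @return character vector of feature ids
#' @export
gene_panel <- function(n_filler = 430) {
  c(.marker_names, .mito_names, sprintf("FILLER%03d", seq_len(n_filler)))
}

# Per-lineage marker means (negative-binomial mu). Marker genes use a tight
# dispersion (size 10) so that a lineage-defining marker essentially never
# drops out entirely: this emulates the clean separation of well-annotated
# lineages and makes truth-recovery checks sharp.
.lineage_mu <- list(
  CD8_T   = c(PTPRC = 30, CD3E = 30, CD8A = 30),
  CD4_T   = c(PTPRC = 30, CD3E = 30, CD4 = 30),
  gd_T    = c(PTPRC = 30, CD3E = 30, TRDC = 30),
  B       = c(PTPRC = 30, CD19 = 30),
  myeloid = c(PTPRC = 30, CD14 = 30, CD68 = 30, ITGAX = 25, CD4 = 2)
)

.program_mu <- list(
  none = numeric(0),
  activated = c(GZMB = 8, IFNG = 6, GNLY = 6, PRF1 = 6, GZMK = 4),
  exhausted = c(PDCD1 = 6, HAVCR2 = 6, LAG3 = 6, TIGIT = 5),
  resident_memory = c(ZNF683 = 8, CD69 = 8, ITGAE = 6, CXCR6 = 5)
)

.base_mu <- function(features) {
  mu <- stats::setNames(rep(0, length(features)), features)
  mu[startsWith(features, "FILLER")] <- 2
  mu[features %in% .mito_names] <- 1.5
  mu[c("MTOR", "RPTOR", "RICTOR", "TSC1", "TSC2", "FKBP1A")] <- 1.5
  mu["S1PR1"] <- 1
  mu
}

#' Simulate a count matrix for assigned cells
#'
#' Counts are negative binomial around a base mean plus lineage- and
#' phenotype-program-specific marker shifts (dispersion size 2 for background
#' genes, 10 for marker genes). Cells flagged as
#' mitochondrial outliers have mitochondrial counts raised to half their
#' total (fraction 0.5 > 0.25 by construction); low-gene cells keep counts
#' in only 150 genes.
#'
#' @param assignments data.frame with columns `barcode, lineage, program,
#'   is_mito_outlier, is_low_gene` (one row per cell)
#' @param features feature ids (default [gene_panel()])
#' @return sparse genes x cells count matrix
#' @export
emit_expression <- function(assignments, features = gene_panel()) {
  n_cells <- nrow(assignments)
  n_genes <- length(features)
  base <- .base_mu(features)
  mat <- matrix(0L, nrow = n_genes, ncol = n_cells,
                dimnames = list(features, assignments$barcode))
  class_key <- paste(assignments$lineage, assignments$program, sep = "|")
  for (ck in unique(class_key)) {
    idx <- which(class_key == ck)
    parts <- strsplit(ck, "|", fixed = TRUE)[[1]]
    mu <- base
    lm <- .lineage_mu[[parts[1]]]
    if (!is.null(lm)) mu[names(lm)] <- lm
    pm <- .program_mu[[parts[2]]] %||% numeric(0)
    if (length(pm) > 0) mu[names(pm)] <- pm
    size <- ifelse(features %in% .marker_names, 10, 2)
    draws <- stats::rnbinom(n_genes * length(idx),
                            mu = rep(mu, times = length(idx)),
                            size = rep(size, times = length(idx)))
    mat[, idx] <- draws
  }
  # low-gene cells: keep counts in only 150 randomly chosen genes
  for (i in which(assignments$is_low_gene)) {
    keep <- sample.int(n_genes, 150)
    drop <- setdiff(seq_len(n_genes), keep)
    mat[drop, i] <- 0L
  }
  # mito outliers: raise mitochondrial mass to the non-mito total
  mito_idx <- which(features %in% .mito_names)
  for (i in which(assignments$is_mito_outlier)) {
    nonmito <- sum(mat[-mito_idx, i])
    cur <- sum(mat[mito_idx, i])
    extra <- max(0L, as.integer(nonmito - cur + 1L))
    per <- extra %/% length(mito_idx)
    rem <- extra %% length(mito_idx)
    add <- rep(per, length(mito_idx))
    if (rem > 0) add[seq_len(rem)] <- add[seq_len(rem)] + 1L
    mat[mito_idx, i] <- mat[mito_idx, i] + add
  }
  Matrix::Matrix(mat, sparse = TRUE)
}

# -- contig emission ---------------------------------------------------------

.plan_receptor <- function(alpha_nt, beta_nt) {
  list(alpha_nt = alpha_nt, beta_nt = beta_nt)
}

#' Emit V(D)J contig records for assigned cells
#'
#' Every receptor-bearing cell (planted clone member or background T cell)
#' emits alpha and beta contigs subject to `chain_recovery_rate` (dropout
#' removes one chain type), with dual-alpha cells carrying their second alpha
#' and `doublet_rate` barcodes receiving an extra beta from another receptor
#' in the sample. Gamma/delta cells emit TRD/TRG contigs (excluded by
#' downstream collapsing). All contigs are productive, full-length and
#' high-confidence unless `corrupt_rate` > 0.
#'
#' @param assignments data.frame: `barcode, lineage, clone_id` (NA for
#'   background)
#' @param receptors named list: barcode -> list(alpha_nt, beta_nt) planned
#'   chains (from the clone spec or drawn for background cells)
#' @param config a [cohort_config()]
#' @return data.frame of contig records in the filtered-contig layout
#' @export
emit_contigs <- function(assignments, receptors, config) {
  if (nrow(assignments) == 0) stopf("assignments must be nonempty")
  bearing <- assignments$barcode[assignments$barcode %in% names(receptors)]
  lin_by_bc <- stats::setNames(assignments$lineage, assignments$barcode)
  all_betas <- unique(unlist(lapply(receptors, function(r) r$beta_nt)))
  bc_out <- character(0); chain_out <- character(0); nt_out <- character(0)
  cid_out <- character(0)
  for (bc in bearing) {
    rec <- receptors[[bc]]
    alpha <- rec$alpha_nt
    beta <- rec$beta_nt
    # chain dropout: with prob 1 - recovery, lose one chain type
    if (stats::runif(1) > config$chain_recovery_rate) {
      if (stats::runif(1) < 0.5) alpha <- character(0) else beta <- character(0)
    }
    # doublet: an extra beta from another cell's receptor
    if (length(beta) > 0 && stats::runif(1) < config$doublet_rate &&
        length(all_betas) > 1) {
      other <- setdiff(all_betas, beta)
      beta <- c(beta, sample(other, 1))
    }
    nt <- c(alpha, beta)
    if (length(nt) == 0) next
    chains <- if (lin_by_bc[[bc]] == "gd_T") {
      c(rep("TRG", length(alpha)), rep("TRD", length(beta)))
    } else {
      c(rep("TRA", length(alpha)), rep("TRB", length(beta)))
    }
    bc_out <- c(bc_out, rep(bc, length(nt)))
    chain_out <- c(chain_out, chains)
    nt_out <- c(nt_out, nt)
    cid_out <- c(cid_out, paste0(bc, "_contig_", seq_along(nt)))
  }
  if (length(bc_out) == 0) stopf("no receptor-bearing cells in assignments")
  n <- length(bc_out)
  productive <- if (config$corrupt_rate > 0) {
    stats::runif(n) >= config$corrupt_rate
  } else rep(TRUE, n)
  out <- data.frame(
    barcode = bc_out, is_cell = TRUE, contig_id = cid_out,
    high_confidence = TRUE, chain = chain_out,
    v_gene = paste0(chain_out, "V", sample(1:40, n, replace = TRUE), "*01"),
    d_gene = ifelse(chain_out %in% c("TRB", "TRD"),
                    paste0(chain_out, "D1*01"), ""),
    j_gene = paste0(chain_out, "J", sample(1:50, n, replace = TRUE), "*01"),
    cdr3 = translate_cdr3(nt_out), cdr3_nt = nt_out,
    productive = productive, full_length = TRUE,
    reads = sample(500:5000, n, replace = TRUE),
    umis = sample(2:40, n, replace = TRUE),
    raw_clonotype_id = "", stringsAsFactors = FALSE
  )
  # advisory per-sample clonotype ids: group by (alpha set, beta) of emitted
  # productive TRA/TRB contigs
  key_by_bc <- tapply(seq_len(nrow(out)), out$barcode, function(idx) {
    a <- sort(out$cdr3_nt[idx][out$chain[idx] == "TRA"])
    b <- sort(out$cdr3_nt[idx][out$chain[idx] == "TRB"])
    paste(paste(a, collapse = ";"), paste(b, collapse = ";"), sep = "|")
  })
  ids <- stats::setNames(paste0("clonotype", seq_along(unique(key_by_bc))),
                         unique(key_by_bc))
  out$raw_clonotype_id <- ids[key_by_bc[out$barcode]]
  out
}

.clonotypes_csv <- function(contigs) {
  grp <- split(contigs, contigs$raw_clonotype_id)
  df <- do.call(rbind, lapply(grp, function(g) {
    bcs <- unique(g$barcode)
    one <- g[!duplicated(g$cdr3_nt), , drop = FALSE]
    one <- one[order(one$chain, one$cdr3_nt), , drop = FALSE]
    data.frame(
      clonotype_id = g$raw_clonotype_id[1],
      frequency = length(bcs),
      proportion = NA_real_,
      cdr3s_aa = paste(paste0(one$chain, ":", one$cdr3), collapse = ";"),
      cdr3s_nt = paste(paste0(one$chain, ":", one$cdr3_nt), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  df$proportion <- df$frequency / sum(df$frequency)
  df <- df[order(-df$frequency, df$clonotype_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# -- cohort generation -------------------------------------------------------

.background_lineages <- c(CD8_T = 0.30, CD4_T = 0.25, gd_T = 0.05,
                          B = 0.15, myeloid = 0.25)

.sample_assignments <- function(p, sid, config) {
  clone_rows <- list()
  for (cl in p$clones) {
    n <- as.integer(unname(cl$size_by_sample[sid]) %||% 0L)
    if (is.na(n) || n == 0) next
    lin <- unname(c(CD8 = "CD8_T", CD4 = "CD4_T", gdT = "gd_T")[cl$lineage])
    clone_rows[[length(clone_rows) + 1]] <- data.frame(
      clone_id = rep(cl$clone_id, n), lineage = lin,
      program = cl$phenotype_program, stringsAsFactors = FALSE)
  }
  planted <- if (length(clone_rows) > 0) do.call(rbind, clone_rows) else
    data.frame(clone_id = character(0), lineage = character(0),
               program = character(0), stringsAsFactors = FALSE)
  n_bg <- config$cells_per_sample - nrow(planted)
  bg <- data.frame(
    clone_id = rep(NA_character_, n_bg),
    lineage = sample(names(.background_lineages), n_bg, replace = TRUE,
                     prob = .background_lineages),
    program = rep("none", n_bg), stringsAsFactors = FALSE)
  ass <- rbind(planted, bg)
  ass$barcode <- .random_barcodes(nrow(ass))
  ass$is_mito_outlier <- stats::runif(nrow(ass)) < config$mito_outlier_rate
  ass$is_low_gene <- stats::runif(nrow(ass)) < config$low_gene_rate
  ass
}

.sample_receptors <- function(ass, p, config) {
  recs <- list()
  clone_by_id <- stats::setNames(p$clones,
                                 vapply(p$clones, `[[`, "", "clone_id"))
  for (i in seq_len(nrow(ass))) {
    bc <- ass$barcode[i]
    if (!is.na(ass$clone_id[i])) {
      cl <- clone_by_id[[ass$clone_id[i]]]
      recs[[bc]] <- .plan_receptor(cl$alpha_cdr3_nt, cl$beta_cdr3_nt)
    } else if (ass$lineage[i] %in% c("CD8_T", "CD4_T", "gd_T")) {
      n_alpha <- if (stats::runif(1) < config$dual_alpha_rate) 2 else 1
      recs[[bc]] <- .plan_receptor(random_cdr3(n_alpha), random_cdr3(1))
    }
  }
  recs
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per sample, `filtered_contig_annotations.csv`, `clonotypes.csv`
#' and a Matrix Market count directory, plus a cohort `manifest.yaml` and
#' `truth.json` recording the planted ground truth. Regeneration with the
#' same config (and seed) is byte-identical.
#'
#' @param config a [cohort_config()]
#' @param outdir output directory, created if needed
#' @return invisibly, a list: `manifest` (data.frame), `truth` (planted
#'   clonal truth; see Details), `outdir`
#'
#' @details The truth registry holds: `clonotypes` (per sample: clone_id,
#'   key, lineage, program, planted size, expanded flag at size > 2),
#'   `barcodes` (per-barcode clone assignment and lineage),
#'   `shared_across_samples` and `shared_across_compartments` (per
#'   participant, keys planted in more than one sample / in both
#'   compartments).
#' @export
generate_cohort <- function(config, outdir) {
  validate_cohort_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stopf("cannot create output directory: %s", outdir)
  manifest <- list()
  truth_clono <- list()
  truth_bc <- list()
  stream <- 0L
  for (p in config$participants) {
    for (j in seq_len(nrow(p$samples))) {
      stream <- stream + 1L
      sid <- p$samples$sample_id[j]
      set.seed(derive_seed(config$seed, stream))
      ass <- .sample_assignments(p, sid, config)
      recs <- .sample_receptors(ass, p, config)
      contigs <- emit_contigs(ass, recs, config)
      counts <- emit_expression(ass)
      sdir <- file.path(outdir, sid)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      write_contigs(contigs, file.path(sdir, "filtered_contig_annotations.csv"))
      utils::write.csv(.clonotypes_csv(contigs),
                       file.path(sdir, "clonotypes.csv"),
                       row.names = FALSE, quote = FALSE)
      write_mtx(counts, sdir)
      manifest[[length(manifest) + 1]] <- data.frame(
        sample_id = sid, participant_id = p$participant_id,
        compartment = p$samples$compartment[j],
        post_transplant_day = p$samples$post_transplant_day[j],
        is_arm = p$is_arm, vdj_dir = sdir, gex_dir = sdir,
        stringsAsFactors = FALSE)
      truth_clono[[sid]] <- do.call(rbind, lapply(p$clones, function(cl) {
        n <- as.integer(unname(cl$size_by_sample[sid]) %||% 0L)
        if (is.na(n)) n <- 0L
        data.frame(participant_id = p$participant_id, sample_id = sid,
                   clone_id = cl$clone_id,
                   key = clonotype_key(cl$alpha_cdr3_nt, cl$beta_cdr3_nt),
                   lineage = cl$lineage, program = cl$phenotype_program,
                   size = n, expanded = n > 2, stringsAsFactors = FALSE)
      }))
      truth_bc[[sid]] <- data.frame(
        sample_id = sid, barcode = ass$barcode, clone_id = ass$clone_id,
        lineage = ass$lineage, program = ass$program,
        is_mito_outlier = ass$is_mito_outlier,
        is_low_gene = ass$is_low_gene, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  clono <- do.call(rbind, truth_clono)
  rownames(clono) <- NULL
  present <- clono[clono$size > 0, , drop = FALSE]
  shared_samples <- do.call(rbind, lapply(
    split(present, present$participant_id), function(d) {
      t <- table(d$key)
      k <- names(t)[t > 1]
      if (length(k) == 0) return(NULL)
      data.frame(participant_id = d$participant_id[1], key = k,
                 stringsAsFactors = FALSE)
    }))
  pm <- merge(present, manifest[, c("sample_id", "compartment")],
              by = "sample_id")
  shared_comp <- do.call(rbind, lapply(
    split(pm, pm$participant_id), function(d) {
      k <- intersect(d$key[d$compartment == "biopsy"],
                     d$key[d$compartment == "urine"])
      if (length(k) == 0) return(NULL)
      data.frame(participant_id = d$participant_id[1], key = k,
                 stringsAsFactors = FALSE)
    }))
  truth <- list(clonotypes = clono,
                barcodes = do.call(rbind, truth_bc),
                shared_across_samples = shared_samples,
                shared_across_compartments = shared_comp)
  write_manifest(manifest, file.path(outdir, "manifest.yaml"))
  jsonlite::write_json(
    list(clonotypes = clono,
         shared_across_samples = shared_samples,
         shared_across_compartments = shared_comp,
         seed = config$seed),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, truth = truth, outdir = outdir))
}
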