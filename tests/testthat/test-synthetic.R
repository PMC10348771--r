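zero_noise_config <- function(participants, seed, cells = 50) {
  cohort_config(participants, seed = seed, chain_recovery_rate = 1,
                dual_alpha_rate = 0, doublet_rate = 0,
                mito_outlier_rate = 0, low_gene_rate = 0,
                cells_per_sample = cells)
}

one_clone_participant <- function(size = 3, sid = "S1") {
  samples <- data.frame(sample_id = sid, compartment = "biopsy",
                        post_transplant_day = 100L)
  clone <- clone_spec("c1", alpha_cdr3_nt = "TGTGCAGCAGCAGCA",
                      beta_cdr3_nt = "TGTGCCAGCAGCAGC",
                      size_by_sample = stats::setNames(size, sid))
  participant_spec("P1", "tacrolimus", samples, list(clone))
}

test_that("config invariants are enforced with named fields", {
  p <- one_clone_participant()
  expect_error(cohort_config(list(p), 1, chain_recovery_rate = 1.2),
               "chain_recovery_rate")
  expect_error(cohort_config(list(p), 1, cells_per_sample = 0),
               "cells_per_sample")
  bad <- one_clone_participant()
  bad$clones[[1]]$alpha_cdr3_nt <- "TGTGC"   # not a codon multiple
  expect_error(cohort_config(list(bad), 1), "length")
  two_days <- one_clone_participant()
  two_days$samples <- data.frame(
    sample_id = c("S1", "S2"), compartment = "biopsy",
    post_transplant_day = c(100L, 100L))
  expect_error(cohort_config(list(two_days), 1), "strictly increasing")
  dup <- participant_spec("P2", "none", one_clone_participant()$samples,
                          one_clone_participant()$clones)
  expect_error(cohort_config(list(one_clone_participant(), dup), 1),
               "unique")
  big <- one_clone_participant(size = 100)
  expect_error(cohort_config(list(big), 1, cells_per_sample = 50),
               "exceed")
})

test_that("zero-noise single clone of 3 yields exactly 3 barcodes on one pair", {
  cfg <- zero_noise_config(list(one_clone_participant(3)), seed = 101,
                           cells = 3)
  # 3 cells total: all clone members, no background
  out <- withr::local_tempdir()
  res <- generate_cohort(cfg, out)
  contigs <- read_contigs(file.path(out, "S1",
                                    "filtered_contig_annotations.csv"))
  expect_equal(length(unique(contigs$barcode)), 3)
  expect_equal(sort(unique(contigs$cdr3_nt)),
               c("TGTGCAGCAGCAGCA", "TGTGCCAGCAGCAGC"))
  per_bc <- table(contigs$barcode, contigs$chain)
  expect_true(all(per_bc[, "TRA"] == 1 & per_bc[, "TRB"] == 1))
  expect_true(all(contigs$productive & contigs$full_length))
})

test_that("regeneration with the same seed is byte-identical", {
  cfg <- design_cohort(seed = 19, n_participants = 1, n_timepoints = 2,
                       cells_per_sample = 250, n_clones = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_equal(files, sort(list.files(d2, recursive = TRUE)))
  files <- setdiff(files, "manifest.yaml")  # holds the output paths
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     label = f)
  }
})

test_that("truth registry counts expanded keys and covers every barcode", {
  cfg <- design_cohort(seed = 29, n_participants = 2, n_timepoints = 2,
                       cells_per_sample = 400, n_clones = 12,
                       zero_noise = TRUE)
  out <- withr::local_tempdir()
  res <- generate_cohort(cfg, out)
  truth <- res$truth
  expect_true(all(truth$clonotypes$expanded == (truth$clonotypes$size > 2)))
  for (sid in res$manifest$sample_id) {
    contigs <- read_contigs(file.path(out, sid,
                                      "filtered_contig_annotations.csv"))
    sidecar <- readLines(file.path(out, sid, "barcodes.tsv"))
    bcs <- truth$barcodes[truth$barcodes$sample_id == sid, ]
    # referential integrity: every truth barcode is in the sidecar, and
    # every contig barcode is a truth barcode
    expect_true(all(bcs$barcode %in% sidecar))
    expect_true(all(contigs$barcode %in% bcs$barcode))
    # receptor-bearing lineages only
    rec_lin <- bcs$lineage[match(unique(contigs$barcode), bcs$barcode)]
    expect_true(all(rec_lin %in% c("CD8_T", "CD4_T", "gd_T")))
  }
  # planted expanded count equals the truth registry count per sample
  reg <- truth$clonotypes
  for (sid in unique(reg$sample_id)) {
    n_exp <- sum(reg$size[reg$sample_id == sid] > 2)
    expect_equal(sum(reg$expanded[reg$sample_id == sid]), n_exp)
  }
})

test_that("contig marginal rates recover configured values within 3 SD", {
  p <- one_clone_participant(0, sid = "S1")
  cfg <- cohort_config(list(p), seed = 71, chain_recovery_rate = 0.9,
                       dual_alpha_rate = 0.08, doublet_rate = 0,
                       mito_outlier_rate = 0, low_gene_rate = 0,
                       cells_per_sample = 10000)
  set.seed(713)
  n <- 10000
  ass <- data.frame(
    barcode = sprintf("BC%05d-1", 1:n), clone_id = NA_character_,
    lineage = "CD8_T", program = "none",
    is_mito_outlier = FALSE, is_low_gene = FALSE, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(n), function(i) {
    n_alpha <- if (runif(1) < cfg$dual_alpha_rate) 2 else 1
    list(alpha_nt = random_cdr3(n_alpha), beta_nt = random_cdr3(1))
  })
  names(recs) <- ass$barcode
  contigs <- emit_contigs(ass, recs, cfg)
  rec <- build_receptors(collapse_variants(contigs), ass$barcode)
  paired <- mean(rec$n_alpha >= 1 & rec$n_beta >= 1)
  sd_pair <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(paired - 0.9), 3 * sd_pair)
  dual <- mean(rec$n_alpha[rec$n_alpha >= 1] == 2)
  n_alpha_bearing <- sum(rec$n_alpha >= 1)
  sd_dual <- sqrt(0.08 * 0.92 / n_alpha_bearing)
  expect_lt(abs(dual - 0.08), 3 * sd_dual)
})

test_that("boundary rates behave: dual_alpha 1 doubles alphas, dropout 0 pairs all", {
  p <- one_clone_participant(0)
  cfg <- cohort_config(list(p), seed = 73, chain_recovery_rate = 1,
                       dual_alpha_rate = 1, doublet_rate = 0,
                       mito_outlier_rate = 0, low_gene_rate = 0,
                       cells_per_sample = 100)
  set.seed(731)
  ass <- data.frame(
    barcode = sprintf("BC%03d-1", 1:100), clone_id = NA_character_,
    lineage = "CD8_T", program = "none",
    is_mito_outlier = FALSE, is_low_gene = FALSE, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(100), function(i)
    list(alpha_nt = random_cdr3(2), beta_nt = random_cdr3(1)))
  names(recs) <- ass$barcode
  contigs <- emit_contigs(ass, recs, cfg)
  tab <- table(contigs$barcode, contigs$chain)
  expect_true(all(tab[, "TRA"] == 2))
  expect_true(all(tab[, "TRB"] == 1))
})

test_that("expression model places markers, QC outliers and programs as planted", {
  set.seed(81)
  n <- 500
  ass <- data.frame(
    barcode = sprintf("E%04d-1", 1:n),
    lineage = rep(c("CD8_T", "CD4_T"), each = n / 2),
    program = rep(c("activated", "none"), each = n / 2),
    is_mito_outlier = c(rep(TRUE, 20), rep(FALSE, n - 20)),
    is_low_gene = c(rep(FALSE, 40), rep(TRUE, 20), rep(FALSE, n - 60)),
    stringsAsFactors = FALSE)
  counts <- emit_expression(ass)
  mito <- grep("^MT-", rownames(counts))
  frac <- Matrix::colSums(counts[mito, ]) / Matrix::colSums(counts)
  expect_true(all(frac[1:20] > 0.25))          # outliers by construction
  n_genes <- Matrix::colSums(counts > 0)
  expect_true(all(n_genes[41:60] < 200))       # low-gene cells
  expect_true(all(n_genes[61:n] >= 200))       # normal cells clear the QC bar
  cd8 <- which(ass$lineage == "CD8_T" & !ass$is_low_gene)
  cd4 <- which(ass$lineage == "CD4_T" & !ass$is_low_gene)
  expect_gte(mean(counts["CD8A", cd8] > 0), 0.95)
  expect_gte(mean(counts["CD4", cd8] == 0), 0.95)
  expect_gte(mean(counts["CD4", cd4] > 0), 0.95)
  # activated program raises GZMB: two-sample check on planted groups
  expect_gt(mean(counts["GZMB", cd8]), mean(counts["GZMB", cd4]) + 2)
})
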