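test_that("variant collapsing maps gene variants onto TRA/TRB loci", {
  contigs <- rbind(
    contig_row("A-1", "TRA", "TGTGCAGCA"),
    contig_row("A-1", "Multi", "TGTGCCAGC", v_gene = "TRBV12-3*01"),
    contig_row("B-1", "TRD", "TGTGCCTCC"),
    contig_row("C-1", "Multi", "TGTGCATCC", v_gene = "IGHV1-2*02",
               j_gene = "IGHJ4*02")
  )
  out <- collapse_variants(contigs)
  expect_equal(out$chain, c("TRA", "TRB", "TRD", "Multi"))
  expect_equal(out$chain_flagged, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$v_gene[2], "TRBV12-3")        # allele suffix stripped
  expect_equal(out$cdr3_nt, contigs$cdr3_nt)     # CDR3 untouched
})

test_that("receptor assembly pairs chains, filters and flags malformation", {
  contigs <- collapse_variants(rbind(
    contig_row("pair-1", "TRA", "TGTGCAGCA"),
    contig_row("pair-1", "TRB", "TGTGCCAGC"),
    contig_row("bonly-1", "TRB", "TGTGCCTCC"),
    contig_row("dup-1", "TRA", "TGTGCAGCA"),
    contig_row("dup-1", "TRA", "TGTGCAGCA"),     # duplicate CDR3 deduped
    contig_row("dup-1", "TRB", "TGTGCCAGC"),
    contig_row("bad-1", "TRA", "TGTAAAGCA"),
    contig_row("bad-1", "TRA", "TGTCCCGCA"),
    contig_row("bad-1", "TRA", "TGTGGGGCA"),     # 3 alphas -> malformed
    contig_row("bad-1", "TRB", "TGTGCCAGC"),
    contig_row("unprod-1", "TRB", "TGTGCCAGC", productive = FALSE),
    contig_row("gd-1", "TRD", "TGTGACAGC"),
    contig_row("notcd8-1", "TRA", "TGTGCAGCA")
  ))
  cd8 <- c("pair-1", "bonly-1", "dup-1", "bad-1", "unprod-1", "gd-1")
  rec <- build_receptors(contigs, cd8)
  expect_setequal(rec$barcode, c("pair-1", "bonly-1", "dup-1", "bad-1"))
  p <- rec[rec$barcode == "pair-1", ]
  expect_equal(c(p$n_alpha, p$n_beta), c(1L, 1L))
  expect_equal(rec[rec$barcode == "bonly-1", "n_alpha"], 0L)
  expect_equal(rec[rec$barcode == "dup-1", "n_alpha"], 1L)
  expect_true(rec[rec$barcode == "bad-1", "malformed"])
  # alpha sets are sorted so keys are order-independent
  r2 <- build_receptors(collapse_variants(rbind(
    contig_row("x-1", "TRA", "TTTGCAGCA"),
    contig_row("x-1", "TRA", "AAAGCAGCA"),
    contig_row("x-1", "TRB", "TGTGCCAGC"))), "x-1")
  expect_equal(r2$alpha_nt, "AAAGCAGCA;TTTGCAGCA")
})

test_that("expansion rule boundary is exhaustive: >2 cells, dual-beta, single chain", {
  a <- "TGTGCAGCAGCAGCA"; b <- "TGTGCCAGCAGCAGC"
  make_clone <- function(n) do.call(rbind, lapply(seq_len(n), function(i)
    receptor_row(sprintf("c%d-1", i), a, b)))
  for (n in 1:5) {
    calls <- call_clonotypes(make_clone(n))
    expect_equal(nrow(calls$clonotypes), 1)
    expect_equal(calls$clonotypes$size, n)
    expect_equal(calls$clonotypes$status,
                 if (n > 2) "expanded" else "unexpanded",
                 label = sprintf("size %d", n))
  }
  # 5 cells each bearing 2 beta chains -> 5 keyless unexpanded units
  dual_b <- do.call(rbind, lapply(1:5, function(i)
    receptor_row(sprintf("d%d-1", i), a, c(b, "TGTAAAAGCAGCAGC"))))
  calls <- call_clonotypes(dual_b)
  expect_equal(nrow(calls$clonotypes), 0)
  expect_equal(nrow(calls$keyless), 5)
  expect_true(all(calls$keyless$status == "unexpanded"))
  expect_true(all(calls$keyless$reason == "dual_beta"))
  # single-chain receptors are keyless whatever their multiplicity
  aonly <- do.call(rbind, lapply(1:4, function(i)
    receptor_row(sprintf("a%d-1", i), a, character(0))))
  bonly <- do.call(rbind, lapply(1:4, function(i)
    receptor_row(sprintf("b%d-1", i), character(0), b)))
  calls <- call_clonotypes(rbind(aonly, bonly))
  expect_equal(nrow(calls$clonotypes), 0)
  expect_equal(nrow(calls$keyless), 8)
  expect_setequal(unique(calls$keyless$reason), c("beta_only", "alpha_only"))
  # dual-alpha receptors merge only on the identical full alpha set
  a2 <- "TGTCCCGCAGCAGCA"
  mixed <- rbind(
    receptor_row("m1-1", c(a, a2), b),
    receptor_row("m2-1", c(a, a2), b),
    receptor_row("m3-1", a, b)          # partial alpha overlap: own clone
  )
  calls <- call_clonotypes(mixed)
  expect_equal(sort(calls$clonotypes$size), c(1L, 2L))
})

test_that("clonotype grouping equals a brute-force all-pairs oracle", {
  set.seed(41)
  pool_a <- random_cdr3(12)
  pool_b <- random_cdr3(12)
  rec <- do.call(rbind, lapply(1:80, function(i) {
    n_a <- sample(0:2, 1, prob = c(.15, .65, .2))
    n_b <- sample(0:2, 1, prob = c(.1, .75, .15))
    receptor_row(sprintf("r%03d-1", i),
                 sample(pool_a, n_a), sample(pool_b, n_b))
  }))
  calls <- call_clonotypes(rec)
  # oracle: naive all-pairs comparison on (sorted alpha set, beta)
  keyed <- rec[rec$n_alpha >= 1 & rec$n_alpha <= 2 & rec$n_beta == 1, ]
  same <- function(i, j) {
    keyed$alpha_nt[i] == keyed$alpha_nt[j] &&
      keyed$beta_nt[i] == keyed$beta_nt[j]
  }
  groups <- list()
  for (i in seq_len(nrow(keyed))) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (same(i, groups[[g]][1])) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  expect_equal(nrow(calls$clonotypes), length(groups))
  expect_equal(sort(calls$clonotypes$size), sort(lengths(groups)),
               ignore_attr = TRUE)
  # partition: every receptor is in exactly one clonotype or keyless unit
  bcs_in_clones <- unlist(strsplit(calls$clonotypes$barcodes, ","))
  expect_equal(sort(c(bcs_in_clones, calls$keyless$barcode)),
               sort(rec$barcode))
  expect_equal(sum(calls$clonotypes$size) + nrow(calls$keyless), nrow(rec))
})

test_that("expansion status is invariant under barcode relabeling and order", {
  rec <- clonal_receptors(n_exp = 4, n_single = 10, seed = 6)
  calls1 <- call_clonotypes(rec)
  shuffled <- rec[sample(nrow(rec)), ]
  shuffled$barcode <- sprintf("NEW%04d-1", seq_len(nrow(shuffled)))
  calls2 <- call_clonotypes(shuffled)
  expect_equal(calls1$clonotypes[order(calls1$clonotypes$key),
                                 c("key", "size", "status")],
               calls2$clonotypes[order(calls2$clonotypes$key),
                                 c("key", "size", "status")],
               ignore_attr = TRUE)
})

test_that("amino-acid keying groups nt variants encoding the same protein", {
  # two nt sequences translating to the same peptide
  rec <- rbind(
    receptor_row("s1-1", "TGTGCA", "TGCGCC"),
    receptor_row("s2-1", "TGTGCA", "TGTGCA"),
    receptor_row("s3-1", "TGTGCA", "TGTGCT")
  )
  rec$alpha_aa <- "CA"
  rec$beta_aa <- "CA"  # all betas translate to CA
  nt_calls <- call_clonotypes(rec, key_level = "nt")
  aa_calls <- call_clonotypes(rec, key_level = "aa")
  expect_equal(nrow(nt_calls$clonotypes), 3)
  expect_equal(nrow(aa_calls$clonotypes), 1)
  expect_equal(aa_calls$clonotypes$status, "expanded")
})

test_that("dual-alpha percentages are computed per stratum with a z-test", {
  a <- random_cdr3(8); b <- random_cdr3(8)
  # expanded clone of 4 (dual alpha), one of 3 (single alpha), 3 singletons
  rec <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      receptor_row(sprintf("e%d-1", i), c(a[1], a[2]), b[1]))),
    do.call(rbind, lapply(1:3, function(i)
      receptor_row(sprintf("f%d-1", i), a[3], b[2]))),
    receptor_row("g1-1", a[4], b[3]),
    receptor_row("g2-1", c(a[5], a[6]), b[4]),
    receptor_row("g3-1", a[7], b[5])
  )
  calls <- call_clonotypes(rec)
  da <- dual_alpha_stats(calls, rec)
  expect_equal(da$pct_dual_alpha_expanded, 100 * 4 / 7)
  expect_equal(da$pct_dual_alpha_unexpanded, 100 * 1 / 3)
  expect_true(da$p_value >= 0 && da$p_value <= 1)
  # degenerate strata
  none <- call_clonotypes(rec[8:10, ])
  expect_warning(da0 <- dual_alpha_stats(none, rec[8:10, ]), "empty stratum")
  expect_true(is.nan(da0$pct_dual_alpha_expanded))
})

test_that("clonal summaries reproduce printed expanded-clonotype ratios", {
  # 26 expanded out of 336 total clonotypes -> 7.7%
  rec <- clonal_receptors(n_exp = 26, n_single = 310, seed = 2)
  s <- summarize_sample(call_clonotypes(rec), "index_biopsy")
  expect_equal(s$n_clonotypes_total, 336)
  expect_equal(s$n_expanded, 26)
  expect_equal(s$pct_expanded, 7.7)
  expect_equal(s$n_expanded + s$n_unexpanded, s$n_clonotypes_total)
  expect_equal(s$n_cd8_cells_with_receptor, 26 * 3 + 310)
  # 24 of 182 -> 13.2%
  rec <- clonal_receptors(n_exp = 24, n_single = 158, seed = 3)
  expect_equal(summarize_sample(call_clonotypes(rec), "s")$pct_expanded, 13.2)
  # 0 of 50 -> 0.0, and keyless units count in the denominator
  rec <- clonal_receptors(n_exp = 0, n_single = 50, seed = 4)
  expect_equal(summarize_sample(call_clonotypes(rec), "s")$pct_expanded, 0)
  single_chain <- do.call(rbind, lapply(1:10, function(i)
    receptor_row(sprintf("k%d-1", i), random_cdr3(1), character(0))))
  s2 <- summarize_sample(call_clonotypes(rbind(rec, single_chain)), "s")
  expect_equal(s2$n_clonotypes_total, 60)
})
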