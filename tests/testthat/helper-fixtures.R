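# Shared fixture builders. Everything is generated in code; no binary files.

# a tiny count matrix with named genes/cells
toy_counts <- function(values, genes, cells) {
  m <- matrix(values, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, cells))
  Matrix::Matrix(m, sparse = TRUE)
}

# one contig row in the filtered-contig layout
contig_row <- function(barcode, chain, cdr3_nt, cdr3 = "CASSF",
                       v_gene = paste0(chain, "V1-1*01"),
                       j_gene = paste0(chain, "J2*01"),
                       productive = TRUE, full_length = TRUE,
                       high_confidence = TRUE) {
  data.frame(barcode = barcode, is_cell = TRUE,
             contig_id = paste0(barcode, "_", chain, "_", substr(cdr3_nt, 1, 6)),
             high_confidence = high_confidence, chain = chain,
             v_gene = v_gene, d_gene = "", j_gene = j_gene,
             cdr3 = cdr3, cdr3_nt = cdr3_nt,
             productive = productive, full_length = full_length,
             reads = 1000L, umis = 5L, raw_clonotype_id = "clonotype1",
             stringsAsFactors = FALSE)
}

# receptor table rows for constructing clonotype calls directly
receptor_row <- function(barcode, alpha_nt, beta_nt) {
  alpha_nt <- sort(alpha_nt)
  data.frame(barcode = barcode,
             alpha_nt = paste(alpha_nt, collapse = ";"),
             beta_nt = paste(beta_nt, collapse = ";"),
             alpha_aa = paste(alpha_nt, collapse = ";"),
             beta_aa = paste(beta_nt, collapse = ";"),
             n_alpha = length(alpha_nt), n_beta = length(beta_nt),
             malformed = length(alpha_nt) > 2 || length(beta_nt) > 2,
             stringsAsFactors = FALSE)
}

# a receptor cohort with n_exp clones of `clone_size` cells plus n_single
# paired singletons, all keys distinct
clonal_receptors <- function(n_exp, n_single, clone_size = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  k <- 0
  for (i in seq_len(n_exp)) {
    a <- random_cdr3(1); b <- random_cdr3(1)
    for (j in seq_len(clone_size)) {
      k <- k + 1
      rows[[k]] <- receptor_row(sprintf("BC%05d-1", k), a, b)
    }
  }
  for (i in seq_len(n_single)) {
    k <- k + 1
    rows[[k]] <- receptor_row(sprintf("BC%05d-1", k), random_cdr3(1),
                              random_cdr3(1))
  }
  do.call(rbind, rows)
}

# manifest for hand-built per-sample clonotype calls (tracking tests)
toy_manifest <- function(samples) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id,
               participant_id = s$participant_id %||% "P1",
               compartment = s$compartment %||% "biopsy",
               post_transplant_day = s$day,
               is_arm = "tacrolimus", vdj_dir = ".", gex_dir = ".",
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clonotype-calls object from (key, size, status) triples
toy_calls <- function(keys, sizes, n_keyless = 0) {
  status <- ifelse(sizes >= 3, "expanded", "unexpanded")
  bcs <- vapply(seq_along(keys), function(i)
    paste(sprintf("S%02d_%03d", i, seq_len(sizes[i])), collapse = ","),
    character(1))
  cl <- data.frame(key = keys, size = sizes, status = status,
                   n_dual_alpha = 0L, barcodes = bcs,
                   stringsAsFactors = FALSE)
  keyless <- data.frame(
    barcode = if (n_keyless > 0) sprintf("KL%03d", seq_len(n_keyless))
      else character(0),
    reason = rep("beta_only", n_keyless), n_alpha = rep(0L, n_keyless),
    n_beta = rep(1L, n_keyless), status = rep("unexpanded", n_keyless),
    stringsAsFactors = FALSE)
  list(clonotypes = cl, keyless = keyless,
       log = c(receptors_in = sum(sizes) + n_keyless,
               keyed = sum(sizes), keyless = n_keyless, malformed = 0L))
}
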