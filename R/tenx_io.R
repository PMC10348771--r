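# Reading and writing of the 10x-style file layouts (filtered contig
# annotations, clonotypes, MatrixMarket counts with barcode/feature sidecars)
# and the cohort manifest. Single source of truth for dialects: internal
# coordinates are 0-based R objects, MTX is 1-based at the file boundary,
# barcodes are kept verbatim including any GEM-well "-1" suffix.

.contig_mandatory <- c(
  "barcode", "chain", "cdr3", "cdr3_nt", "productive", "full_length",
  "high_confidence"
)

.contig_canonical <- c(
  "barcode", "is_cell", "contig_id", "high_confidence", "chain",
  "v_gene", "d_gene", "j_gene", "cdr3", "cdr3_nt", "productive",
  "full_length", "reads", "umis", "raw_clonotype_id"
)

.parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1")
}

#' Read a filtered contig annotation CSV
#'
#' Parses a 10x-style `filtered_contig_annotations.csv`. Boolean columns are
#' accepted in any of the `True/true/TRUE` spellings; columns beyond the
#' canonical set are preserved untouched so nothing is silently dropped.
#'
#' @param path path to the CSV file
#' @return data.frame with one row per contig; mandatory columns
#'   `barcode, chain, cdr3, cdr3_nt, productive, full_length,
#'   high_confidence` are always present and booleans are logical
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stopf("contig file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.contig_mandatory, names(df))
  if (length(missing) > 0) {
    stopf("contig file %s is missing mandatory column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warnf("contig file %s has a header but no rows", path)
    return(df)
  }
  for (col in c("productive", "full_length", "high_confidence", "is_cell")) {
    if (col %in% names(df)) df[[col]] <- .parse_bool(df[[col]])
  }
  if (any(df$barcode == "" | is.na(df$barcode))) {
    stopf("contig file %s contains empty barcodes", path)
  }
  df
}

#' Write contig records as a filtered contig annotation CSV
#'
#' @param contigs data.frame of contig records
#' @param path output path
#' @return invisibly, `path`
#' @export
write_contigs <- function(contigs, path) {
  out <- contigs
  for (col in c("is_cell", "high_confidence", "productive", "full_length")) {
    if (col %in% names(out)) {
      out[[col]] <- ifelse(out[[col]], "True", "False")
    }
  }
  cols <- c(intersect(.contig_canonical, names(out)),
            setdiff(names(out), .contig_canonical))
  utils::write.csv(out[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clonotypes.csv summary file
#'
#' Read for completeness of the layout; clonotype identity is always
#' recomputed from contigs because `raw_clonotype_id` is per-sample and
#' cannot support cross-sample matching.
#'
#' @param path path to clonotypes.csv
#' @return data.frame with at least `clonotype_id` and `frequency`
#' @export
read_clonotypes_file <- function(path) {
  if (!file.exists(path)) stopf("clonotypes file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("clonotype_id", "frequency"), names(df))
  if (length(missing) > 0) {
    stopf("clonotypes file %s is missing column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  df
}

#' Read a 10x-style Matrix Market count directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` under `dirpath`.
#' File indices are 1-based MatrixMarket coordinates; duplicate (i, j)
#' entries are summed per the MatrixMarket convention.
#'
#' @param dirpath directory containing the three files
#' @return a `dgCMatrix` genes x cells with feature ids as rownames and
#'   verbatim barcodes as colnames
#' @export
read_mtx <- function(dirpath) {
  paths <- file.path(dirpath, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stopf("missing count file(s): %s", paste(missing, collapse = ", "))
  }
  m <- Matrix::readMM(paths[1])
  m <- methods::as(m, "CsparseMatrix")  # sums duplicate triplets
  barcodes <- readLines(paths[2])
  features <- utils::read.table(paths[3], sep = "\t",
                                stringsAsFactors = FALSE)
  if (nrow(m) != nrow(features) || ncol(m) != length(barcodes)) {
    stopf("matrix dimensions %d x %d do not match %d features / %d barcodes",
          nrow(m), ncol(m), nrow(features), length(barcodes))
  }
  if (anyDuplicated(barcodes)) stopf("duplicate barcodes in %s", paths[2])
  dimnames(m) <- list(features[[1]], barcodes)
  m
}

#' Write a count matrix in the 10x Matrix Market layout
#'
#' @param counts genes x cells matrix (coerced to sparse); rownames are
#'   feature ids, colnames are barcodes
#' @param dirpath output directory (created if needed)
#' @return invisibly, `dirpath`
#' @export
write_mtx <- function(counts, dirpath) {
  dir.create(dirpath, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dirpath, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dirpath, "barcodes.tsv"))
  feat <- data.frame(id = rownames(counts), name = rownames(counts),
                     type = "Gene Expression")
  utils::write.table(feat, file.path(dirpath, "features.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dirpath)
}

#' Read a cohort manifest
#'
#' The manifest lists one entry per sample: sample id, participant,
#' compartment (biopsy or urine), post-transplant day, immunosuppression arm
#' and the paths of its V(D)J and gene-expression files.
#'
#' @param path path to a manifest YAML file
#' @return data.frame with columns `sample_id, participant_id, compartment,
#'   post_transplant_day, is_arm, vdj_dir, gex_dir`
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$samples) || length(y$samples) == 0) {
    stopf("manifest %s lists no samples", path)
  }
  rows <- lapply(y$samples, function(s) {
    data.frame(
      sample_id = s$sample_id, participant_id = s$participant_id,
      compartment = s$compartment,
      post_transplant_day = as.integer(s$post_transplant_day),
      is_arm = s$is_arm %||% "none",
      vdj_dir = s$vdj_dir, gex_dir = s$gex_dir,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a cohort manifest
#'
#' @param manifest data.frame as returned by [read_manifest()]
#' @param path output YAML path
#' @return invisibly, `path`
#' @export
write_manifest <- function(manifest, path) {
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    as.list(manifest[i, , drop = FALSE])
  })
  samples <- lapply(samples, function(s) {
    s$post_transplant_day <- as.integer(s$post_transplant_day)
    lapply(s, function(v) if (is.factor(v)) as.character(v) else v)
  })
  yaml::write_yaml(list(samples = samples), path)
  invisible(path)
}

#' Write result tables and a machine-readable run report
#'
#' Emits each element of `results` whose value is a data.frame as a TSV with
#' a stable column order (empty tables produce a header-only file), plus a
#' `run_report.json` holding versions, seed and every decided threshold.
#'
#' @param results named list of data.frames
#' @param outdir output directory (created if needed)
#' @param report named list appended to the run report (seed, config, ...)
#' @return invisibly, character vector of files written
#' @export
write_tables <- function(results, outdir, report = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (!is.data.frame(x)) next
    path <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  report$package_version <- as.character(utils::packageVersion("clonotrack"))
  report$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  rp <- file.path(outdir, "run_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(written, rp))
}
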