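#' Write a cohort to disk in Matrix Market interchange format
#'
#' Emits `matrix.mtx` (genes x cells), `genes.tsv`, `barcodes.tsv`,
#' `metadata.tsv` (barcode, animal_id, animal_type, cell_type, batch plus QC
#' covariates), and, when present, `effect_truth.tsv` (long format, affected
#' entries only) and `manifest.json` recording the full simulation config and
#' seed.
#'
#' @param cohort A `cell_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cohort$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cohort$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(cohort$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(cohort$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.table(truth_to_table(cohort$truth),
                       file.path(dir, "effect_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$config)) {
    jsonlite::write_json(unclass(cohort$config), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and `metadata.tsv`.
#' @return A `cell_cohort`.
#' @export
read_cohort <- function(dir) {
  f <- function(x) file.path(dir, x)
  for (x in c("matrix.mtx", "genes.tsv", "barcodes.tsv", "metadata.tsv")) {
    if (!file.exists(f(x))) stop("missing cohort file: ", f(x), call. = FALSE)
  }
  counts <- methods::as(Matrix::readMM(f("matrix.mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(f("genes.tsv"))
  colnames(counts) <- readLines(f("barcodes.tsv"))
  meta <- utils::read.delim(f("metadata.tsv"), stringsAsFactors = FALSE)
  rownames(meta) <- meta$barcode
  truth <- NULL
  if (file.exists(f("effect_truth.tsv")) && file.exists(f("manifest.json"))) {
    # truth table is informational on read; matrices are rebuilt lazily by
    # consumers that need them (tests regenerate from the manifest config)
    truth <- utils::read.delim(f("effect_truth.tsv"), stringsAsFactors = FALSE)
  }
  new_cell_cohort(counts, meta, truth = truth)
}

#' Long-format view of an effect-truth object
#'
#' @param truth An `effect_truth`.
#' @return data.frame with columns gene, cell_type, a, sY, sO, r, q (rows
#'   limited to entries where at least one effect is nonzero).
#' @export
truth_to_table <- function(truth) {
  stopifnot(inherits(truth, "effect_truth"))
  out <- do.call(rbind, lapply(truth$cell_types, function(ct) {
    df <- data.frame(gene = truth$genes, cell_type = ct,
                     a = truth$a[, ct], sY = truth$sY[, ct], sO = truth$sO[, ct],
                     r = truth$r[, ct], q = truth$q[, ct],
                     stringsAsFactors = FALSE)
    df[rowSums(abs(df[, c("a", "sY", "sO", "r", "q")])) > 0, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Write one DGE table per (cell type, contrast)
#'
#' File name pattern `dge_<cellType>_<contrast>.tsv`; columns follow the
#' pseudobulk results schema (gene, logFC, logCPM, F, p_val, p_adj.loc,
#' p_adj.glb, tpm.<TYPE>, pct.<TYPE>).
#'
#' @param dge Nested list as returned by [run_dge()] (`res$tables`).
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_dge_tables <- function(dge, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ct in names(dge)) {
    for (cn in names(dge[[ct]])) {
      fn <- file.path(dir, sprintf("dge_%s_%s.tsv", ct, cn))
      utils::write.table(dge[[ct]][[cn]], fn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, fn)
    }
  }
  invisible(files)
}

#' Read DGE tables written by [write_dge_tables()]
#'
#' @param dir Directory of `dge_*_*.tsv` files.
#' @return Nested list `tables[[cell_type]][[contrast]]`.
#' @export
read_dge_tables <- function(dir) {
  fns <- list.files(dir, pattern = "^dge_.*\\.tsv$", full.names = TRUE)
  out <- list()
  for (fn in fns) {
    parts <- strsplit(sub("\\.tsv$", "", basename(fn)), "_")[[1]]
    ct <- parts[2]; cn <- paste(parts[-(1:2)], collapse = "_")
    out[[ct]][[cn]] <- utils::read.delim(fn, stringsAsFactors = FALSE,
                                         check.names = FALSE)
  }
  out
}
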