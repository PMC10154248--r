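#' Classify genes by their RJV/AGA shift pattern
#'
#' Genes significant (q <= `fdr`) in both contrasts with opposite log2FC
#' signs are bidirectional, subclassed by direction; genes significant in
#' exactly one contrast are `RJV_only` / `AGA_only`; significant in both with
#' the same sign are `concordant`; otherwise `neither`.
#'
#' @param rjv,aga `dge_table`s sharing a gene universe (per cell type).
#' @param fdr Significance threshold on the q-value (default 0.05).
#' @param q_col Which adjusted-p column to threshold (default `p_adj.loc`).
#' @return data.frame of shift records: gene, the two (logFC, q) pairs, the
#'   class, and the signed absolute difference (magnitude, sign).
#' @export
classify_bidirectional <- function(rjv, aga, fdr = 0.05, q_col = "p_adj.loc") {
  mrg <- merge(rjv[, c("gene", "logFC", q_col)],
               aga[, c("gene", "logFC", q_col)],
               by = "gene", suffixes = c(".rjv", ".aga"))
  qr <- mrg[[paste0(q_col, ".rjv")]]; qa <- mrg[[paste0(q_col, ".aga")]]
  lr <- mrg$logFC.rjv; la <- mrg$logFC.aga
  sig_r <- !is.na(qr) & qr <= fdr
  sig_a <- !is.na(qa) & qa <= fdr
  cls <- rep("neither", nrow(mrg))
  cls[sig_r & !sig_a] <- "RJV_only"
  cls[!sig_r & sig_a] <- "AGA_only"
  both <- sig_r & sig_a
  cls[both & lr * la > 0] <- "concordant"
  cls[both & lr < 0 & la > 0] <- "down_in_RJV_up_in_AGA"
  cls[both & lr > 0 & la < 0] <- "up_in_RJV_down_in_AGA"
  cls[both & lr * la == 0] <- "concordant"  # an exact zero has no direction
  sd_ <- signed_abs_difference(lr, la)
  out <- data.frame(gene = mrg$gene,
                    logFC.rjv = lr, q.rjv = qr,
                    logFC.aga = la, q.aga = qa,
                    class = cls,
                    magnitude = sd_$magnitude, sign = sd_$sign,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Signed absolute log2FC difference between two paradigms
#'
#' The reversal statistic: magnitude `|rjv - aga|`, with sign `+` when the
#' first paradigm is up and the second down, `-` when the second is up and
#' the first down, and `0` (no reversal) when both move in the same
#' direction — an exact zero in either input counts as "same direction".
#'
#' @param rjv_log2FC,aga_log2FC Numeric vectors (any pair of per-entity
#'   log2FC tables: genes, transcription factors, regulons...).
#' @return list(magnitude, sign, score) where `sign` is "+", "-" or "0" and
#'   `score` is the signed magnitude (0 when sign is "0").
#' @export
signed_abs_difference <- function(rjv_log2FC, aga_log2FC) {
  stopifnot(length(rjv_log2FC) == length(aga_log2FC),
            all(is.finite(rjv_log2FC)), all(is.finite(aga_log2FC)))
  mag <- abs(rjv_log2FC - aga_log2FC)
  sgn <- rep("0", length(mag))
  sgn[rjv_log2FC > 0 & aga_log2FC < 0] <- "+"
  sgn[aga_log2FC > 0 & rjv_log2FC < 0] <- "-"
  list(magnitude = mag, sign = sgn,
       score = ifelse(sgn == "+", mag, ifelse(sgn == "-", -mag, 0)))
}

.sig_genes <- function(tab, direction, fdr, q_col) {
  q <- tab[[q_col]]
  keep <- !is.na(q) & q <= fdr &
    if (direction == "up") tab$logFC > 0 else tab$logFC < 0
  tab$gene[keep]
}

#' Upset-style intersection counts of significant genes across cell types
#'
#' For each nonempty subset of cell types, counts genes significant with the
#' stated direction in exactly that subset of cell types.
#'
#' @param tables Named list of `dge_table`s, one per cell type (at most 20).
#' @param direction "up" (logFC > 0) or "down" (logFC < 0).
#' @param fdr Significance threshold (default 0.05).
#' @param q_col Adjusted-p column (default `p_adj.loc`).
#' @return data.frame: `subset` (comma-joined cell types), `n_cell_types`,
#'   `count`. Subsets with zero exclusive members are included for
#'   completeness of the power set only when some gene is significant
#'   somewhere; counts sum to the size of the union of significant genes.
#' @export
overlap_sets <- function(tables, direction = c("up", "down"), fdr = 0.05,
                         q_col = "p_adj.loc") {
  direction <- match.arg(direction)
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  if (length(tables) > 20) stop("too many cell types for power-set counts", call. = FALSE)
  sig <- lapply(tables, .sig_genes, direction = direction, fdr = fdr, q_col = q_col)
  univ <- unique(unlist(sig))
  memb <- vapply(sig, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(sig)))
  key <- apply(memb, 1, function(r) paste(names(sig)[r], collapse = ","))
  tab <- table(key)
  out <- data.frame(subset = names(tab),
                    n_cell_types = lengths(strsplit(names(tab), ",")),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition significant genes into common / contrast-only / aging-only
#'
#' Compares a contrast's significant genes (either direction) with the aging
#' comparison's, per cell type.
#'
#' @param contrast_table,aging_table `dge_table`s over a shared gene
#'   universe.
#' @param fdr Significance threshold (default 0.05).
#' @param q_col Adjusted-p column (default `p_adj.loc`).
#' @return list(common, contrast_only, aging_only) of gene character vectors
#'   (disjoint; their union is the union of significant genes).
#' @export
common_unique_vs_aging <- function(contrast_table, aging_table, fdr = 0.05,
                                   q_col = "p_adj.loc") {
  sig <- function(tab) {
    q <- tab[[q_col]]
    tab$gene[!is.na(q) & q <= fdr]
  }
  a <- sig(contrast_table); b <- sig(aging_table)
  list(common = sort(intersect(a, b)),
       contrast_only = sort(setdiff(a, b)),
       aging_only = sort(setdiff(b, a)))
}

#' DGE frequency normalized to population size
#'
#' The number of significant genes per 100 cells of the population:
#' `100 * n_dge / n_cells`.
#'
#' @param n_dge Number of significant genes.
#' @param n_cells Number of cells of the population.
#' @return Numeric frequency (full precision; print with 4 decimals to match
#'   conventional reporting).
#' @export
normalized_dge_frequency <- function(n_dge, n_cells) {
  stopifnot(n_dge >= 0)
  if (any(n_cells <= 0)) stop("n_cells must be positive", call. = FALSE)
  100 * n_dge / n_cells
}
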