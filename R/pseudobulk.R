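#' Aggregate a cohort to per-animal pseudobulk sums
#'
#' Within each cell type, collapses raw counts to integer sums per animal.
#' Animals contributing zero cells of a cell type are absent from that
#' assay.
#'
#' @param cohort A (QC-filtered) `cell_cohort`.
#' @return Named list, one `pseudobulk` object per cell type. Each holds the
#'   genes x animals sum matrix, raw library sizes, TMM normalization
#'   factors (initialized to 1; see [tmm_factors()]), effective library
#'   sizes, the animal-type label per animal and the number of contributing
#'   cells per animal.
#' @export
aggregate_pseudobulk <- function(cohort) {
  m <- cohort$meta
  out <- list()
  for (ct in sort(unique(m$cell_type))) {
    i <- m$cell_type == ct
    anim <- factor(m$animal_id[i])
    ind <- Matrix::sparseMatrix(i = seq_len(sum(i)), j = as.integer(anim),
                                x = 1, dims = c(sum(i), nlevels(anim)))
    sums <- as.matrix(cohort$counts[, i, drop = FALSE] %*% ind)
    colnames(sums) <- levels(anim)
    atype <- m$animal_type[i][match(levels(anim), m$animal_id[i])]
    out[[ct]] <- new_pseudobulk(sums, atype, n_cells = as.integer(table(anim)),
                                cell_type = ct)
  }
  out
}

#' Construct a pseudobulk assay
#'
#' @param counts Integer genes x animals matrix.
#' @param animal_type Animal-type label per animal (column).
#' @param n_cells Cells contributing per animal.
#' @param cell_type Cell-type name.
#' @param norm_factors Normalization factors (default all 1).
#' @return Object of class `pseudobulk`.
#' @export
new_pseudobulk <- function(counts, animal_type, n_cells = NA_integer_,
                           cell_type = NA_character_, norm_factors = NULL) {
  .check_animal_type(animal_type)
  stopifnot(ncol(counts) == length(animal_type))
  lib <- colSums(counts)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  structure(list(counts = counts, animal_type = animal_type,
                 lib_size = lib, norm_factors = norm_factors,
                 eff_lib = lib * norm_factors,
                 n_cells = rep_len(n_cells, ncol(counts)),
                 cell_type = cell_type),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk [%s]: %d genes x %d animals\n",
              x$cell_type, nrow(x$counts), ncol(x$counts)))
  print(table(x$animal_type))
  invisible(x)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between each animal and a reference animal:
#' per-gene log2 ratios (M) and average log2 abundances (A) are computed on
#' library-size-scaled counts, genes in the most extreme 30% of M (each
#' side) or 5% of A (each side) are trimmed, and the remaining M are averaged
#' with inverse approximate-variance weights. Factors are rescaled to
#' geometric mean 1.
#'
#' @param assay A `pseudobulk` (or bare genes x animals matrix).
#' @param reference Reference animal (column name or index), or `NULL` to
#'   pick the animal whose upper-quartile scaled count is closest to the
#'   mean upper quartile.
#' @param logratio_trim,sum_trim Two-sided trim fractions for M and A
#'   (defaults 0.3 and 0.05).
#' @return The assay with `norm_factors` and `eff_lib` updated (or, for a
#'   bare matrix, the numeric factor vector).
#' @export
tmm_factors <- function(assay, reference = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05) {
  mat <- if (inherits(assay, "pseudobulk")) assay$counts else as.matrix(assay)
  if (ncol(mat) < 2) stop("need at least 2 animals", call. = FALSE)
  lib <- colSums(mat)
  if (any(lib == 0)) stop("animal with all-zero counts", call. = FALSE)
  scaled <- sweep(mat, 2, lib, "/")
  if (is.null(reference)) {
    uq <- apply(scaled, 2, stats::quantile, probs = 0.75)
    reference <- which.min(abs(uq - mean(uq)))
  }
  if (is.character(reference)) reference <- match(reference, colnames(mat))
  yr <- mat[, reference]; nr <- lib[reference]
  f <- vapply(seq_len(ncol(mat)), function(k) {
    yk <- mat[, k]; nk <- lib[k]
    ok <- yk > 0 & yr > 0
    if (!any(ok)) return(1)
    M <- log2((yk[ok] / nk) / (yr[ok] / nr))
    A <- 0.5 * log2((yk[ok] / nk) * (yr[ok] / nr))
    w <- (nk - yk[ok]) / (nk * yk[ok]) + (nr - yr[ok]) / (nr * yr[ok])
    # rank-based double trim: drop the extreme 30% of M and 5% of A per side
    nM <- length(M)
    loM <- floor(nM * logratio_trim) + 1; hiM <- nM + 1 - loM
    loA <- floor(nM * sum_trim) + 1; hiA <- nM + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep) || sum(w[keep]) == 0) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  if (inherits(assay, "pseudobulk")) {
    assay$norm_factors <- f
    assay$eff_lib <- assay$lib_size * f
    assay
  } else f
}

#' Filter genes and decide testability of cell types
#'
#' Genes are kept when their total pseudobulk count reaches `min_total_count`
#' and they are detected in at least `min_animals_detected` animals. A cell
#' type is testable for a contrast only when every animal type carrying
#' nonzero contrast weight has at least `min_animals_per_type` contributing
#' animals with at least `min_cells` cells each; otherwise the cell type is
#' skipped with an explicit reason.
#'
#' @param assays Named list of `pseudobulk` objects.
#' @param contrast A [contrast_vec()] (testability is contrast-specific).
#' @param min_total_count,min_animals_detected Gene filters (defaults 10, 2).
#' @param min_animals_per_type,min_cells Cell-type filters (defaults 2, 10).
#' @return list(assays = filtered testable assays, skipped = data.frame of
#'   skipped cell types with reasons, genes_dropped = named integer).
#' @export
filter_test_units <- function(assays, contrast, min_total_count = 10,
                              min_animals_detected = 2,
                              min_animals_per_type = 2, min_cells = 10) {
  kept <- list(); skipped <- list(); dropped <- integer(0)
  need_types <- names(contrast)[contrast != 0]
  for (ct in names(assays)) {
    as_ <- assays[[ct]]
    ok_an <- as_$n_cells >= min_cells
    n_by_type <- table(factor(as_$animal_type[ok_an], levels = animal_types()))
    low <- need_types[n_by_type[need_types] < min_animals_per_type]
    if (length(low)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        cell_type = ct,
        reason = sprintf("fewer than %d animals with >= %d cells in: %s",
                         min_animals_per_type, min_cells,
                         paste(low, collapse = ", ")),
        stringsAsFactors = FALSE
      )
      next
    }
    gk <- rowSums(as_$counts) >= min_total_count &
      rowSums(as_$counts > 0) >= min_animals_detected
    dropped[ct] <- sum(!gk)
    as_$counts <- as_$counts[gk, , drop = FALSE]
    kept[[ct]] <- as_
  }
  list(assays = kept,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(cell_type = character(0), reason = character(0)),
       genes_dropped = dropped)
}

#' Benjamini-Hochberg adjustment with optional grouping
#'
#' Step-up BH within each group (e.g. per cell type for local q-values, or
#' across all cell types of a class for global q-values). Missing p-values
#' propagate as missing and do not consume ranks.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @param group Optional grouping vector; `NULL` adjusts the whole vector
#'   together.
#' @return Vector of BH q-values.
#' @export
bh_adjust <- function(p, group = NULL) {
  if (is.null(group)) return(stats::p.adjust(p, method = "BH"))
  out <- rep(NA_real_, length(p))
  for (g in unique(group)) {
    i <- which(group == g)
    out[i] <- stats::p.adjust(p[i], method = "BH")
  }
  out
}

#' Per-gene TPM and percent-expressing summaries by animal type
#'
#' TPM per animal: pseudobulk counts x 1e6 / raw library size; per animal
#' type, the unweighted mean over that type's animals (set `pooled = TRUE`
#' for the pooled-count variant). Percent expressing per type: the fraction
#' of that type's cells (of this cell type) with raw count >= 1.
#'
#' @param cohort The `cell_cohort` the assay was aggregated from.
#' @param assay A `pseudobulk` for one cell type.
#' @param pooled Use pooled counts across a type's animals instead of the
#'   per-animal mean.
#' @return list(tpm = genes x types matrix, pct = genes x types matrix,
#'   tpm_animal = genes x animals matrix).
#' @export
summarize_tpm_pct <- function(cohort, assay, pooled = FALSE) {
  tpm_an <- sweep(assay$counts, 2, assay$lib_size, "/") * 1e6
  types <- intersect(animal_types(), unique(assay$animal_type))
  tpm <- sapply(types, function(ty) {
    j <- assay$animal_type == ty
    if (pooled) {
      pool <- rowSums(assay$counts[, j, drop = FALSE])
      pool / sum(pool) * 1e6
    } else {
      rowMeans(tpm_an[, j, drop = FALSE])
    }
  })
  i <- if (is.na(assay$cell_type)) rep(TRUE, nrow(cohort$meta)) else
    cohort$meta$cell_type == assay$cell_type
  sub <- cohort$counts[rownames(assay$counts), i, drop = FALSE]
  aty <- cohort$meta$animal_type[i]
  pct <- sapply(types, function(ty) {
    j <- aty == ty
    if (!any(j)) return(rep(NA_real_, nrow(sub)))
    Matrix::rowMeans(sub[, j, drop = FALSE] > 0)
  })
  if (!is.matrix(tpm)) tpm <- matrix(tpm, nrow = nrow(assay$counts),
                                     dimnames = list(NULL, types))
  if (!is.matrix(pct)) pct <- matrix(pct, nrow = nrow(assay$counts),
                                     dimnames = list(NULL, types))
  rownames(tpm) <- rownames(pct) <- rownames(assay$counts)
  list(tpm = tpm, pct = pct, tpm_animal = tpm_an)
}

#' Row-wise z-score of log2 TPM
#'
#' Heatmap preparation: per gene, z-score of log2(TPM + pseudocount) across
#' animals (sample SD). Rows with zero variance map to all-zero rows.
#'
#' @param tpm Genes x animals TPM matrix.
#' @param pseudocount Added before the log2 (default 1).
#' @return Matrix of the same shape.
#' @export
row_zscore_log2 <- function(tpm, pseudocount = 1) {
  if (ncol(tpm) < 2) stop("need at least 2 animals", call. = FALSE)
  lg <- log2(tpm + pseudocount)
  mu <- rowMeans(lg)
  sd <- apply(lg, 1, stats::sd)
  z <- (lg - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}
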