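#' Library-size log-normalization
#'
#' Counts scaled to 10,000 transcripts per cell, then log1p — the standard
#' normalization used before marker testing.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param scale_factor Target per-cell total (default 1e4).
#' @return Sparse matrix of log-normalized values.
#' @export
normalize_log1p <- function(counts, scale_factor = 1e4) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  out <- counts %*% Matrix::Diagonal(x = scale_factor / cs)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Ties handled by midranks. For combined sample sizes up to `exact_max` the
#' null distribution of the rank sum is enumerated exactly over all
#' assignments of the observed (mid)ranks to the first group; above that, a
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined n for which exact enumeration is used
#'   (default 20).
#' @return Two-sided p-value.
#' @export
rank_sum_p <- function(x, y, exact_max = 20) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= exact_max) {
    sets <- utils::combn(n, n1)
    s_all <- colSums(matrix(r[sets], nrow = n1))
    mean(abs(s_all - mu) >= abs(s_obs - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(s_obs - mu) - 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-max(z, 0)))
  }
}

#' Rank-sum cluster markers
#'
#' For every cluster, tests each gene (cluster cells vs all other cells) on
#' log-normalized expression with a two-sided rank-sum test; reports the
#' average log2 fold-change of normalized means (pseudocount 1), the fraction
#' of cells expressing in (`pct.1`) and outside (`pct.2`) the cluster, and a
#' Bonferroni-adjusted p over genes. The `top_n` markers per cluster are the
#' genes with largest positive avg_log2FC.
#'
#' @param cohort A `cell_cohort`.
#' @param cluster_labels One label per cell.
#' @param top_n Markers retained per cluster (default 10).
#' @param all_genes Keep the full table rather than only the top markers.
#' @return data.frame (cluster, gene, avg_log2FC, p_val, p_val_adj, pct.1,
#'   pct.2, rank). Clusters with fewer than 3 cells yield no rows, with a
#'   warning.
#' @export
find_cluster_markers <- function(cohort, cluster_labels, top_n = 10,
                                 all_genes = FALSE) {
  cl <- as.character(cluster_labels)
  if (length(cl) != ncol(cohort$counts)) {
    stop("cluster_labels must have one entry per cell", call. = FALSE)
  }
  ks <- sort(unique(cl))
  if (length(ks) < 2) stop("need at least 2 clusters", call. = FALSE)
  ln <- normalize_log1p(cohort$counts)
  norm <- expm1(ln)  # normalized counts per 10k
  G <- nrow(ln)
  out <- list()
  for (k in ks) {
    in_k <- cl == k
    if (sum(in_k) < 3) {
      warning("cluster ", k, " has fewer than 3 cells; no markers computed")
      next
    }
    m1 <- as.matrix(ln[, in_k, drop = FALSE])
    m2 <- as.matrix(ln[, !in_k, drop = FALSE])
    p <- vapply(seq_len(G), function(g) rank_sum_p(m1[g, ], m2[g, ]), numeric(1))
    mean1 <- Matrix::rowMeans(norm[, in_k, drop = FALSE])
    mean2 <- Matrix::rowMeans(norm[, !in_k, drop = FALSE])
    lfc <- log2((mean1 + 1) / (mean2 + 1))
    df <- data.frame(
      cluster = k, gene = rownames(ln),
      avg_log2FC = lfc, p_val = p, p_val_adj = pmin(1, p * G),
      pct.1 = Matrix::rowMeans(cohort$counts[, in_k, drop = FALSE] > 0),
      pct.2 = Matrix::rowMeans(cohort$counts[, !in_k, drop = FALSE] > 0),
      stringsAsFactors = FALSE
    )
    df <- df[order(-df$avg_log2FC), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    if (!all_genes) df <- df[df$avg_log2FC > 0, , drop = FALSE][seq_len(min(top_n, sum(df$avg_log2FC > 0))), , drop = FALSE]
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag doublet clusters by foreign marker co-expression
#'
#' A cluster is flagged as a probable doublet/multiplet artifact when more
#' than 40% of its cells express (raw count >= 1) at least 7 of the top-10
#' markers of a foreign cell type whose class differs from the cluster's own
#' class.
#'
#' @param cohort A `cell_cohort`.
#' @param cluster_labels One cell-type/cluster label per cell; the cluster's
#'   own type is its label.
#' @param markers Marker table from [find_cluster_markers()] (top markers per
#'   cell type, in the `cluster` column).
#' @param class_map Named character vector mapping every cell type to its
#'   class (e.g. the five-class grouping oligodendrocyte-lineage /
#'   astroependymal / neuronal / vascular / immune).
#' @param frac_threshold Flag when the expressing fraction exceeds this
#'   (default 0.40).
#' @param n_top,n_required Top markers considered and minimum expressed
#'   (default 10 and 7); if a type has fewer than `n_top` markers all
#'   available are used, with a warning.
#' @return data.frame with one row per (cluster, foreign type): the fraction
#'   of cluster cells expressing >= `n_required` foreign markers and the flag.
#' @export
flag_doublet_clusters <- function(cohort, cluster_labels, markers, class_map,
                                  frac_threshold = 0.40, n_top = 10,
                                  n_required = 7) {
  cl <- as.character(cluster_labels)
  ks <- sort(unique(cl))
  types <- sort(unique(markers$cluster))
  miss <- setdiff(c(ks, types), names(class_map))
  if (length(miss)) {
    stop("class_map lacks type(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (k in ks) {
    in_k <- cl == k
    for (ty in types) {
      if (class_map[[ty]] == class_map[[k]]) next
      mk <- markers[markers$cluster == ty, , drop = FALSE]
      mk <- mk[order(mk$rank), , drop = FALSE]
      top <- utils::head(mk$gene, n_top)
      if (length(top) < n_top) {
        warning("type ", ty, " has only ", length(top), " markers; using all")
      }
      top <- intersect(top, rownames(cohort$counts))
      if (!length(top)) next
      expr <- cohort$counts[top, in_k, drop = FALSE] > 0
      n_hit <- Matrix::colSums(expr)
      frac <- mean(n_hit >= n_required)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, foreign_type = ty, fraction = frac,
        flagged = frac > frac_threshold, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(0), foreign_type = character(0),
               fraction = numeric(0), flagged = logical(0))
  rownames(out) <- NULL
  out
}
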