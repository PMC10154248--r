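#' Quality-control thresholds
#'
#' Defaults reproduce a standard two-round droplet QC for brain single-cell
#' data: per-cell bounds on percent-mitochondrial reads, detected genes and
#' total UMI; a minimum number of cells per retained gene; cluster-level
#' flags; and animal-level exclusion rules.
#'
#' @param min_pct_mito,max_pct_mito Per-cell percent-mitochondrial bounds
#'   (default 0 and 5).
#' @param min_nFeature,max_nFeature Per-cell detected-gene bounds (250, 6000).
#' @param min_nCount,max_nCount Per-cell UMI bounds (200, 30000).
#' @param min_cells Minimum cells in which a gene must be detected (5).
#' @param cluster_max_mean_pct_mito Flag clusters whose mean percent-mito
#'   exceeds this (8).
#' @param cluster_min_nCount,cluster_min_nFeature Flag clusters whose summary
#'   nCount / nFeature fall below these (1000, 500).
#' @param cluster_stat Summary statistic for the cluster nCount/nFeature
#'   flags: "median" (default, robust to outlier cells) or "mean".
#' @param animal_min_avg_genes Exclude animals whose average number of
#'   detected genes (over cells with > 0 genes) is below this (700).
#' @param animal_max_pct_mito Exclude animals whose mean percent-mito exceeds
#'   this (1.5).
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_pct_mito = 0, max_pct_mito = 5,
                          min_nFeature = 250, max_nFeature = 6000,
                          min_nCount = 200, max_nCount = 30000,
                          min_cells = 5,
                          cluster_max_mean_pct_mito = 8,
                          cluster_min_nCount = 1000,
                          cluster_min_nFeature = 500,
                          cluster_stat = c("median", "mean"),
                          animal_min_avg_genes = 700,
                          animal_max_pct_mito = 1.5) {
  cluster_stat <- match.arg(cluster_stat)
  th <- structure(as.list(environment()), class = "qc_thresholds")
  for (pair in list(c("min_pct_mito", "max_pct_mito"),
                    c("min_nFeature", "max_nFeature"),
                    c("min_nCount", "max_nCount"))) {
    if (th[[pair[1]]] > th[[pair[2]]]) {
      stop(pair[1], " exceeds ", pair[2], call. = FALSE)
    }
  }
  num <- vapply(th[setdiff(names(th), "cluster_stat")], identity, numeric(1))
  if (any(num < 0)) stop("thresholds must be nonnegative", call. = FALSE)
  th
}

#' Cell- and gene-level QC filtering
#'
#' Retains cells whose stored QC covariates satisfy all per-cell bounds, then
#' retains genes detected (count >= 1) in at least `min_cells` of the
#' retained cells. The stored nCount/nFeature/percent-mito covariates are
#' taken as fixed cell annotations (computed when the cohort was assembled),
#' so the filter is idempotent.
#'
#' @param cohort A `cell_cohort` whose metadata contains `nCount`, `nFeature`
#'   and `percent_mito`.
#' @param thresholds A [qc_thresholds()].
#' @return Filtered `cell_cohort` with a `qc_report` attribute listing cells
#'   and genes removed.
#' @export
filter_cells <- function(cohort, thresholds = qc_thresholds()) {
  m <- cohort$meta
  need <- c("nCount", "nFeature", "percent_mito")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metadata lacks QC column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  th <- thresholds
  keep <- m$percent_mito >= th$min_pct_mito & m$percent_mito <= th$max_pct_mito &
    m$nFeature >= th$min_nFeature & m$nFeature <= th$max_nFeature &
    m$nCount >= th$min_nCount & m$nCount <= th$max_nCount
  if (!any(keep)) stop("all cells filtered out", call. = FALSE)
  out <- subset_cohort(cohort, cells = keep)
  gene_keep <- Matrix::rowSums(out$counts > 0) >= th$min_cells
  out <- subset_cohort(out, genes = gene_keep)
  attr(out, "qc_report") <- list(
    cells_in = nrow(m), cells_removed = sum(!keep),
    genes_in = length(gene_keep), genes_removed = sum(!gene_keep)
  )
  out
}

.cluster_stat_fun <- function(stat) if (stat == "median") stats::median else mean

#' Flag low-quality clusters
#'
#' A cluster is flagged when its mean percent-mitochondrial exceeds the
#' threshold (default 8%), or its summary nCount falls below 1,000, or its
#' summary nFeature falls below 500 (summary = median by default).
#'
#' @param cohort A `cell_cohort`.
#' @param cluster_labels Character/factor vector, one label per cell.
#' @param thresholds A [qc_thresholds()].
#' @return data.frame with one row per cluster: summary statistics, `flagged`
#'   and a semicolon-joined `reason`.
#' @export
flag_low_quality_clusters <- function(cohort, cluster_labels,
                                      thresholds = qc_thresholds()) {
  if (length(cluster_labels) != nrow(cohort$meta)) {
    stop("cluster_labels must have one entry per cell", call. = FALSE)
  }
  if (anyNA(cluster_labels)) stop("unknown (NA) cluster labels", call. = FALSE)
  th <- thresholds
  f <- .cluster_stat_fun(th$cluster_stat)
  cl <- as.character(cluster_labels)
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    i <- cl == k
    mp <- mean(cohort$meta$percent_mito[i])
    nc <- f(cohort$meta$nCount[i])
    nf <- f(cohort$meta$nFeature[i])
    reasons <- c(
      if (mp > th$cluster_max_mean_pct_mito) "high_pct_mito",
      if (nc < th$cluster_min_nCount) "low_nCount",
      if (nf < th$cluster_min_nFeature) "low_nFeature"
    )
    data.frame(cluster = k, n_cells = sum(i), mean_pct_mito = mp,
               stat_nCount = nc, stat_nFeature = nf,
               flagged = length(reasons) > 0,
               reason = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Animal-level exclusion
#'
#' Excludes an animal when its average number of detected genes (over cells
#' with at least one detected gene) is below the threshold (default 700),
#' its mean percent-mitochondrial exceeds the threshold (default 1.5), or it
#' contributes zero cells to at least one cluster.
#'
#' @param cohort A `cell_cohort`.
#' @param thresholds A [qc_thresholds()].
#' @param cluster_labels Optional per-cell cluster labels; when supplied the
#'   every-cluster contribution rule is applied.
#' @return data.frame of per-animal summaries with `excluded` and `reason`.
#' @export
exclude_animals <- function(cohort, thresholds = qc_thresholds(),
                            cluster_labels = NULL) {
  th <- thresholds
  m <- cohort$meta
  animals <- unique(m$animal_id)
  clusters <- if (!is.null(cluster_labels)) unique(as.character(cluster_labels))
  out <- do.call(rbind, lapply(animals, function(an) {
    i <- m$animal_id == an
    nf <- m$nFeature[i]
    avg_genes <- mean(nf[nf > 0])
    mp <- mean(m$percent_mito[i])
    missing_cluster <- if (!is.null(clusters)) {
      length(setdiff(clusters, cluster_labels[i])) > 0
    } else FALSE
    reasons <- c(
      if (is.nan(avg_genes) || avg_genes < th$animal_min_avg_genes) "low_avg_genes",
      if (mp > th$animal_max_pct_mito) "high_pct_mito",
      if (missing_cluster) "missing_cluster"
    )
    data.frame(animal_id = an, animal_type = m$animal_type[i][1],
               n_cells = sum(i), avg_genes = avg_genes, mean_pct_mito = mp,
               excluded = length(reasons) > 0,
               reason = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-cell-type ANOVA on per-animal cell counts
#'
#' For each cell type and each requested pair of animal types, performs a
#' one-way ANOVA (two groups) on the per-animal cell counts, with no
#' multiple-comparison correction. Animals of the compared types that
#' contribute zero cells of a cell type enter with count 0.
#'
#' @param cohort A `cell_cohort`.
#' @param type_pairs List of length-2 character vectors of animal types;
#'   default all 15 pairs present in the cohort.
#' @return data.frame with cell_type, pair, group sizes, F and p (NA when a
#'   group has fewer than 2 animals).
#' @export
cell_count_comparison <- function(cohort, type_pairs = NULL) {
  m <- cohort$meta
  roster <- unique(m[, c("animal_id", "animal_type")])
  types <- intersect(animal_types(), unique(roster$animal_type))
  if (is.null(type_pairs)) {
    type_pairs <- utils::combn(types, 2, simplify = FALSE)
  }
  cts <- sort(unique(m$cell_type))
  rows <- list()
  for (ct in cts) {
    counts <- table(factor(m$animal_id[m$cell_type == ct],
                           levels = roster$animal_id))
    for (pr in type_pairs) {
      .check_animal_type(pr)
      ids1 <- roster$animal_id[roster$animal_type == pr[1]]
      ids2 <- roster$animal_id[roster$animal_type == pr[2]]
      n1 <- length(ids1); n2 <- length(ids2)
      if (n1 < 2 || n2 < 2) {
        Fv <- NA_real_; pv <- NA_real_
      } else {
        y <- c(as.numeric(counts[ids1]), as.numeric(counts[ids2]))
        g <- factor(rep(c(pr[1], pr[2]), c(n1, n2)))
        ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
        if (ss_between == 0) {
          Fv <- 0; pv <- 1  # identical group means (incl. all-equal data)
        } else {
          av <- stats::anova(stats::lm(y ~ g))
          Fv <- av[["F value"]][1]; pv <- av[["Pr(>F)"]][1]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, pair = paste(pr, collapse = "v"),
        n1 = n1, n2 = n2, F = Fv, p = pv, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
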