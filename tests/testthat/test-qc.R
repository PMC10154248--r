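test_that("cell filtering applies the documented per-cell predicates", {
  coh <- toy_cohort(n_cells = 10)
  th <- qc_thresholds(min_nFeature = 0, min_nCount = 0, min_cells = 0)
  # in-bounds cohort passes unchanged
  expect_equal(ncol(filter_cells(coh, th)$counts), 10)
  # three cells pushed over the mito bound are removed
  coh$meta$percent_mito[1:3] <- 6
  expect_equal(ncol(filter_cells(coh, th)$counts), 7)
  expect_equal(attr(filter_cells(coh, th), "qc_report")$cells_removed, 3)
  coh$meta$percent_mito <- rep(99, 10)
  expect_error(filter_cells(coh, th), "all cells filtered")
})

test_that("filtering equals a brute-force predicate oracle and is idempotent", {
  cfg <- small_config(n_genes = 120, seed = 8)
  coh <- simulate_cohort(cfg)
  # spread covariates so every bound is exercised
  set.seed(1)
  coh$meta$percent_mito <- runif(ncol(coh$counts), 0, 8)
  coh$meta$nFeature <- sample(100:7000, ncol(coh$counts), replace = TRUE)
  coh$meta$nCount <- sample(50:40000, ncol(coh$counts), replace = TRUE)
  th <- qc_thresholds()
  f1 <- filter_cells(coh, th)
  keep_oracle <- vapply(seq_len(ncol(coh$counts)), function(i) {
    m <- coh$meta[i, ]
    m$percent_mito >= 0 && m$percent_mito <= 5 &&
      m$nFeature >= 250 && m$nFeature <= 6000 &&
      m$nCount >= 200 && m$nCount <= 30000
  }, logical(1))
  expect_equal(f1$meta$barcode, coh$meta$barcode[keep_oracle])
  genes_oracle <- rownames(coh$counts)[
    Matrix::rowSums(coh$counts[, keep_oracle, drop = FALSE] > 0) >= 5]
  expect_equal(rownames(f1$counts), genes_oracle)
  f2 <- filter_cells(f1, th)
  expect_identical(as.matrix(f2$counts), as.matrix(f1$counts))
  expect_identical(f2$meta, f1$meta)
})

test_that("cluster flagging matches the stated summary rules", {
  cfg <- small_config(n_genes = 60, seed = 2)
  coh <- simulate_cohort(cfg)
  n <- ncol(coh$counts)
  cl <- rep(c("A", "B", "C"), length.out = n)
  coh$meta$percent_mito <- rep(1, n)
  coh$meta$nCount <- rep(5000, n)
  coh$meta$nFeature <- rep(2000, n)
  fl <- flag_low_quality_clusters(coh, cl)
  expect_false(any(fl$flagged))
  # one cluster driven over the mito bound
  coh$meta$percent_mito[cl == "B"] <- 10
  fl2 <- flag_low_quality_clusters(coh, cl)
  expect_equal(fl2$cluster[fl2$flagged], "B")
  expect_match(fl2$reason[fl2$cluster == "B"], "high_pct_mito")
  # random covariates vs a brute-force re-evaluation of the median rule
  set.seed(5)
  coh$meta$percent_mito <- runif(n, 0, 12)
  coh$meta$nCount <- sample(200:3000, n, TRUE)
  coh$meta$nFeature <- sample(100:1200, n, TRUE)
  fl3 <- flag_low_quality_clusters(coh, cl)
  for (k in c("A", "B", "C")) {
    i <- cl == k
    expect_equal(fl3$flagged[fl3$cluster == k],
                 mean(coh$meta$percent_mito[i]) > 8 ||
                   median(coh$meta$nCount[i]) < 1000 ||
                   median(coh$meta$nFeature[i]) < 500)
  }
  expect_error(flag_low_quality_clusters(coh, cl[-1]), "one entry per cell")
})

test_that("animal exclusion fires on low genes, high mito and missing clusters", {
  cfg <- small_config(n_genes = 80, seed = 3)
  coh <- simulate_cohort(cfg)
  coh$meta$nFeature <- rep(900, ncol(coh$counts))
  coh$meta$percent_mito <- rep(1, ncol(coh$counts))
  ex0 <- exclude_animals(coh)
  expect_false(any(ex0$excluded))
  coh$meta$percent_mito[coh$meta$animal_id == "OO_01"] <- 2
  coh$meta$nFeature[coh$meta$animal_id == "YY_02"] <- 300
  ex1 <- exclude_animals(coh)
  expect_setequal(ex1$animal_id[ex1$excluded], c("OO_01", "YY_02"))
  expect_match(ex1$reason[ex1$animal_id == "OO_01"], "high_pct_mito")
  expect_match(ex1$reason[ex1$animal_id == "YY_02"], "low_avg_genes")
  # an animal absent from one cluster is excluded under the contribution rule
  cl <- rep("c1", ncol(coh$counts))
  cl[coh$meta$animal_id != "YX_01"] <- sample(c("c1", "c2"),
                                              sum(coh$meta$animal_id != "YX_01"),
                                              replace = TRUE)
  cl[coh$meta$animal_id == "YX_01"] <- "c1"
  ex2 <- exclude_animals(coh, cluster_labels = cl)
  expect_true(ex2$excluded[ex2$animal_id == "YX_01"])
  expect_match(ex2$reason[ex2$animal_id == "YX_01"], "missing_cluster")
})

test_that("cell-count ANOVA reduces to the pooled-t identity and handles ties", {
  # identical per-animal counts in both groups
  meta <- data.frame(
    barcode = sprintf("c%d", 1:40),
    animal_id = rep(sprintf("%s_%02d", rep(c("YX", "OX"), each = 4), 1:4), 5),
    animal_type = rep(rep(c("YX", "OX"), each = 4), 5),
    cell_type = "CT1", batch = "b1", stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(0, 1, 40, sparse = TRUE,
                           dimnames = list("g1", meta$barcode))
  coh <- new_cell_cohort(counts, meta)
  res <- cell_count_comparison(coh, list(c("YX", "OX")))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # unbalanced counts: F equals the square of the pooled-variance t statistic
  set.seed(7)
  n_per <- c(YX_01 = 9, YX_02 = 4, YX_03 = 7, YX_04 = 11,
             OX_01 = 2, OX_02 = 8, OX_03 = 5, OX_04 = 3)
  meta2 <- data.frame(
    barcode = sprintf("c%d", 1:sum(n_per)),
    animal_id = rep(names(n_per), n_per),
    animal_type = substr(rep(names(n_per), n_per), 1, 2),
    cell_type = "CT1", batch = "b1", stringsAsFactors = FALSE)
  counts2 <- Matrix::Matrix(0, 1, nrow(meta2), sparse = TRUE,
                            dimnames = list("g1", meta2$barcode))
  coh2 <- new_cell_cohort(counts2, meta2)
  res2 <- cell_count_comparison(coh2, list(c("YX", "OX")))
  tt <- t.test(n_per[1:4], n_per[5:8], var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic^2))
  expect_equal(res2$p, tt$p.value)

  # a group with fewer than 2 animals is reported as missing
  keep <- meta2$animal_id %in% c("YX_01", "YX_02", "OX_01")
  res3 <- cell_count_comparison(
    new_cell_cohort(counts2[, keep, drop = FALSE], meta2[keep, ]),
    list(c("YX", "OX")))
  expect_true(is.na(res3$F))
})

test_that("a planted cell-abundance shift is detected with high power", {
  # 2x more cells of one type in OY than OX; 50 seeded replicates
  hits <- 0L
  for (rep_i in 1:50) {
    set.seed(100 + rep_i)
    n_oy <- rnbinom(8, mu = 80, size = 20)
    n_ox <- rnbinom(8, mu = 40, size = 20)
    ids <- c(sprintf("OY_%02d", 1:8), sprintf("OX_%02d", 1:8))
    n <- c(n_oy, n_ox)
    meta <- data.frame(
      barcode = sprintf("c%d", seq_len(sum(n))),
      animal_id = rep(ids, n),
      animal_type = rep(c("OY", "OX"), c(sum(n_oy), sum(n_ox))),
      cell_type = "CT1", batch = "b1", stringsAsFactors = FALSE)
    counts <- Matrix::Matrix(0, 1, nrow(meta), sparse = TRUE,
                             dimnames = list("g1", meta$barcode))
    res <- cell_count_comparison(new_cell_cohort(counts, meta),
                                 list(c("OY", "OX")))
    if (res$p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 45)  # >= 90% power
})
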