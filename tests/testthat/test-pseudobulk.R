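test_that("pseudobulk aggregation equals a group-by-sum oracle", {
  # hand case: one animal, two cells
  counts <- Matrix::Matrix(matrix(c(1, 2, 0, 3), 2, 2,
                                  dimnames = list(c("g1", "g2"), c("c1", "c2"))),
                           sparse = TRUE)
  meta <- data.frame(barcode = c("c1", "c2"), animal_id = "YX_01",
                     animal_type = "YX", cell_type = "CT1", batch = "b1",
                     stringsAsFactors = FALSE)
  pb <- aggregate_pseudobulk(new_cell_cohort(counts, meta))$CT1
  expect_equal(unname(pb$counts[, 1]), c(1, 5))

  cfg <- small_config(n_genes = 80, seed = 4, cell_types = c(X = 0.5, Y = 0.5))
  coh <- simulate_cohort(cfg)
  pbs <- aggregate_pseudobulk(coh)
  for (ct in names(pbs)) {
    for (an in colnames(pbs[[ct]]$counts)) {
      i <- coh$meta$cell_type == ct & coh$meta$animal_id == an
      expect_equal(unname(pbs[[ct]]$counts[, an]),
                   unname(Matrix::rowSums(coh$counts[, i, drop = FALSE])))
    }
  }
  # permuting cell order leaves the assay unchanged
  perm <- sample(ncol(coh$counts))
  coh_p <- subset_cohort(coh, cells = perm)
  pbs_p <- aggregate_pseudobulk(coh_p)
  expect_equal(pbs_p$X$counts, pbs$X$counts)
})

test_that("TMM factors honor scaling invariances and the documented trim rule", {
  m <- matrix(rpois(400, 50) + 1, 100, 4)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(tmm_factors(same), rep(1, 3))
  # doubling a sample changes no factor (composition unchanged)
  sc <- cbind(m[, 1], 2 * m[, 1])
  expect_equal(tmm_factors(sc), c(1, 1))
  expect_error(tmm_factors(cbind(m[, 1], 0 * m[, 1])), "all-zero")

  # toy with one inflated gene vs the hand-computed trimmed weighted mean
  y1 <- c(10, 20, 30, 40, 50, 60, 70, 80)
  y2 <- c(10, 20, 30, 40, 50, 60, 70, 800)
  f <- tmm_factors(cbind(a = y1, b = y2), reference = "a")
  n1 <- sum(y1); n2 <- sum(y2)
  M <- log2((y2 / n2) / (y1 / n1))
  A <- 0.5 * log2((y2 / n2) * (y1 / n1))
  w <- (n2 - y2) / (n2 * y2) + (n1 - y1) / (n1 * y1)
  keep <- rank(M) >= 3 & rank(M) <= 6 & rank(A) >= 1 & rank(A) <= 8
  f2_hand <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  hand <- c(1, f2_hand) / exp(mean(log(c(1, f2_hand))))
  expect_equal(unname(f), hand)
})

test_that("TMM factors agree with the reference implementation", {
  set.seed(19)
  m <- matrix(rnbinom(200 * 6, mu = 100, size = 2), 200, 6)
  colnames(m) <- paste0("s", 1:6)
  f_pkg <- tmm_factors(m)
  f_ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f_pkg), unname(f_ref), tolerance = 1e-6)
})

test_that("test-unit filtering drops weak genes and skips thin cell types", {
  cfg <- small_config(n_genes = 100, seed = 6)
  coh <- simulate_cohort(cfg)
  pbs <- aggregate_pseudobulk(coh)
  fl <- filter_test_units(pbs, rjv_contrast(), min_cells = 5)
  as_ <- pbs$CT1
  keep_oracle <- rowSums(as_$counts) >= 10 & rowSums(as_$counts > 0) >= 2
  expect_equal(rownames(fl$assays$CT1$counts),
               rownames(as_$counts)[keep_oracle])
  # a cell type with a single OY animal is untestable for the RJV contrast
  oy <- which(as_$animal_type == "OY")
  keep_an <- setdiff(seq_along(as_$animal_type), oy[-1])
  thin <- new_pseudobulk(as_$counts[, keep_an, drop = FALSE],
                         as_$animal_type[keep_an],
                         n_cells = as_$n_cells[keep_an], cell_type = "CT1")
  fl2 <- filter_test_units(list(CT1 = thin), rjv_contrast(), min_cells = 1)
  expect_equal(length(fl2$assays), 0)
  expect_match(fl2$skipped$reason, "OY")
  # an all-zero gene is always dropped
  zero_gene <- rownames(as_$counts)[rowSums(as_$counts) == 0]
  expect_false(any(zero_gene %in% rownames(fl$assays$CT1$counts)))
})

test_that("BH adjustment equals the textbook step-up oracle", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (n in c(10, 100, 5000)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # grouped adjustment is per-group; NA propagates
  p <- c(0.01, NA, 0.2, 0.03, 0.5, NA)
  g <- c(1, 1, 1, 2, 2, 2)
  q <- bh_adjust(p, g)
  expect_true(is.na(q[2]) && is.na(q[6]))
  expect_equal(q[c(1, 3)], stats::p.adjust(p[c(1, 2, 3)], "BH")[c(1, 3)])
  expect_equal(q[4:5], stats::p.adjust(p[4:6], "BH")[1:2])
})

test_that("TPM and percent-expressing summaries match hand computation", {
  counts <- Matrix::Matrix(
    matrix(c(5, 0, 5, 2, 3, 5, 0, 0, 10, 1, 4, 5), 3, 4,
           dimnames = list(c("g1", "g2", "g3"), sprintf("c%d", 1:4))),
    sparse = TRUE)
  meta <- data.frame(barcode = sprintf("c%d", 1:4),
                     animal_id = c("YX_01", "YX_01", "OX_01", "OX_01"),
                     animal_type = c("YX", "YX", "OX", "OX"),
                     cell_type = "CT1", batch = "b1", stringsAsFactors = FALSE)
  coh <- new_cell_cohort(counts, meta)
  pb <- aggregate_pseudobulk(coh)$CT1
  s <- summarize_tpm_pct(coh, pb)
  # per-animal TPM sums to 1e6
  expect_equal(unname(colSums(s$tpm_animal)), rep(1e6, 2))
  # hand: YX animal sums g=(7,3,10), lib 20 -> TPM (350000,150000,500000)
  expect_equal(unname(s$tpm[, "YX"]), c(350000, 150000, 500000))
  expect_equal(unname(s$pct[, "YX"]), c(1, 0.5, 1))
  # gene absent in all OX cells
  counts2 <- counts; counts2["g2", 3:4] <- 0
  coh2 <- new_cell_cohort(counts2, meta)
  pb2 <- aggregate_pseudobulk(coh2)$CT1
  s2 <- summarize_tpm_pct(coh2, pb2)
  expect_equal(unname(s2$pct["g2", "OX"]), 0)
  # single-gene assay: TPM is 1e6 by construction
  one <- new_pseudobulk(matrix(c(4L, 9L), 1, 2,
                               dimnames = list("g1", c("YX_01", "OX_01"))),
                        c("YX", "OX"))
  expect_true(all(summarize_tpm_pct(coh, one)$tpm_animal == 1e6))
})

test_that("row z-scoring of log2 TPM has the stated normalization properties", {
  m <- rbind(c(1, 3, 9), c(4, 4, 4), c(0, 10, 100))
  z <- row_zscore_log2(m, pseudocount = 1)
  expect_equal(unname(z[2, ]), c(0, 0, 0))           # constant row -> zeros
  expect_equal(unname(rowMeans(z)), c(0, 0, 0))
  expect_equal(apply(z[-2, ], 1, sd), c(1, 1))       # sample-SD convention
  hand <- log2(c(1, 3, 9) + 1)
  expect_equal(unname(z[1, ]), unname((hand - mean(hand)) / sd(hand)))
  expect_error(row_zscore_log2(m[, 1, drop = FALSE]), "at least 2")
})
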