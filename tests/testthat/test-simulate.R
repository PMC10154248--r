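test_that("effect planting follows the seeded-shuffle selection rule", {
  cfg <- small_config()
  truth <- plant_effects(cfg)
  for (eff in c("a", "sY", "sO", "r", "q")) {
    expect_true(all(truth[[eff]] == 0))
  }

  cfg2 <- sim_config(n_genes = 2000,
                     effects = list(a = list(frac = 0.1, mean = 0, sd = 1),
                                    sY = list(frac = 0, mean = 0, sd = 0),
                                    sO = list(frac = 0, mean = 0, sd = 0),
                                    r = list(frac = 0, mean = 0, sd = 0),
                                    q = list(frac = 0, mean = 0, sd = 0)),
                     seed = 9)
  truth2 <- plant_effects(cfg2)
  # independent re-derivation of the documented rule: first floor(frac*G)
  # genes of a seeded shuffle
  expect_equal(sum(truth2$a[, 1] != 0), floor(0.1 * 2000))
  set.seed(parabulk:::derive_seed(9, "effects a CT1"))
  idx <- sample.int(2000)[seq_len(200)]
  expect_equal(unname(which(truth2$a[, 1] != 0)), sort(idx))
  expect_identical(truth2$a, plant_effects(cfg2)$a)

  cfg3 <- small_config()
  cfg3$effects$a <- list(frac = 1, mean = 1, sd = 0)
  expect_true(all(plant_effects(cfg3)$a == 1))
  cfg4 <- small_config()
  cfg4$effects$a$frac <- 1.5
  expect_error(validate_sim_config(cfg4), "frac")
})

test_that("expected offsets follow the generative double-difference algebra", {
  cfg <- small_config(n_genes = 10)
  truth <- make_truth(cfg, a_idx = 1, a = 1, sO = 0.5)
  truth$r[1, 1] <- -1
  g <- truth$genes[1]
  expect_equal(expected_log2_offset(truth, "OY", g, "CT1"), 0.5)
  expect_equal(expected_log2_offset(truth, "OO", g, "CT1"), 1.5)
  expect_equal(expected_log2_offset(truth, "OX", g, "CT1"), 1)
  expect_equal(expected_log2_offset(truth, "YX", g, "CT1"), 0)
  om <- offset_matrix(truth, "CT1")[g, ]
  rjv <- rjv_contrast()
  expect_equal(sum(om * rjv[names(om)]), -2)  # r - a

  truth2 <- make_truth(cfg, sY = 0.3, q_val = 0.7)
  om2 <- offset_matrix(truth2, "CT1")[1, ]
  aga <- aga_contrast()
  expect_equal(sum(om2 * aga[names(om2)]), 0.7)  # q + a with a = 0
  expect_equal(unname(om2["YO"]), 1.0)           # sY + q
  expect_error(expected_log2_offset(truth, "XX", g, "CT1"), "unknown")
  zero <- make_truth(cfg)
  expect_true(all(offset_matrix(zero, "CT1") == 0))
})

test_that("simulated cohorts are seed-deterministic with consistent metadata", {
  cfg <- small_config()
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$meta, c2$meta)
  expect_equal(unname(c1$meta$nCount), unname(Matrix::colSums(c1$counts)))
  expect_equal(unname(c1$meta$nFeature), unname(Matrix::colSums(c1$counts > 0)))
  mito <- startsWith(rownames(c1$counts), "mt-")
  expect_equal(sum(mito), cfg$n_mito_genes)
  expect_equal(unname(c1$meta$percent_mito),
               unname(100 * Matrix::colSums(c1$counts[mito, ]) / c1$meta$nCount))
  roster <- unique(c1$meta[, c("animal_id", "animal_type")])
  expect_equal(as.integer(table(roster$animal_type)[names(cfg$n_animals)]),
               as.integer(cfg$n_animals))
})

test_that("zero baseline abundance yields all-zero gene columns", {
  cfg <- small_config(mito_expr_frac = 0)  # mito genes get baseline 0
  coh <- simulate_cohort(cfg)
  mito <- startsWith(rownames(coh$counts), "mt-")
  expect_true(all(coh$counts[mito, ] == 0))
  expect_true(any(coh$counts[!mito, ] > 0))
})

test_that("zero dispersion gives Poisson-like variance-to-mean ratios", {
  cfg <- small_config(n_genes = 100, dispersion = 0, animal_sd_log2 = 0,
                      libsize_sdlog = 1e-8)
  cfg$n_animals <- c(YX = 6, YY = 0, YO = 0, OX = 0, OO = 0, OY = 0)
  cfg$cells_per_animal <- 200
  coh <- simulate_cohort(cfg)
  m <- as.matrix(coh$counts)
  mu <- rowMeans(m)
  vr <- apply(m, 1, var)
  keep <- mu > 0.5
  ratio <- vr[keep] / mu[keep]
  expect_gt(sum(keep), 30)
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("planted aging effects are recovered in raw pseudobulk ratios", {
  cfg <- sim_config(seed = 3, effects = default_effects(frac = 0))
  truth <- make_truth(cfg, a_idx = 1:200, a = 1)
  coh <- simulate_cohort(cfg, truth)
  # TMM-corrected libraries: planting 10% of genes up inflates raw library
  # sizes of the affected arms (compositional bias), which TMM removes
  pb <- tmm_factors(aggregate_pseudobulk(coh)$CT1)
  cpm <- sweep(pb$counts, 2, pb$eff_lib, "/") * 1e6
  ox <- rowMeans(cpm[, pb$animal_type == "OX"])
  yx <- rowMeans(cpm[, pb$animal_type == "YX"])
  lr <- log2(ox[1:200] / yx[1:200])
  expect_lt(abs(mean(lr[is.finite(lr)]) - 1), 0.1)
  # null genes carry at most the residual compositional shift TMM leaves
  null_lr <- log2(ox[201:2000] / yx[201:2000])
  expect_lt(abs(mean(null_lr[is.finite(null_lr)])), 0.1)
})

test_that("cohorts round-trip through the MTX interchange format", {
  cfg <- small_config(n_genes = 50)
  coh <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_true(all(file.exists(file.path(d, c("matrix.mtx", "genes.tsv",
                                             "barcodes.tsv", "metadata.tsv",
                                             "manifest.json")))))
  back <- read_cohort(d)
  expect_equal(as.matrix(back$counts), as.matrix(coh$counts))
  expect_equal(back$meta$animal_id, coh$meta$animal_id)
  expect_equal(back$meta$nCount, coh$meta$nCount)
  expect_error(read_cohort(file.path(d, "nope")), "missing cohort file")
})
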