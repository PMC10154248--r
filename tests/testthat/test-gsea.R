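test_that("the rank metric is signed -log10(p)", {
  expect_equal(rank_metric(0.01, -2), -2)
  expect_equal(rank_metric(1, 5), 0)
  expect_equal(rank_metric(0.001, 0.5), 3)
  expect_equal(rank_metric(0.05, 0), 0)
  expect_true(is.finite(rank_metric(0, 1)))  # p = 0 capped
})

mk_ranked <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  out <- data.frame(gene = genes[order(-scores)], score = sort(scores, decreasing = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

test_that("enrichment scores hit the boundary cases and a brute-force oracle", {
  rk <- mk_ranked(seq(10, 1))
  expect_equal(enrichment_score(rk, rk$gene[1])$es, 1)
  expect_equal(enrichment_score(rk, rk$gene[10])$es, -1)
  expect_true(is.na(enrichment_score(rk, "absent")$es))

  # independent running-sum oracle on random 20-gene lists with 4-gene sets
  set.seed(61)
  for (rep_i in 1:5) {
    scores <- round(rnorm(20), 2)
    rk2 <- mk_ranked(scores)
    set_ <- sample(rk2$gene, 4)
    got <- enrichment_score(rk2, set_)
    hit <- rk2$gene %in% set_
    w <- abs(rk2$score)
    run <- 0; best <- 0; best_pos <- NA
    for (i in 1:20) {
      run <- run + if (hit[i]) w[i] / sum(w[hit]) else -1 / 16
      if (abs(run) > abs(best)) { best <- run; best_pos <- i }
    }
    expect_equal(got$es, best)
    expect_equal(got$position, best_pos)
    le <- if (best >= 0) rk2$gene[1:best_pos][hit[1:best_pos]] else
      rk2$gene[best_pos:20][hit[best_pos:20]]
    expect_equal(got$leading_edge, le)
  }
})

test_that("ES obeys scale invariance and antisymmetry", {
  set.seed(62)
  scores <- rnorm(30)
  rk <- mk_ranked(scores)
  set_ <- sample(rk$gene, 6)
  es1 <- enrichment_score(rk, set_)$es
  rk_scaled <- rk; rk_scaled$score <- rk$score * 7.3
  expect_equal(enrichment_score(rk_scaled, set_)$es, es1)
  # reverse the list and negate scores
  rk_rev <- rk[rev(seq_len(nrow(rk))), ]
  rk_rev$score <- -rk_rev$score
  expect_equal(enrichment_score(rk_rev, set_)$es, -es1)
})

test_that("sampled permutation p approximates exhaustive enumeration", {
  set.seed(63)
  scores <- rnorm(10)
  rk <- mk_ranked(scores)
  set_ <- rk$gene[c(2, 5)]
  coll <- gene_set_collection(list(S = set_))
  res <- permutation_enrichment(rk, coll, n_perm = 1000, min_size = 1,
                                max_size = Inf, seed = 64)
  es_obs <- res$es
  # exact null: all C(10,2) = 45 same-size sets
  pairs <- combn(10, 2)
  null_es <- apply(pairs, 2, function(ij) enrichment_score(rk, rk$gene[ij])$es)
  same <- if (es_obs >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p_exact <- sum(abs(same) >= abs(es_obs)) / length(same)
  expect_lt(abs(res$p_val - p_exact), 0.05)
  expect_equal(sign(res$nes), sign(res$es))
})

test_that("permutation p is uniform under a random set and ranking", {
  set.seed(65)
  ps <- vapply(1:200, function(i) {
    rk <- mk_ranked(rnorm(40), genes = sprintf("r%02d", 1:40))
    coll <- gene_set_collection(list(S = sample(rk$gene, 8)))
    permutation_enrichment(rk, coll, n_perm = 250, min_size = 1,
                           max_size = Inf, seed = i)$p_val
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation results are seed-reproducible and size-filtered", {
  set.seed(66)
  rk <- mk_ranked(rnorm(100))
  coll <- gene_set_collection(list(big = rk$gene[1:30], small = rk$gene[1:5]))
  r1 <- permutation_enrichment(rk, coll, n_perm = 200, min_size = 15,
                               max_size = 500, seed = 3)
  r2 <- permutation_enrichment(rk, coll, n_perm = 200, min_size = 15,
                               max_size = 500, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$set, "big")  # 5-gene set filtered out
  expect_warning(
    permutation_enrichment(rk, gene_set_collection(list(s = rk$gene[1:3])),
                           n_perm = 50, seed = 1),
    "no gene set survives")
})

test_that("GMT files round-trip and malformed lines are rejected", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tG1\tG2", "S2\tother\tG3\tG4\tG5"), f)
  coll <- read_gmt(f)
  expect_equal(coll$S1, c("G1", "G2"))
  expect_equal(coll$S2, c("G3", "G4", "G5"))
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, f2)
  expect_equal(read_gmt(f2)$S2, coll$S2)
  writeLines(c("S1\tdesc\tG1", "badline\tonly2fields"), f)
  expect_error(read_gmt(f), "line 2")
})

test_that("ortholog mapping keeps all targets and drops unmapped genes", {
  coll <- gene_set_collection(list(S = c("m1", "m2", "m3")))
  ident <- data.frame(source = c("m1", "m2", "m3"),
                      target = c("m1", "m2", "m3"), stringsAsFactors = FALSE)
  expect_equal(map_orthologs(coll, ident)$S, c("m1", "m2", "m3"))
  # one-to-many keeps all targets; unmapped m3 dropped with a message
  mp <- data.frame(source = c("m1", "m1", "m2"),
                   target = c("H1A", "H1B", "H2"), stringsAsFactors = FALSE)
  expect_message(out <- map_orthologs(coll, mp), "dropped 1")
  expect_setequal(out$S, c("H1A", "H1B", "H2"))
  # ranked list: renamed, duplicates resolved to first occurrence
  rk <- mk_ranked(c(3, 2, 1), genes = c("m1", "m2", "m3"))
  mp2 <- data.frame(source = c("m1", "m2"), target = c("H", "H"),
                    stringsAsFactors = FALSE)
  out2 <- suppressMessages(map_orthologs(rk, mp2))
  expect_equal(out2$gene, "H")
  expect_equal(out2$score, 3)
})

test_that("the senescence scan rejects an empty set", {
  expect_error(senescence_scan(list(), character(0)), "empty")
})
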