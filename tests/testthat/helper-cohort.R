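# Shared fixture builders. Everything is generated in code; nothing on disk.

# A small but complete six-arm cohort for fast module tests.
small_config <- function(n_genes = 200, seed = 42, ...) {
  sim_config(
    n_animals = c(YX = 3, YY = 3, YO = 3, OX = 3, OO = 3, OY = 3),
    n_genes = n_genes, cells_per_animal = 20, n_mito_genes = 3,
    effects = default_effects(frac = 0), seed = seed, ...
  )
}

# Hand-built cohort with explicit QC covariates; counts are a dense toy
# matrix so predicates can be recomputed trivially.
toy_cohort <- function(n_cells = 10, n_genes = 6, seed = 1) {
  set.seed(seed)
  counts <- Matrix::Matrix(
    matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
           dimnames = list(sprintf("g%d", 1:n_genes), sprintf("c%d", 1:n_cells))),
    sparse = TRUE)
  meta <- data.frame(
    barcode = colnames(counts),
    animal_id = rep(c("YX_01", "OX_01"), length.out = n_cells),
    animal_type = rep(c("YX", "OX"), length.out = n_cells),
    cell_type = "CT1", batch = "b1",
    nCount = Matrix::colSums(counts),
    nFeature = Matrix::colSums(counts > 0),
    percent_mito = rep(1, n_cells),
    stringsAsFactors = FALSE)
  rownames(meta) <- meta$barcode
  new_cell_cohort(counts, meta)
}

# Truth object with chosen genes carrying exact effect values; starts from an
# all-zero truth so scenarios are fully controlled.
make_truth <- function(config, a_idx = integer(0), a = 1,
                       r_mult = 0, q_val = 0, sY = 0, sO = 0) {
  truth <- plant_effects(config)  # frac 0 expected -> all-zero matrices
  ct <- names(config$cell_types)[1]
  if (length(a_idx)) {
    truth$a[a_idx, ct] <- a
    truth$r[a_idx, ct] <- r_mult * truth$a[a_idx, ct]
  }
  truth$q[, ct] <- q_val
  truth$sY[, ct] <- sY
  truth$sO[, ct] <- sO
  truth
}

# Textbook step-up BH, written independently of the package implementation.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Two-cluster cohort in which a chosen fraction of cluster B cells co-express
# n_expr of cluster A's top-10 markers (doublet-rule scenarios).
doublet_fixture <- function(frac_pos, n_expr = 8, seed = 31) {
  set.seed(seed)
  nA <- 40; nB <- 40; G <- 30
  counts <- matrix(rpois((nA + nB) * G, 1), G, nA + nB,
                   dimnames = list(sprintf("g%02d", 1:G),
                                   sprintf("c%d", 1:(nA + nB))))
  markersA <- sprintf("g%02d", 1:10)
  counts[markersA, 1:nA] <- rpois(10 * nA, 15)        # A expresses its markers
  counts[markersA, (nA + 1):(nA + nB)] <- 0           # B silent by default
  n_pos <- round(frac_pos * nB)
  if (n_pos > 0) {
    pos <- nA + seq_len(n_pos)
    counts[markersA[seq_len(n_expr)], pos] <- rpois(n_expr * n_pos, 5) + 1
  }
  meta <- data.frame(barcode = colnames(counts),
                     animal_id = "YX_01", animal_type = "YX",
                     cell_type = rep(c("A", "B"), c(nA, nB)), batch = "b1",
                     stringsAsFactors = FALSE)
  coh <- new_cell_cohort(Matrix::Matrix(counts, sparse = TRUE), meta)
  cl <- meta$cell_type
  list(cohort = coh, labels = cl,
       markers = find_cluster_markers(coh, cl, top_n = 10),
       class_map = c(A = "neuronal", B = "vascular"))
}
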