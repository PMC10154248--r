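#' Plant ground-truth expression effects
#'
#' Selects affected genes per cell type and per effect by a seeded shuffle
#' (take the first `floor(frac * n_genes)` genes of the shuffled order) and
#' draws their log2 effect sizes from the configured normal distribution.
#' All other entries are exactly zero.
#'
#' @param config A [sim_config()].
#' @return Object of class `effect_truth`: a list with `genes`, `cell_types`
#'   and one `n_genes x n_cell_types` matrix per effect (`a`, `sY`, `sO`,
#'   `r`, `q`), plus the affected-gene index per (effect, cell type).
#' @export
plant_effects <- function(config) {
  validate_sim_config(config)
  genes <- gene_names(config)
  cts <- names(config$cell_types)
  G <- config$n_genes
  mats <- list()
  affected <- list()
  for (eff in c("a", "sY", "sO", "r", "q")) {
    m <- matrix(0, G, length(cts), dimnames = list(genes, cts))
    affected[[eff]] <- list()
    spec <- config$effects[[eff]]
    n_aff <- floor(spec$frac * G)
    for (ct in cts) {
      if (n_aff > 0) {
        rs <- .rng_state(derive_seed(config$seed, paste("effects", eff, ct)))
        idx <- sample.int(G)[seq_len(n_aff)]
        m[idx, ct] <- stats::rnorm(n_aff, spec$mean, spec$sd)
        .rng_restore(rs)
        affected[[eff]][[ct]] <- sort(idx)
      } else {
        affected[[eff]][[ct]] <- integer(0)
      }
    }
    mats[[eff]] <- m
  }
  structure(c(list(genes = genes, cell_types = cts, affected = affected), mats),
            class = "effect_truth")
}

gene_names <- function(config) {
  G <- config$n_genes
  nm <- sprintf("gene%04d", seq_len(G))
  if (config$n_mito_genes > 0) {
    nm[seq_len(config$n_mito_genes)] <- sprintf("mt-gene%02d",
                                                seq_len(config$n_mito_genes))
  }
  nm
}

# Scoped RNG: save/restore the caller's .Random.seed around a seeded draw.
.rng_state <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.rng_restore <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Expected log2 mean offset for an animal type
#'
#' The generative counterparts of the double-difference designs: unpaired
#' young animals (YX) are the reference; surgery effects enter both members
#' of a pairing arm, aging enters all old arms, and the heterochronic shifts
#' `r` (old joined to young) and `q` (young joined to old) enter only their
#' own arm:
#' \deqn{YX: 0;\; YY: sY;\; YO: sY + q;\; OX: a;\; OO: a + sO;\; OY: a + sO + r}
#' Consequently the RJV contrast has expectation `r - a` and the AGA contrast
#' `q + a`, and the surgery effects cancel exactly.
#'
#' @param truth An [plant_effects()] result.
#' @param animal_type One of [animal_types()] (vectorized).
#' @param gene Gene name or index (vectorized).
#' @param cell_type Cell-type name.
#' @return Numeric vector of log2 offsets.
#' @export
expected_log2_offset <- function(truth, animal_type, gene, cell_type) {
  .check_animal_type(animal_type)
  om <- offset_matrix(truth, cell_type)
  om[cbind(gene, animal_type)]
}

#' Full gene-by-animal-type offset matrix for one cell type
#'
#' @inheritParams expected_log2_offset
#' @return `n_genes x 6` matrix of log2 offsets, columns ordered as
#'   [animal_types()].
#' @export
offset_matrix <- function(truth, cell_type) {
  stopifnot(inherits(truth, "effect_truth"))
  if (!cell_type %in% truth$cell_types) stop("unknown cell type: ", cell_type, call. = FALSE)
  a <- truth$a[, cell_type]; sY <- truth$sY[, cell_type]
  sO <- truth$sO[, cell_type]; r <- truth$r[, cell_type]; q <- truth$q[, cell_type]
  cbind(YX = a * 0, YY = sY, YO = sY + q, OX = a, OO = a + sO, OY = a + sO + r)
}

#' Simulate a single-cell parabiosis cohort
#'
#' Draws UMI counts per cell as NB(mean = library-size factor x baseline
#' relative abundance x 2^(animal-type offset + per-animal random effect),
#' dispersion phi). All draws are made by inverse CDF on seeded uniforms so
#' that two configs differing only in planted effect sizes produce exactly
#' coupled cohorts (same uniforms, shifted means) — this is what makes
#' invariance checks such as surgery cancellation sharp.
#'
#' @param config A [sim_config()].
#' @param truth Optional [plant_effects()] result; computed from `config` if
#'   missing.
#' @return Object of class `cell_cohort`: a list with `counts` (sparse
#'   genes x cells dgCMatrix), `meta` (one row per cell: barcode, animal_id,
#'   animal_type, cell_type, batch, nCount, nFeature, percent_mito), and the
#'   `truth` and `config` used.
#' @export
simulate_cohort <- function(config, truth = plant_effects(config)) {
  validate_sim_config(config)
  genes <- gene_names(config)
  G <- config$n_genes
  cts <- names(config$cell_types)
  phi <- rep_len(unlist(config$dispersion), G)

  # baseline relative abundance; mito genes rescaled to a fixed total share
  rs <- .rng_state(derive_seed(config$seed, "baseline"))
  base <- stats::rgamma(G, shape = config$baseline_shape, rate = 1)
  .rng_restore(rs)
  is_mito <- startsWith(genes, "mt-")
  if (any(is_mito) && config$mito_expr_frac > 0) {
    base[is_mito] <- base[is_mito] / sum(base[is_mito]) * config$mito_expr_frac
    base[!is_mito] <- base[!is_mito] / sum(base[!is_mito]) * (1 - config$mito_expr_frac)
  } else {
    base[is_mito] <- 0
    base <- base / sum(base)
  }

  # animal roster and batch (round-robin, no batch effect)
  atype <- rep(names(config$n_animals), config$n_animals)
  animal_id <- unlist(lapply(names(config$n_animals), function(ty) {
    sprintf("%s_%02d", ty, seq_len(config$n_animals[[ty]]))
  }))
  n_batches <- 3L
  batch <- sprintf("b%d", (seq_along(animal_id) - 1L) %% n_batches + 1L)
  names(atype) <- names(batch) <- animal_id

  # per-(animal, gene) random intercept (log2), shared across cell types
  re <- matrix(0, G, length(animal_id), dimnames = list(genes, animal_id))
  if (config$animal_sd_log2 > 0) {
    for (an in animal_id) {
      rs <- .rng_state(derive_seed(config$seed, paste("animal_re", an)))
      re[, an] <- stats::qnorm(stats::runif(G)) * config$animal_sd_log2
      .rng_restore(rs)
    }
  }

  offs <- lapply(cts, function(ct) offset_matrix(truth, ct))
  names(offs) <- cts

  blocks <- list()
  meta_rows <- list()
  for (an in animal_id) {
    for (ct in cts) {
      sd_ct <- derive_seed(config$seed, paste("cells", an, ct))
      mu_cells <- config$cells_per_animal * config$cell_types[[ct]]
      rs <- .rng_state(sd_ct)
      u_n <- stats::runif(1)
      n_cells <- if (config$cells_overdispersion > 0) {
        stats::qnbinom(u_n, mu = mu_cells, size = 1 / config$cells_overdispersion)
      } else {
        stats::qpois(u_n, mu_cells)
      }
      u_lib <- stats::runif(n_cells)
      u_cnt <- if (n_cells > 0) stats::runif(as.double(G) * n_cells) else numeric(0)
      .rng_restore(rs)
      if (n_cells == 0) next
      libsize <- stats::qlnorm(u_lib, config$libsize_meanlog, config$libsize_sdlog)
      lam <- base * 2^(offs[[ct]][, atype[[an]]] + re[, an])
      mu <- lam %o% libsize  # G x n_cells
      cnt <- matrix(0, G, n_cells)
      pos <- phi > 0
      if (any(pos)) {
        cnt[pos, ] <- stats::qnbinom(matrix(u_cnt, G, n_cells)[pos, , drop = FALSE],
                                     mu = mu[pos, , drop = FALSE],
                                     size = 1 / phi[pos])
      }
      if (any(!pos)) {
        cnt[!pos, ] <- stats::qpois(matrix(u_cnt, G, n_cells)[!pos, , drop = FALSE],
                                    mu[!pos, , drop = FALSE])
      }
      bc <- sprintf("%s.%s.c%04d", an, ct, seq_len(n_cells))
      blocks[[length(blocks) + 1L]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        barcode = bc, animal_id = an, animal_type = atype[[an]],
        cell_type = ct, batch = batch[[an]], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(blocks)) stop("no cells simulated; check cohort sizes", call. = FALSE)
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta_rows)
  rownames(counts) <- genes
  colnames(counts) <- meta$barcode
  meta$nCount <- Matrix::colSums(counts)
  meta$nFeature <- Matrix::colSums(counts > 0)
  mito_sum <- Matrix::colSums(counts[is_mito, , drop = FALSE])
  meta$percent_mito <- ifelse(meta$nCount > 0, 100 * mito_sum / meta$nCount, 0)
  rownames(meta) <- meta$barcode
  new_cell_cohort(counts, meta, truth = truth, config = config)
}

#' Construct a cell cohort container
#'
#' @param counts Sparse genes x cells count matrix.
#' @param meta Per-cell metadata data.frame (rows match columns of `counts`).
#' @param truth,config Optional provenance from the simulator.
#' @return Object of class `cell_cohort`.
#' @export
new_cell_cohort <- function(counts, meta, truth = NULL, config = NULL) {
  stopifnot(ncol(counts) == nrow(meta))
  need <- c("barcode", "animal_id", "animal_type", "cell_type")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  tab <- unique(meta[, c("animal_id", "animal_type")])
  if (anyDuplicated(tab$animal_id)) {
    stop("an animal id maps to more than one animal type", call. = FALSE)
  }
  structure(list(counts = counts, meta = meta, truth = truth, config = config),
            class = "cell_cohort")
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat(sprintf("cell_cohort: %d genes x %d cells, %d animals, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$animal_id)),
              length(unique(x$meta$cell_type))))
  tt <- table(x$meta$animal_type)
  cat("  cells per arm:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_cohort <- function(x) dim(x$counts)

#' Subset a cohort by cells (and optionally genes)
#'
#' @param cohort A `cell_cohort`.
#' @param cells Logical/integer/character index over cells.
#' @param genes Optional index over genes.
#' @return Subsetted `cell_cohort`.
#' @export
subset_cohort <- function(cohort, cells = NULL, genes = NULL) {
  counts <- cohort$counts
  meta <- cohort$meta
  if (!is.null(cells)) {
    counts <- counts[, cells, drop = FALSE]
    meta <- meta[cells, , drop = FALSE]
  }
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  new_cell_cohort(counts, meta, truth = cohort$truth, config = cohort$config)
}
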