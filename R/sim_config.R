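#' Simulation configuration for a six-arm parabiosis cohort
#'
#' Collects every knob of the cohort generator. Defaults emulate the structure
#' of a droplet-based mouse brain parabiosis study: six unbalanced animal arms
#' (8 YX, 7 YY, 9 YO, 8 OX, 7 OO, 11 OY), negative-binomial UMI counts with a
#' per-animal random intercept, log-normal per-cell library sizes with median
#' about 2,800 UMI, and planted log2-scale effects for aging (`a`), surgery in
#' young (`sY`) and old (`sO`) animals, rejuvenation (`r`) and
#' aging-acceleration (`q`).
#'
#' @param n_animals Named integer vector of animals per arm; names must be
#'   exactly the six labels of [animal_types()].
#' @param n_genes Number of genes.
#' @param cell_types Named numeric vector of relative cell-type abundances
#'   (must sum to 1).
#' @param cells_per_animal Mean number of cells captured per animal (across
#'   all cell types).
#' @param cells_overdispersion Negative-binomial overdispersion of the
#'   per-(animal, cell type) cell count around its mean; 0 gives Poisson.
#' @param baseline_shape Gamma shape of the baseline relative gene-abundance
#'   distribution (normalized to sum 1 per cell type).
#' @param dispersion Global NB dispersion phi (variance `mu + phi * mu^2`), or
#'   a per-gene vector. 0 gives Poisson counts.
#' @param animal_sd_log2 SD of the per-(animal, gene) random intercept on the
#'   log2 scale; this is what gives pseudobulk replicates genuine
#'   between-animal variance.
#' @param libsize_meanlog,libsize_sdlog Log-normal parameters of the per-cell
#'   library-size factor (natural-log scale); defaults give median 2,800 UMI.
#' @param effects Named list with entries `a`, `sY`, `sO`, `r`, `q`; each a
#'   list `list(frac =, mean =, sd =)` giving the fraction of genes affected
#'   and the normal distribution (log2 scale) the nonzero effect sizes are
#'   drawn from. Use `sd = 0` for a fixed effect size.
#' @param n_mito_genes Number of genes labelled mitochondrial (name prefix
#'   `mt-`).
#' @param mito_expr_frac Total baseline expression share of the mitochondrial
#'   genes; default 0.01 keeps simulated animals below the 1.5% animal-level
#'   QC threshold while still exercising the per-cell filters.
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = c(YX = 8, YY = 7, YO = 9, OX = 8, OO = 7, OY = 11),
                       n_genes = 2000,
                       cell_types = c(CT1 = 1),
                       cells_per_animal = 40,
                       cells_overdispersion = 0.05,
                       baseline_shape = 0.5,
                       dispersion = 0.4,
                       animal_sd_log2 = 0.15,
                       libsize_meanlog = log(2800),
                       libsize_sdlog = 0.35,
                       effects = default_effects(),
                       n_mito_genes = 13,
                       mito_expr_frac = 0.01,
                       seed = 1L) {
  cfg <- structure(list(
    n_animals = n_animals, n_genes = as.integer(n_genes),
    cell_types = cell_types, cells_per_animal = cells_per_animal,
    cells_overdispersion = cells_overdispersion,
    baseline_shape = baseline_shape, dispersion = dispersion,
    animal_sd_log2 = animal_sd_log2,
    libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
    effects = effects, n_mito_genes = as.integer(n_mito_genes),
    mito_expr_frac = mito_expr_frac, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default planted-effect specification
#'
#' A modest regime: 5% of genes per effect, effect sizes N(0, 1) on the log2
#' scale (so typical |effects| around 0.8 log2 units). Tests and analyses
#' override these to create specific scenarios.
#'
#' @param frac,mean,sd Shared defaults applied to every effect.
#' @return Named list with entries `a`, `sY`, `sO`, `r`, `q`.
#' @export
default_effects <- function(frac = 0.05, mean = 0, sd = 1) {
  eff <- list(frac = frac, mean = mean, sd = sd)
  list(a = eff, sY = eff, sO = eff, r = eff, q = eff)
}

#' @rdname sim_config
#' @param cfg A `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!setequal(names(cfg$n_animals), animal_types())) {
    stop("n_animals must be named with exactly the six animal types ",
         paste(animal_types(), collapse = ", "), call. = FALSE)
  }
  if (any(cfg$n_animals < 0)) stop("animal counts must be nonnegative", call. = FALSE)
  if (cfg$n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  if (is.null(names(cfg$cell_types)) || any(cfg$cell_types < 0)) {
    stop("cell_types must be a named vector of nonnegative abundances", call. = FALSE)
  }
  if (abs(sum(cfg$cell_types) - 1) > 1e-8) {
    stop("cell-type relative abundances must sum to 1", call. = FALSE)
  }
  if (any(unlist(cfg$dispersion) < 0)) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$animal_sd_log2 < 0 || cfg$cells_overdispersion < 0 ||
      cfg$cells_per_animal <= 0 || cfg$baseline_shape <= 0) {
    stop("rates and scales must be nonnegative", call. = FALSE)
  }
  if (!setequal(names(cfg$effects), c("a", "sY", "sO", "r", "q"))) {
    stop("effects must contain exactly a, sY, sO, r, q", call. = FALSE)
  }
  for (nm in names(cfg$effects)) {
    e <- cfg$effects[[nm]]
    if (e$frac < 0 || e$frac > 1) {
      stop("effect fraction for ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_mito_genes < 0 || cfg$n_mito_genes >= cfg$n_genes) {
    stop("n_mito_genes must be in [0, n_genes)", call. = FALSE)
  }
  if (cfg$mito_expr_frac < 0 || cfg$mito_expr_frac >= 1) {
    stop("mito_expr_frac must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Parabiosis cohort simulation config\n")
  cat("  animals:", paste(sprintf("%d %s", x$n_animals, names(x$n_animals)),
                          collapse = ", "), "\n")
  cat("  genes:", x$n_genes, " cell types:", length(x$cell_types),
      " cells/animal:", x$cells_per_animal, "\n")
  cat("  NB dispersion:", x$dispersion[1], " animal SD (log2):",
      x$animal_sd_log2, " seed:", x$seed, "\n")
  fr <- vapply(x$effects, function(e) e$frac, numeric(1))
  cat("  effect fractions:", paste(sprintf("%s=%.3g", names(fr), fr),
                                   collapse = ", "), "\n")
  invisible(x)
}

# Deterministic sub-seed derivation: one global seed fans out to independent
# streams per component so that e.g. changing an effect size never perturbs
# library sizes or cell counts. Simple 32-bit multiplicative hash of the tag.
derive_seed <- function(seed, tag) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}
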