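#' Pipeline configuration
#'
#' Bundles paths, thresholds and stage settings for [run_pipeline()].
#' Written to / read from a YAML file so runs are auditable and repeatable.
#'
#' @param cohort_dir Path to a cohort in MTX+TSV interchange format, or
#'   `NULL` to simulate one from `sim`.
#' @param gmt Optional path to a GMT gene-set collection for the pathway
#'   enrichment stage.
#' @param senescence_gmt Optional path to a single-set GMT for the
#'   senescence scan.
#' @param ortholog_map Optional path to a two-column TSV (source, target)
#'   applied to ranked lists before enrichment.
#' @param out_dir Output directory.
#' @param qc A [qc_thresholds()].
#' @param contrasts Names from [standard_contrasts()] to test.
#' @param fdr DGE significance threshold (default 0.05).
#' @param gsea_nperm,gsea_min_size,gsea_max_size,gsea_fdr Enrichment settings
#'   (defaults 1000, 15, 500, 0.25).
#' @param sim A [sim_config()] used when `cohort_dir` is NULL.
#' @param seed Global seed; per-stage seeds derive from it deterministically.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, gmt = NULL,
                            senescence_gmt = NULL, ortholog_map = NULL,
                            out_dir = "parabulk_out",
                            qc = qc_thresholds(),
                            contrasts = c("RJV", "AGA", "OXvYX"),
                            fdr = 0.05,
                            gsea_nperm = 1000, gsea_min_size = 15,
                            gsea_max_size = 500, gsea_fdr = 0.25,
                            sim = sim_config(), seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (when no cohort path is given) -> cell/gene QC ->
#' pseudobulk aggregation, TMM, NB quasi-likelihood contrasts -> shift
#' catalog (bidirectional classes, upset counts, frequencies) -> pathway
#' enrichment (when a GMT is given) -> senescence scan (when a senescence
#' GMT is given). All artifacts are flat TSV/MTX/JSON; a manifest records
#' the config, seed and per-stage row counts and skip reasons.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("cohort_dir", "gmt", "senescence_gmt", "ortholog_map")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("configured path does not exist: ", p, " = ", config[[p]], call. = FALSE)
    }
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message(sprintf("[%s] %s", name,
                    paste(sprintf("%s=%s", names(list(...)), list(...)),
                          collapse = " ")))
  }

  if (is.null(config$cohort_dir)) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, "simulate")
    cohort <- simulate_cohort(sim)
    write_cohort(cohort, file.path(out, "cohort"))
    log_stage("simulate", cells = ncol(cohort$counts), genes = nrow(cohort$counts))
  } else {
    cohort <- read_cohort(config$cohort_dir)
    log_stage("load", cells = ncol(cohort$counts), genes = nrow(cohort$counts))
  }

  cohort <- filter_cells(cohort, config$qc)
  rep_ <- attr(cohort, "qc_report")
  excl <- exclude_animals(cohort, config$qc)
  bad <- excl$animal_id[excl$excluded]
  if (length(bad)) {
    cohort <- subset_cohort(cohort, cells = !cohort$meta$animal_id %in% bad)
  }
  utils::write.table(excl, file.path(out, "animal_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("qc", cells_removed = rep_$cells_removed,
            genes_removed = rep_$genes_removed,
            animals_excluded = length(bad))

  contrasts <- standard_contrasts()[config$contrasts]
  dge <- run_dge(cohort, contrasts)
  write_dge_tables(dge$tables, file.path(out, "dge"))
  utils::write.table(dge$skipped, file.path(out, "dge_skipped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("dge", cell_types_tested = length(dge$tables),
            skipped = nrow(dge$skipped))

  if (all(c("RJV", "AGA") %in% config$contrasts)) {
    shifts <- list(); freq <- list()
    for (ct in names(dge$tables)) {
      t_ <- dge$tables[[ct]]
      if (!all(c("RJV", "AGA") %in% names(t_))) next
      sh <- classify_bidirectional(t_$RJV, t_$AGA, fdr = config$fdr)
      sh <- cbind(cell_type = ct, sh)
      shifts[[ct]] <- sh
      n_cells <- sum(cohort$meta$cell_type == ct)
      freq[[ct]] <- data.frame(
        cell_type = ct, n_cells = n_cells,
        rjv_dge = sum(!is.na(t_$RJV$p_adj.loc) & t_$RJV$p_adj.loc <= config$fdr),
        aga_dge = sum(!is.na(t_$AGA$p_adj.loc) & t_$AGA$p_adj.loc <= config$fdr),
        stringsAsFactors = FALSE
      )
      freq[[ct]]$rjv_per100 <- normalized_dge_frequency(freq[[ct]]$rjv_dge, n_cells)
      freq[[ct]]$aga_per100 <- normalized_dge_frequency(freq[[ct]]$aga_dge, n_cells)
    }
    if (length(shifts)) {
      shift_tab <- do.call(rbind, shifts)
      utils::write.table(shift_tab, file.path(out, "shift_catalog.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(do.call(rbind, freq), file.path(out, "dge_frequency.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (dir_ in c("up", "down")) {
        up <- overlap_sets(lapply(dge$tables, `[[`, "RJV"), dir_, fdr = config$fdr)
        utils::write.table(up, file.path(out, sprintf("upset_RJV_%s.tsv", dir_)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log_stage("shift", records = nrow(shift_tab),
                bidirectional = sum(shift_tab$class %in%
                  c("down_in_RJV_up_in_AGA", "up_in_RJV_down_in_AGA")))
    }
  }

  if (!is.null(config$gmt)) {
    coll <- read_gmt(config$gmt)
    n_enr <- 0L
    for (ct in names(dge$tables)) {
      for (cn in names(dge$tables[[ct]])) {
        rk <- ranked_list(dge$tables[[ct]][[cn]])
        if (!is.null(config$ortholog_map)) {
          mp <- utils::read.delim(config$ortholog_map, stringsAsFactors = FALSE)
          rk <- map_orthologs(rk, mp)
        }
        enr <- permutation_enrichment(
          rk, coll, n_perm = config$gsea_nperm,
          min_size = config$gsea_min_size, max_size = config$gsea_max_size,
          seed = derive_seed(config$seed, paste("gsea", ct, cn)),
          fdr = config$gsea_fdr
        )
        utils::write.table(enr, file.path(out, sprintf("gsea_%s_%s.tsv", ct, cn)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        n_enr <- n_enr + nrow(enr)
      }
    }
    log_stage("gsea", records = n_enr)
  }

  if (!is.null(config$senescence_gmt)) {
    sen_coll <- read_gmt(config$senescence_gmt)
    sen <- senescence_scan(dge$tables, sen_coll[[1]],
                           n_perm = config$gsea_nperm,
                           seed = derive_seed(config$seed, "senescence"))
    if (!is.null(sen)) {
      utils::write.table(sen, file.path(out, "senescence_scan.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log_stage("senescence", records = nrow(sen))
    }
  }

  manifest$config <- lapply(unclass(config), function(x)
    if (inherits(x, "qc_thresholds") || inherits(x, "sim_config")) unclass(x) else x)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Read a pipeline config from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `qc` and
#' `sim` sub-maps override individual threshold / simulator fields.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("qc", "sim"))]
  if (!is.null(y$qc)) args$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$n_animals)) y$sim$n_animals <- unlist(y$sim$n_animals)
    if (!is.null(y$sim$cell_types)) y$sim$cell_types <- unlist(y$sim$cell_types)
    args$sim <- do.call(sim_config, y$sim)
  }
  do.call(pipeline_config, args)
}
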