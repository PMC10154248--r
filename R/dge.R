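#' Pseudobulk differential expression across cell types and contrasts
#'
#' The full DGE stage: aggregate the cohort to per-animal pseudobulk sums per
#' cell type, compute TMM factors, apply the gene and testability filters,
#' fit the NB quasi-likelihood model once per cell type and test every
#' requested contrast, then attach per-animal-type TPM and percent-expressing
#' summaries and BH-adjusted q-values — `p_adj.loc` within each (cell type,
#' contrast) table and `p_adj.glb` across all tested cell types of the run.
#'
#' @param cohort A QC-filtered `cell_cohort`.
#' @param contrasts Named list of [contrast_vec()] objects (default
#'   [standard_contrasts()]).
#' @param min_total_count,min_animals_detected,min_animals_per_type,min_cells
#'   Passed to [filter_test_units()].
#' @param pooled_tpm Use pooled-count TPM per animal type (see
#'   [summarize_tpm_pct()]).
#' @param ... Passed to [fit_nb_glm()].
#' @return list with `tables` (nested: `tables[[cell_type]][[contrast]]`, each
#'   a `dge_table` with q-value and TPM/pct columns), `skipped` (data.frame of
#'   skip reasons), `fits` (the `nb_fit` per tested cell type) and `assays`.
#' @export
run_dge <- function(cohort, contrasts = standard_contrasts(),
                    min_total_count = 10, min_animals_detected = 2,
                    min_animals_per_type = 2, min_cells = 10,
                    pooled_tpm = FALSE, ...) {
  stopifnot(length(contrasts) > 0, !is.null(names(contrasts)))
  assays <- aggregate_pseudobulk(cohort)
  tables <- list(); fits <- list(); skipped <- list(); kept_assays <- list()
  for (ct in names(assays)) {
    assay <- tmm_factors(assays[[ct]])
    fitted <- NULL
    for (cn in names(contrasts)) {
      fl <- filter_test_units(stats::setNames(list(assay), ct), contrasts[[cn]],
                              min_total_count, min_animals_detected,
                              min_animals_per_type, min_cells)
      if (!length(fl$assays)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(cell_type = ct, contrast = cn,
                     reason = fl$skipped$reason[1], stringsAsFactors = FALSE)
        next
      }
      if (is.null(fitted)) {
        # gene filters are contrast-independent; fit once per cell type
        kept_assays[[ct]] <- fl$assays[[ct]]
        fitted <- fit_nb_glm(fl$assays[[ct]], ...)
        fits[[ct]] <- fitted
        summ <- summarize_tpm_pct(cohort, fl$assays[[ct]], pooled = pooled_tpm)
      }
      missing_types <- setdiff(names(contrasts[[cn]])[contrasts[[cn]] != 0],
                               colnames(fitted$design))
      if (length(missing_types)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(cell_type = ct, contrast = cn,
                     reason = paste("animal type(s) absent:",
                                    paste(missing_types, collapse = ", ")),
                     stringsAsFactors = FALSE)
        next
      }
      tab <- ql_f_test(fitted, contrasts[[cn]])
      tab$p_adj.loc <- bh_adjust(tab$p_val)
      for (ty in colnames(summ$tpm)) tab[[paste0("tpm.", ty)]] <- summ$tpm[, ty]
      for (ty in colnames(summ$pct)) tab[[paste0("pct.", ty)]] <- summ$pct[, ty]
      tables[[ct]][[cn]] <- tab
    }
  }
  # global BH across all cell types, per contrast
  for (cn in unique(unlist(lapply(tables, names)))) {
    cts <- names(tables)[vapply(tables, function(x) cn %in% names(x), logical(1))]
    allp <- unlist(lapply(cts, function(ct) tables[[ct]][[cn]]$p_val))
    allq <- bh_adjust(allp)
    i <- 0L
    for (ct in cts) {
      nG <- nrow(tables[[ct]][[cn]])
      tables[[ct]][[cn]]$p_adj.glb <- allq[i + seq_len(nG)]
      i <- i + nG
    }
  }
  list(tables = tables,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(cell_type = character(0), contrast = character(0),
                    reason = character(0)),
       fits = fits, assays = kept_assays)
}
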