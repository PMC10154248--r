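#' Preranked gene score
#'
#' The rank metric: `-log10(p) * sign(log2FC)` (zero log2FC gives 0).
#' p-values of exactly 0 are capped at `p_floor` to keep scores finite.
#'
#' @param p_val P-values in (0, 1] (0 allowed, capped).
#' @param log2FC Finite log2 fold-changes.
#' @param p_floor Smallest p used (default the smallest positive normalized
#'   double, i.e. about 2.2e-308).
#' @return Numeric scores.
#' @export
rank_metric <- function(p_val, log2FC, p_floor = .Machine$double.xmin) {
  stopifnot(all(is.finite(log2FC)), all(p_val >= 0 & p_val <= 1, na.rm = TRUE))
  -log10(pmax(p_val, p_floor)) * sign(log2FC)
}

#' Build a ranked list from a DGE table
#'
#' Scores via [rank_metric()], sorted descending; ties keep their input
#' order (stable sort) so runs are reproducible.
#'
#' @param tab A `dge_table` (needs `gene`, `p_val`, `logFC`); rows with
#'   missing p are dropped.
#' @return data.frame (gene, score) of class `ranked_list`, sorted
#'   descending.
#' @export
ranked_list <- function(tab) {
  tab <- tab[!is.na(tab$p_val), , drop = FALSE]
  if (anyDuplicated(tab$gene)) stop("duplicate genes in ranked list", call. = FALSE)
  sc <- rank_metric(tab$p_val, tab$logFC)
  ord <- order(-sc)  # stable in base R
  out <- data.frame(gene = tab$gene[ord], score = sc[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic running-sum statistic: walking down the ranked list, set members
#' ("hits") increment the sum by `|score|^weight / sum(|score|^weight)` and
#' non-members decrement by `1 / (N - n_set)`; the ES is the extremum of
#' largest magnitude. The leading edge is the prefix (or suffix, for
#' negative ES) of set members up to the extremum.
#'
#' @param ranked A [ranked_list()] (or data.frame gene/score, sorted
#'   descending).
#' @param set Character vector of gene identifiers.
#' @param weight Score-weighting exponent (default 1; 0 gives the unweighted
#'   KS statistic).
#' @return list(es, position, leading_edge); `NA` es when the set does not
#'   intersect the list.
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  hits <- ranked$gene %in% set
  n_hit <- sum(hits)
  N <- nrow(ranked)
  if (n_hit == 0 || n_hit == N) {
    return(list(es = NA_real_, position = NA_integer_, leading_edge = character(0)))
  }
  w <- abs(ranked$score)^weight
  wh <- w * hits
  denom <- sum(wh)
  inc <- if (denom > 0) wh / denom else hits / n_hit  # all-zero scores: uniform
  dec <- (!hits) / (N - n_hit)
  running <- cumsum(inc - dec)
  pos <- which.max(abs(running))
  es <- running[pos]
  le <- if (es >= 0) {
    ranked$gene[seq_len(pos)][hits[seq_len(pos)]]
  } else {
    ranked$gene[pos:N][hits[pos:N]]
  }
  list(es = es, position = pos, leading_edge = le)
}

# ES for many random same-size index sets at once (gene-label permutation
# null). Uses only hit positions: the running sum is piecewise linear with
# candidate extrema just after each hit and just before the next.
.null_es <- function(absw, n_set, n_perm) {
  N <- length(absw)
  vapply(seq_len(n_perm), function(i) {
    idx <- sort(sample.int(N, n_set))
    wh <- absw[idx]
    denom <- sum(wh)
    inc <- if (denom > 0) cumsum(wh) / denom else seq_len(n_set) / n_set
    miss_before <- (idx - seq_len(n_set)) / (N - n_set)
    up <- inc - miss_before                      # just after each hit
    down <- c(0, inc[-n_set]) - miss_before      # just before each hit
    m1 <- max(up); m2 <- min(down)
    if (m1 >= -m2) m1 else m2
  }, numeric(1))
}

#' Permutation preranked enrichment over a gene-set collection
#'
#' Sets are intersected with the ranked universe and filtered to
#' `[min_size, max_size]`; significance is assessed against a gene-label
#' permutation null (random same-size sets drawn from the ranked list),
#' with one-sided tail p-values with +1 smoothing, NES = ES / mean(|null ES|
#' of matching sign), BH adjustment over all tested sets, and a significance
#' flag at `q <= fdr`.
#'
#' @param ranked A [ranked_list()].
#' @param collection A [gene_set_collection()] (named list of gene sets).
#' @param n_perm Permutations per set (default 1000).
#' @param min_size,max_size Post-intersection size filter (defaults 15, 500;
#'   use `min_size = 1, max_size = Inf` to disable).
#' @param seed Integer seed for the permutation stream.
#' @param fdr Significance threshold on q (default 0.25).
#' @param weight Passed to [enrichment_score()].
#' @return data.frame: set, size, es, nes, p_val, q_val, significant,
#'   leading_edge (comma-joined); empty (with a warning) when no set
#'   survives filtering.
#' @export
permutation_enrichment <- function(ranked, collection, n_perm = 1000,
                                   min_size = 15, max_size = 500,
                                   seed = 1L, fdr = 0.25, weight = 1) {
  stopifnot(inherits(ranked, "data.frame"), nrow(ranked) > 0)
  sizes <- vapply(collection, function(s) length(intersect(s, ranked$gene)),
                  integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    warning("no gene set survives the size filter")
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_val = numeric(0), q_val = numeric(0),
                      significant = logical(0), leading_edge = character(0)))
  }
  absw <- abs(ranked$score)^weight
  rows <- list()
  for (nm in names(collection)[keep]) {
    obs <- enrichment_score(ranked, collection[[nm]], weight = weight)
    rs <- .rng_state(derive_seed(seed, paste("gsea", nm)))
    null <- .null_es(absw, sizes[[nm]], n_perm)
    .rng_restore(rs)
    same <- if (obs$es >= 0) null[null >= 0] else null[null < 0]
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    rows[[nm]] <- data.frame(
      set = nm, size = sizes[[nm]], es = obs$es, nes = nes, p_val = p,
      leading_edge = paste(obs$leading_edge, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$q_val <- bh_adjust(out$p_val)
  out$significant <- out$q_val <= fdr
  out <- out[, c("set", "size", "es", "nes", "p_val", "q_val", "significant",
                 "leading_edge")]
  rownames(out) <- NULL
  out
}

#' Senescence-signature scan across cell types and paradigms
#'
#' Runs single-set permutation enrichment of a curated senescence gene set
#' against the preranked gene list of every (cell type, paradigm) DGE table
#' — typically aging, RJV and AGA. No size filter is applied (the curated
#' set is a single reference list); BH adjustment is performed across the
#' whole grid of scans.
#'
#' @param dge_tables Nested list `tables[[cell_type]][[paradigm]]` of
#'   `dge_table`s (as from [run_dge()]).
#' @param senescence_set Nonempty character vector of senescence gene
#'   identifiers.
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @return data.frame: cell_type, paradigm, size, es, nes, p_val, p_adj,
#'   leading_edge. Cell types whose table yields no ranked genes are
#'   omitted with a message.
#' @export
senescence_scan <- function(dge_tables, senescence_set, n_perm = 1000,
                            seed = 1L) {
  if (!length(senescence_set)) stop("senescence set is empty", call. = FALSE)
  rows <- list()
  for (ct in names(dge_tables)) {
    for (pd in names(dge_tables[[ct]])) {
      tab <- dge_tables[[ct]][[pd]]
      if (is.null(tab) || !nrow(tab) || all(is.na(tab$p_val))) {
        message("senescence scan: no ranked genes for ", ct, "/", pd)
        next
      }
      rk <- ranked_list(tab)
      res <- permutation_enrichment(
        rk, gene_set_collection(list(senescence = senescence_set)),
        n_perm = n_perm, min_size = 1, max_size = Inf,
        seed = derive_seed(seed, paste("senescence", ct, pd))
      )
      if (!nrow(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, paradigm = pd, size = res$size, es = res$es,
        nes = res$nes, p_val = res$p_val, leading_edge = res$leading_edge,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj <- bh_adjust(out$p_val)
  rownames(out) <- NULL
  out[, c("cell_type", "paradigm", "size", "es", "nes", "p_val", "p_adj",
          "leading_edge")]
}

#' Gene-set collection constructor
#'
#' @param sets Named list of nonempty character vectors.
#' @param description Optional named character vector of set descriptions.
#' @return Named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be a uniquely named list", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) stop("empty gene set", call. = FALSE)
  sets <- lapply(sets, unique)
  structure(sets, description = description, class = c("gene_set_collection", "list"))
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descr <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line ", i, ": fewer than 3 fields", call. = FALSE)
    }
    sets[[f[1]]] <- f[-(1:2)]
    descr[f[1]] <- f[2]
  }
  gene_set_collection(sets, description = descr)
}

#' Write a GMT gene-set file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  descr <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(descr) && nm %in% names(descr)) descr[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Apply an ortholog mapping to a collection or ranked list
#'
#' For a gene-set collection, each member is replaced by all its targets
#' (one-to-many mappings keep every target), deduplicated per set; unmapped
#' genes are dropped and their count reported in a message. For a ranked
#' list, genes are renamed and, when several sources collapse onto one
#' target, the first occurrence in the ranking is kept.
#'
#' @param x A `gene_set_collection` or `ranked_list`.
#' @param mapping data.frame with columns `source` and `target`.
#' @return Object of the same type as `x`.
#' @export
map_orthologs <- function(x, mapping) {
  stopifnot(all(c("source", "target") %in% names(mapping)))
  if (inherits(x, "gene_set_collection")) {
    dropped <- 0L
    out <- lapply(x, function(s) {
      hit <- mapping$target[mapping$source %in% s]
      dropped <<- dropped + sum(!s %in% mapping$source)
      unique(hit)
    })
    out <- out[lengths(out) > 0]
    if (dropped) message("map_orthologs: dropped ", dropped, " unmapped genes")
    gene_set_collection(out)
  } else if (inherits(x, "ranked_list")) {
    i <- match(x$gene, mapping$source)
    dropped <- sum(is.na(i))
    out <- x[!is.na(i), , drop = FALSE]
    out$gene <- mapping$target[i[!is.na(i)]]
    out <- out[!duplicated(out$gene), , drop = FALSE]
    if (dropped) message("map_orthologs: dropped ", dropped, " unmapped genes")
    class(out) <- c("ranked_list", "data.frame")
    rownames(out) <- NULL
    out
  } else {
    stop("x must be a gene_set_collection or ranked_list", call. = FALSE)
  }
}
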