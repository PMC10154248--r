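#' One-hot design matrix over animal types
#'
#' One indicator column per animal type present, no intercept; columns in the
#' canonical order of [animal_types()].
#'
#' @param animal_type Character vector of per-animal labels.
#' @return animals x types 0/1 matrix.
#' @export
design_matrix <- function(animal_type) {
  .check_animal_type(animal_type)
  lev <- intersect(animal_types(), unique(animal_type))
  X <- matrix(0, length(animal_type), length(lev),
              dimnames = list(names(animal_type), lev))
  X[cbind(seq_along(animal_type), match(animal_type, lev))] <- 1
  X
}

.check_onehot <- function(design) {
  if (!all(design %in% c(0, 1)) || any(rowSums(design) != 1)) {
    stop("design must be a one-hot animal-type indicator matrix", call. = FALSE)
  }
  invisible(design)
}

# NB log-likelihood and deviance; phi may be 0 (Poisson) or a per-gene vector.
.nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (length(phi) == 1) phi <- rep(phi, nrow(y))
  ll <- numeric(nrow(y))
  pois <- phi <= 0
  if (any(pois)) {
    ll[pois] <- rowSums(stats::dpois(y[pois, , drop = FALSE],
                                     mu[pois, , drop = FALSE], log = TRUE))
  }
  if (any(!pois)) {
    sz <- 1 / phi[!pois]
    ll[!pois] <- rowSums(stats::dnbinom(y[!pois, , drop = FALSE],
                                        mu = mu[!pois, , drop = FALSE],
                                        size = sz, log = TRUE))
  }
  ll
}

.nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (length(phi) == 1) phi <- rep(phi, nrow(y))
  phim <- matrix(phi, nrow(y), ncol(y))
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(phim > 0,
               (y + 1 / phim) * log((1 + phim * y) / (1 + phim * mu)),
               y - mu)
  2 * rowSums(t1 - t2)
}

# Newton fit of the one-hot NB GLM, vectorized over genes. Because each
# animal belongs to exactly one design column, coefficients are independent
# across columns and each reduces to a 1-D root find.
.fit_onehot <- function(y, group, offset, phi) {
  G <- nrow(y); K <- max(group)
  if (length(phi) == 1) phi <- rep(phi, G)
  beta <- matrix(0, G, K)
  info <- matrix(0, G, K)
  eo <- exp(offset)
  for (k in seq_len(K)) {
    j <- which(group == k)
    yk <- y[, j, drop = FALSE]
    ok <- exp(offset[j])
    b <- log((rowSums(yk) + 0.1) / sum(ok))
    for (it in 1:100) {
      mu <- exp(b) %o% ok
      den <- 1 + phi * mu
      score <- rowSums((yk - mu) / den)
      inf <- rowSums(mu / den)
      step <- score / pmax(inf, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      b <- b + step
      if (max(abs(step)) < 1e-8) break
    }
    b <- pmax(b, -50)
    beta[, k] <- b
    mu <- exp(b) %o% ok
    info[, k] <- rowSums(mu / (1 + phi * mu))
  }
  mu_full <- exp(beta[, group, drop = FALSE] + matrix(offset, G, length(offset), byrow = TRUE))
  list(beta = beta, mu = mu_full, info = info)
}

# Adjusted profile likelihood per gene at dispersion phi (Cox-Reid style:
# log-likelihood minus half the log determinant of the Fisher information,
# which for a one-hot design is the product of per-group information terms).
.apl <- function(y, group, offset, phi) {
  fit <- .fit_onehot(y, group, offset, phi)
  .nb_loglik(y, fit$mu, phi) - 0.5 * rowSums(log(pmax(fit$info, 1e-12)))
}

#' Fit per-gene negative-binomial GLMs to a pseudobulk assay
#'
#' The model is a log-link NB GLM with a one-hot animal-type design and
#' offset log(effective library size). Dispersion is estimated in two steps:
#' a common dispersion maximizing the summed Cox-Reid adjusted profile
#' likelihood (APL) over a log-spaced grid, then a gene-wise value
#' maximizing the gene's own APL plus `prior_weight` times the average APL
#' across genes — shrinking gene-wise estimates toward the common value.
#' Coefficients are then refit at the shrunk dispersions by Newton iteration
#' to tolerance 1e-8 (at most 100 iterations).
#'
#' @param assay A `pseudobulk` object, or a genes x animals count matrix.
#' @param design One-hot design from [design_matrix()]; derived from the
#'   assay's animal types when missing.
#' @param offset Per-animal log effective library size; derived from the
#'   assay when missing.
#' @param dispersion Optional fixed dispersion (scalar or per gene),
#'   bypassing estimation.
#' @param prior_weight Shrinkage weight (equivalent number of prior genes,
#'   default 10).
#' @param grid_range,grid_length Dispersion grid (default 1e-4..4, 21 points,
#'   log-spaced).
#' @param prior_count Small library-size-proportional prior count (default
#'   0.125 per average animal) used only for the reported fold-change
#'   coefficients, keeping them finite for genes with an empty arm.
#' @return Object of class `nb_fit` with coefficients (natural-log scale),
#'   fitted means, per-gene dispersion, residual deviance and df.
#' @export
fit_nb_glm <- function(assay, design = NULL, offset = NULL, dispersion = NULL,
                       prior_weight = 10, grid_range = c(1e-4, 4),
                       grid_length = 21, prior_count = 0.125) {
  if (inherits(assay, "pseudobulk")) {
    if (is.null(design)) design <- design_matrix(assay$animal_type)
    if (is.null(offset)) offset <- log(assay$eff_lib)
    y <- assay$counts
  } else {
    y <- as.matrix(assay)
    if (is.null(design)) stop("design required for a bare matrix", call. = FALSE)
    if (is.null(offset)) offset <- log(colSums(y))
  }
  .check_onehot(design)
  stopifnot(nrow(design) == ncol(y), length(offset) == ncol(y))
  group <- apply(design > 0, 1, which)
  G <- nrow(y)

  common <- NA_real_
  if (is.null(dispersion)) {
    grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                    length.out = grid_length))
    apl <- vapply(grid, function(ph) .apl(y, group, offset, ph), numeric(G))
    tot <- colSums(apl)
    common <- grid[which.max(tot)]
    # gene-wise: maximize own APL + prior_weight * mean APL, on the grid
    # with quadratic interpolation in log(phi) around the grid maximum
    score <- apl + matrix(prior_weight * tot / G, G, length(grid), byrow = TRUE)
    lg <- log(grid)
    dispersion <- vapply(seq_len(G), function(g) {
      i <- which.max(score[g, ])
      if (i == 1 || i == length(grid)) return(grid[i])
      s <- score[g, (i - 1):(i + 1)]; x <- lg[(i - 1):(i + 1)]
      den <- (s[1] - 2 * s[2] + s[3])
      if (den >= 0) return(grid[i])
      exp(x[2] - 0.5 * (x[2] - x[1]) * (s[3] - s[1]) / den)
    }, numeric(1))
  } else {
    dispersion <- rep_len(dispersion, G)
  }

  fit <- .fit_onehot(y, group, offset, dispersion)
  mu <- fit$mu
  dev <- .nb_deviance(y, mu, dispersion)
  df_resid <- ncol(y) - ncol(design)
  # reported coefficients use a small library-size-proportional prior count
  # so fold-changes stay bounded for genes with an empty animal-type arm;
  # tests and deviances use the unaugmented fit
  el <- exp(offset)
  aug <- prior_count * length(el) * el / sum(el)
  yaug <- sweep(y, 2, aug, "+")
  rep_fit <- .fit_onehot(yaug, group, offset, dispersion)
  structure(list(
    counts = y, design = design, offset = offset, group = group,
    coefficients = structure(fit$beta, dimnames = list(rownames(y), colnames(design))),
    coefficients_shrunk = structure(rep_fit$beta,
                                    dimnames = list(rownames(y), colnames(design))),
    fitted = mu, dispersion = dispersion, common_dispersion = common,
    deviance = dev, df_resid = df_resid, genes = rownames(y)
  ), class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("nb_fit: %d genes, %d animals, %d animal types\n",
              nrow(x$counts), ncol(x$counts), ncol(x$design)))
  cat(sprintf("  common dispersion: %.4g; gene-wise range: %.4g..%.4g\n",
              x$common_dispersion, min(x$dispersion), max(x$dispersion)))
  cat(sprintf("  residual df: %d\n", x$df_resid))
  invisible(x)
}

#' @export
coef.nb_fit <- function(object, log2 = FALSE, ...) {
  if (log2) object$coefficients / log(2) else object$coefficients
}

#' @export
summary.nb_fit <- function(object, ...) {
  cat("Negative-binomial pseudobulk GLM fit\n")
  print(object)
  cat("  mean residual deviance/df:",
      format(mean(object$deviance) / max(object$df_resid, 1), digits = 4), "\n")
  invisible(object)
}

# Inverse of the trigamma function (Newton on 1/trigamma, as in classic
# empirical-Bayes variance moderation).
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

# Moment fit of the scaled-F model s2 ~ s0 * F(df1, df0) on the log scale;
# returns the prior variance s0 and prior df df0 (possibly Inf).
.fit_fdist <- function(s2, df1) {
  ok <- is.finite(s2) & s2 > 1e-12 & df1 > 0
  if (sum(ok) < 2) return(list(s0 = stats::median(s2[s2 > 0], na.rm = TRUE), df0 = Inf))
  z <- log(s2[ok])
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  ev <- stats::var(e) - trigamma(df1 / 2)
  if (is.na(ev) || ev <= 0) {
    list(s0 = exp(mean(e)), df0 = Inf)
  } else {
    df0 <- 2 * .trigamma_inverse(ev)
    list(s0 = exp(mean(e) + digamma(df0 / 2) - log(df0 / 2)), df0 = df0)
  }
}

# Constrained refit under c'beta = 0 via a null-space reparameterization
# beta = Z gamma; IRLS with per-gene (K-1)x(K-1) normal equations built from
# one-hot group sums, guarded by deviance-based step halving. Genes whose
# constrained fit does not converge are flagged (NA deviance) so the caller
# can exclude them from testing.
.fit_constrained <- function(fit, cvec) {
  y <- fit$counts; group <- fit$group; offset <- fit$offset
  phi <- fit$dispersion
  K <- ncol(fit$design); G <- nrow(y); n <- ncol(y)
  qrc <- qr(matrix(cvec, ncol = 1))
  Z <- qr.Q(qrc, complete = TRUE)[, -1, drop = FALSE]  # K x (K-1)
  ind <- matrix(0, n, K); ind[cbind(seq_len(n), group)] <- 1
  # initialize at the projection of the (floored) unconstrained solution;
  # the floor keeps empty-group coefficients from dominating the projection
  gamma <- pmax(fit$coefficients, -25) %*% Z  # G x (K-1)
  offmat <- matrix(offset, G, n, byrow = TRUE)
  dev_of <- function(gm) {
    beta <- gm %*% t(Z)
    mu <- exp(pmin(beta[, group, drop = FALSE] + offmat, 45))
    .nb_deviance(y, mu, phi)
  }
  dev <- dev_of(gamma)
  conv <- rep(FALSE, G)
  for (it in 1:200) {
    beta <- gamma %*% t(Z)
    eta <- pmin(beta[, group, drop = FALSE] + offmat, 45)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    zresp <- (eta - offmat) + (y - mu) / pmax(mu, 1e-10)
    Wg <- w %*% ind          # G x K group sums of weights
    Bg <- (w * zresp) %*% ind
    prop <- gamma
    act <- which(!conv)
    for (g in act) {
      A <- crossprod(Z, Z * Wg[g, ])
      b <- crossprod(Z, Bg[g, ])
      gnew <- tryCatch(drop(solve(A, b)), error = function(e) gamma[g, ])
      if (any(!is.finite(gnew))) gnew <- gamma[g, ]
      prop[g, ] <- gnew
    }
    dev_new <- dev_of(prop)
    # step halving where the proposal increased the deviance
    for (h in 1:10) {
      worse <- which(!conv & dev_new > dev + 1e-8)
      if (!length(worse)) break
      prop[worse, ] <- (prop[worse, , drop = FALSE] + gamma[worse, , drop = FALSE]) / 2
      dev_new[worse] <- dev_of(prop)[worse]
    }
    still_worse <- !conv & dev_new > dev + 1e-8
    prop[still_worse, ] <- gamma[still_worse, , drop = FALSE]
    dev_new[still_worse] <- dev[still_worse]
    newly <- !conv & (abs(dev - dev_new) < 1e-8 * (abs(dev) + 1) |
                        rowSums(abs(prop - gamma)) < 1e-8)
    gamma <- prop
    dev <- dev_new
    conv <- conv | newly
    if (all(conv)) break
  }
  if (any(!conv)) {
    message("constrained NB fit: ", sum(!conv),
            " gene(s) did not converge; excluded from testing")
    dev[!conv] <- NA_real_
  }
  beta <- gamma %*% t(Z)
  list(beta = beta, deviance = dev, converged = conv)
}

#' Quasi-likelihood F test of a contrast
#'
#' Per gene: the contrast estimate (reported as log2 fold-change), a
#' quasi-likelihood dispersion from residual deviance / residual df moderated
#' by empirical-Bayes squeezing toward a common value with an estimated
#' prior df, and F = (deviance drop of the contrast-constrained fit / 1) /
#' moderated dispersion, referred to F(1, residual df + prior df).
#'
#' @param fit An [fit_nb_glm()] result.
#' @param contrast A [contrast_vec()] (or named weights over design columns).
#' @return Object of class `dge_table` (a data.frame): gene, logFC, logCPM,
#'   F, p_val. Genes with nonpositive residual df get `NA` p-values.
#' @export
ql_f_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "nb_fit"))
  if (!inherits(contrast, "contrast_vec")) contrast <- do.call(contrast_vec, as.list(contrast))
  types <- colnames(fit$design)
  missing_types <- setdiff(names(contrast)[contrast != 0], types)
  if (length(missing_types)) {
    stop("contrast references animal type(s) absent from the fit: ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  cvec <- as.numeric(contrast[types])
  est <- as.numeric(fit$coefficients_shrunk %*% cvec)
  red <- .fit_constrained(fit, cvec)
  devdrop <- pmax(red$deviance - fit$deviance, 0)
  df1 <- fit$df_resid
  s2 <- if (df1 > 0) fit$deviance / df1 else rep(NA_real_, length(est))
  if (df1 > 0) {
    fd <- .fit_fdist(s2, df1)
    s2_post <- if (is.finite(fd$df0)) {
      (fd$df0 * fd$s0 + df1 * s2) / (fd$df0 + df1)
    } else rep(fd$s0, length(s2))
    Fstat <- devdrop / pmax(s2_post, 1e-10)
    df2 <- df1 + fd$df0
    p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  } else {
    Fstat <- rep(NA_real_, length(est)); p <- rep(NA_real_, length(est))
  }
  cpm <- sweep(fit$counts + 0.5, 2, exp(fit$offset) + 1, "/") * 1e6
  out <- data.frame(
    gene = fit$genes,
    logFC = est / log(2),
    logCPM = log2(rowMeans(cpm)),
    F = Fstat,
    p_val = p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dge_table", "data.frame")
  attr(out, "contrast") <- contrast
  rownames(out) <- NULL
  out
}

#' @export
print.dge_table <- function(x, n = 10, ...) {
  cat(sprintf("dge_table: %d genes", nrow(x)))
  if (!is.null(attr(x, "contrast"))) {
    w <- attr(x, "contrast")
    cat(" | contrast:", paste(sprintf("%s:%+g", names(w)[w != 0], w[w != 0]),
                              collapse = " "))
  }
  cat("\n")
  ord <- order(x$p_val)
  print.data.frame(utils::head(x[ord, ], n), digits = 4)
  invisible(x)
}
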