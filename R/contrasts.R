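#' Animal-type labels of a six-arm parabiosis cohort
#'
#' The six arms are: `YX`/`OX` unpaired young/old, `YY`/`OO` isochronic
#' young/old pairs, `YO` young heterochronic (joined to an old partner) and
#' `OY` old heterochronic (joined to a young partner). All design matrices
#' and contrast vectors in this package use this fixed column order.
#'
#' @return Character vector of the six labels.
#' @export
animal_types <- function() c("YX", "YY", "YO", "OX", "OO", "OY")

.check_animal_type <- function(x) {
  bad <- setdiff(unique(x), animal_types())
  if (length(bad)) {
    stop("unknown animal type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Construct a contrast vector over animal types
#'
#' A contrast is a named weight per animal type; weights must sum to zero.
#' Types not named receive weight 0.
#'
#' @param ... Named weights, e.g. `contrast_vec(OY = 1, OO = -1, OX = -1, YX = 1)`.
#' @return Named numeric vector of length 6 (class `contrast_vec`), ordered as
#'   [animal_types()].
#' @export
contrast_vec <- function(...) {
  w <- c(...)
  if (!length(w) || is.null(names(w)) || any(!nzchar(names(w)))) {
    stop("contrast weights must be named", call. = FALSE)
  }
  .check_animal_type(names(w))
  if (anyDuplicated(names(w))) stop("duplicated animal type in contrast", call. = FALSE)
  full <- stats::setNames(numeric(6), animal_types())
  full[names(w)] <- w
  if (all(full == 0)) stop("contrast is identically zero", call. = FALSE)
  if (abs(sum(full)) > 1e-12) stop("contrast weights must sum to 0", call. = FALSE)
  structure(full, class = "contrast_vec")
}

#' Rejuvenation (RJV) double-difference contrast
#'
#' The double difference (OY - OX) - (OO - YX): the shift in old heterochronic
#' animals relative to unpaired old, corrected for the isochronic surgery
#' effect measured against unpaired young. Under the generative model of
#' [simulate_cohort()] its expectation is `r - a` (rejuvenation minus aging).
#'
#' @return A [contrast_vec()] with weights OY +1, OO -1, OX -1, YX +1.
#' @export
rjv_contrast <- function() contrast_vec(OY = 1, OO = -1, OX = -1, YX = 1)

#' Aging-acceleration (AGA) double-difference contrast
#'
#' The young-heterochronic analogue (YO - YX) - (YY - OX); its expectation
#' under the generative model is `q + a` (acceleration plus aging).
#'
#' @return A [contrast_vec()] with weights YO +1, YY -1, YX -1, OX +1.
#' @export
aga_contrast <- function() contrast_vec(YO = 1, YY = -1, YX = -1, OX = 1)

#' Pairwise animal-type contrast
#'
#' @param t1,t2 Animal-type labels; `t1` gets weight +1, `t2` weight -1.
#' @return A [contrast_vec()].
#' @export
pairwise_contrast <- function(t1, t2) {
  .check_animal_type(c(t1, t2))
  if (identical(t1, t2)) stop("t1 and t2 must differ", call. = FALSE)
  w <- stats::setNames(c(1, -1), c(t1, t2))
  do.call(contrast_vec, as.list(w))
}

#' The seven standard pairwise comparisons
#'
#' OXvYX (aging), OYvOX, OYvOO, OOvOX, YOvYX, YOvYY and YYvYX.
#'
#' @return Named list of [contrast_vec()] objects.
#' @export
pairwise_contrasts <- function() {
  pairs <- list(
    OXvYX = c("OX", "YX"), OYvOX = c("OY", "OX"), OYvOO = c("OY", "OO"),
    OOvOX = c("OO", "OX"), YOvYX = c("YO", "YX"), YOvYY = c("YO", "YY"),
    YYvYX = c("YY", "YX")
  )
  lapply(pairs, function(p) pairwise_contrast(p[1], p[2]))
}

#' Standard contrast set for the full analysis
#'
#' RJV and AGA double differences plus the seven pairwise comparisons.
#' @return Named list of [contrast_vec()] objects.
#' @export
standard_contrasts <- function() {
  c(list(RJV = rjv_contrast(), AGA = aga_contrast()), pairwise_contrasts())
}

#' @export
print.contrast_vec <- function(x, ...) {
  cat("Animal-type contrast:\n")
  print(unclass(x))
  invisible(x)
}
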