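#' Rank-based inverse-normal transformation
#'
#' Maps a numeric vector to normal quantiles via the Blom fractional rank:
#' `qnorm((rank - c) / (n - 2c + 1))` with offset `c = 3/8`. Ties receive the
#' average fractional rank, so duplicated values map to identical outputs.
#' The transform is rank-preserving and invariant to any strictly monotone
#' re-expression of the input. By default the quantile scores are then
#' centered and scaled so the output has sample mean exactly 0 and SD exactly
#' 1 (raw Blom scores have SD slightly below 1 in finite samples); set
#' `standardize = FALSE` for the unscaled normal quantiles.
#'
#' @param x Numeric vector, length at least 3, not constant.
#' @param offset Rank offset constant; default the Blom value 3/8.
#' @param standardize Rescale to exact unit sample SD (default TRUE).
#' @return Numeric vector of the same length on the standard-normal scale.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8, standardize = TRUE) {
  if (anyNA(x)) stop("inverse_normal_transform: input contains NA", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("inverse_normal_transform: need at least 3 values", call. = FALSE)
  if (max(x) == min(x)) {
    stop("inverse_normal_transform: column is constant", call. = FALSE)
  }
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  if (standardize) (z - mean(z)) / stats::sd(z) else z
}

#' Inverse-normal transform a metabolite matrix
#'
#' Applies [inverse_normal_transform()] column-wise. Transformation is done on
#' the pooled analysis sample (cases and controls together); downstream
#' association models adjust for case/control status.
#'
#' @param values Numeric matrix or data frame, participants x markers.
#' @return Matrix of the same dimension, `attr(, "transformed") = TRUE`.
#' @export
transform_metabolites <- function(values) {
  m <- as.matrix(values)
  out <- apply(m, 2L, inverse_normal_transform)
  dimnames(out) <- dimnames(m)
  attr(out, "transformed") <- TRUE
  out
}

#' Duplicate-measurement coefficient of variation summary
#'
#' Quality-control summary over blind duplicate pairs: the per-pair CV is the
#' SD of the two replicates divided by their mean; the per-marker CV is the
#' mean of its pair CVs; the summary is the median and interquartile range of
#' the per-marker CVs. Pairs with mean zero are excluded with a warning.
#'
#' @param pairs Data frame with columns `marker`, `value1`, `value2` (one row
#'   per duplicate pair per marker).
#' @return List with `per_marker` (data frame marker/cv), `median_cv`,
#'   `iqr` (length-2: 25th and 75th percentiles). CVs are proportions;
#'   multiply by 100 for percent.
#' @export
duplicate_cv <- function(pairs) {
  .require_columns(pairs, c("marker", "value1", "value2"), "duplicate_cv")
  mean2 <- (pairs$value1 + pairs$value2) / 2
  zero <- mean2 == 0
  if (any(zero)) {
    warning(sprintf("duplicate_cv: excluded %d pair(s) with mean zero", sum(zero)))
    pairs <- pairs[!zero, , drop = FALSE]
    mean2 <- mean2[!zero]
  }
  if (nrow(pairs) == 0L) stop("duplicate_cv: no usable pairs", call. = FALSE)
  # two-point SD: |x1 - x2| / sqrt(2)
  cv <- abs(pairs$value1 - pairs$value2) / sqrt(2) / mean2
  per_marker <- stats::aggregate(cv, by = list(marker = pairs$marker), FUN = mean)
  names(per_marker)[2L] <- "cv"
  qs <- stats::quantile(per_marker$cv, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_marker = per_marker, median_cv = qs[2L], iqr = qs[c(1L, 3L)])
}

#' Top principal components of the transformed metabolite matrix
#'
#' Principal components of the centered (already unit-variance) metabolite
#' matrix, used for joint mediation. Verifies that the first `k` components
#' explain at least `variance_floor` of the total variance and warns
#' otherwise; scores of distinct components are orthogonal by construction.
#'
#' @param values Inverse-normal transformed matrix (participants x markers).
#' @param k Number of components to return (default 5).
#' @param variance_floor Required cumulative variance fraction (default 0.95).
#' @return List with `scores` (n x k matrix, columns `PC1..PCk`),
#'   `variance_explained` (length-k fractions, non-increasing), and
#'   `cumulative_variance` (scalar for the first k).
#' @export
top_principal_components <- function(values, k = 5L, variance_floor = 0.95) {
  m <- as.matrix(values)
  if (is.null(attr(m, "transformed")) || !isTRUE(attr(m, "transformed"))) {
    stop("top_principal_components: transform the matrix first ",
         "(transform_metabolites)", call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rank_m <- sum(pc$sdev > pc$sdev[1L] * 1e-12)
  if (k > rank_m) {
    stop(sprintf("top_principal_components: k = %d exceeds matrix rank %d",
                 k, rank_m), call. = FALSE)
  }
  varexp <- pc$sdev^2 / sum(pc$sdev^2)
  cumk <- sum(varexp[seq_len(k)])
  if (cumk < variance_floor) {
    warning(sprintf(
      "first %d components explain %.1f%% of variance, below the %.0f%% floor",
      k, 100 * cumk, 100 * variance_floor))
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, variance_explained = varexp[seq_len(k)],
       cumulative_variance = cumk)
}
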