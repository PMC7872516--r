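# Conditional stepwise variant selection within a gene window and weighted
# genetic-score construction, mimicking pharmacological LDL-C-lowering
# targets. The selection loop is the algorithmic core: at each iteration the
# remaining candidates are tested for association with LDL-C conditional on
# covariates and previously selected variants (Frisch-Waugh residualization
# gives the exact conditional t-test cheaply), the smallest p-value wins,
# candidates in LD with the pick (r^2 > threshold) are removed, and the loop
# stops when no remaining variant reaches the stopping p-value. Weights are
# the conditional effects from the final joint model, oriented to the allele
# associated with lower LDL-C (the exposure allele), so weights are positive
# magnitudes and a higher score means more LDL-lowering alleles.

#' Squared Pearson correlation of two dosage columns
#'
#' The LD measure used for pruning: squared Pearson correlation between the
#' dosage vectors of two variants.
#'
#' @param dosages Dosage matrix (participants x variants).
#' @param i,j Column indices or names.
#' @return r-squared in 0..1.
#' @export
ld_r2 <- function(dosages, i, j) {
  x <- dosages[, i]
  y <- dosages[, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("ld_r2: constant dosage column", call. = FALSE)
  }
  stats::cor(x, y)^2
}

# Conditional association p-values of every candidate with the phenotype,
# given the current design (covariates + selected variants), via
# residualization; identical to the t-test in the full joint lm.
.conditional_pvalues <- function(y, candidates, design) {
  qx <- qr(design)
  r_y <- qr.resid(qx, y)
  n <- length(y)
  df <- n - ncol(design) - 1L
  rss0 <- sum(r_y^2)
  out <- matrix(NA_real_, ncol(candidates), 2L,
                dimnames = list(colnames(candidates), c("beta", "p")))
  for (k in seq_len(ncol(candidates))) {
    r_g <- qr.resid(qx, candidates[, k])
    ssg <- sum(r_g^2)
    if (ssg < 1e-10) next # aliased with the current design
    beta <- sum(r_g * r_y) / ssg
    sigma2 <- max(rss0 - beta^2 * ssg, 0) / df
    tval <- beta / sqrt(sigma2 / ssg)
    out[k, ] <- c(beta, 2 * stats::pt(-abs(tval), df))
  }
  out
}

#' Conditional stepwise variant selection for a weighted genetic score
#'
#' Iteratively selects variants within one gene window that are conditionally
#' associated with LDL-C: (1) test each remaining candidate in a linear model
#' for LDL-C adjusted for covariates and all previously selected variants;
#' (2) select the variant with the smallest p-value (ties broken by smallest
#' genomic position); (3) stop if that p-value is at or above `p_stop`;
#' (4) remove remaining candidates correlated with the selection
#' (r^2 > `r2_threshold`); repeat until all variants are selected, pruned, or
#' non-significant. Monomorphic variants are excluded up front. The weight of
#' each selected variant is its conditional effect in the final joint model
#' containing all selected variants; the exposure allele is the allele whose
#' extra copy lowers LDL-C, and dosages are counted on that allele, so all
#' weights are positive magnitudes (mmol/l per exposure allele).
#'
#' @param dosages Dosage matrix (participants x variants, columns named).
#' @param variant_meta Variant table with `id`, `pos`, `ref`, `alt`,
#'   `gene_window`.
#' @param ldlc LDL-C in mmol/l.
#' @param covariates Numeric matrix/data frame of adjustment columns
#'   (age, sex indicator, 10 ancestry PCs).
#' @param gene Optional gene-window tag to restrict candidates to.
#' @param r2_threshold LD pruning threshold (default 0.3).
#' @param p_stop Conditional-significance stopping threshold (default 0.05).
#' @return Object of class `genetic_score`: `gene`, `selected_variants`
#'   (ordered as selected), `exposure_alleles`, `weights`, `weight_ses`,
#'   `conditional_p`, and `flip` (whether the dosage column is counted on
#'   the alternative allele or reversed). Empty selection yields a
#'   zero-variant score with a warning.
#' @export
conditional_select_variants <- function(dosages, variant_meta, ldlc,
                                        covariates, gene = NULL,
                                        r2_threshold = 0.3, p_stop = 0.05) {
  stopifnot(nrow(dosages) == length(ldlc))
  meta <- variant_meta
  if (!is.null(gene)) {
    meta <- meta[meta$gene_window == gene, , drop = FALSE]
  } else {
    gene <- paste(unique(meta$gene_window), collapse = "+")
  }
  if (nrow(meta) == 0L) {
    warning("conditional_select_variants: no variants in window '", gene, "'")
    return(structure(list(gene = gene, selected_variants = character(0),
                          exposure_alleles = character(0),
                          weights = numeric(0), weight_ses = numeric(0),
                          conditional_p = numeric(0), flip = logical(0)),
                     class = "genetic_score"))
  }
  G <- dosages[, meta$id, drop = FALSE]
  mono <- apply(G, 2L, function(g) stats::sd(g) == 0)
  meta <- meta[!mono, , drop = FALSE]
  G <- G[, !mono, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))

  remaining <- meta$id
  selected <- character(0)
  repeat {
    if (length(remaining) == 0L) break
    design <- cbind(X, G[, selected, drop = FALSE])
    res <- .conditional_pvalues(ldlc, G[, remaining, drop = FALSE], design)
    p <- res[, "p"]
    if (all(is.na(p))) break
    best_p <- min(p, na.rm = TRUE)
    if (best_p >= p_stop) break
    tied <- remaining[which(!is.na(p) & p == best_p)]
    pick <- tied[which.min(meta$pos[match(tied, meta$id)])]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L) {
      r2 <- vapply(remaining, function(v) ld_r2(G, v, pick), numeric(1))
      remaining <- remaining[r2 <= r2_threshold]
    }
  }

  if (length(selected) == 0L) {
    warning("conditional_select_variants: no variant passed p < ", p_stop,
            " in window '", gene, "'")
    return(structure(list(gene = gene, selected_variants = character(0),
                          exposure_alleles = character(0),
                          weights = numeric(0), weight_ses = numeric(0),
                          conditional_p = numeric(0), flip = logical(0)),
                     class = "genetic_score"))
  }

  # final joint model: conditional effects adjusted for all other selected
  # variants and covariates
  df <- data.frame(.y = ldlc, as.data.frame(as.matrix(covariates)),
                   as.data.frame(G[, selected, drop = FALSE],
                                 check.names = FALSE), check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  cf <- summary(fit)$coefficients
  sel_names <- paste0("`", selected, "`")
  rn <- rownames(cf)
  rows <- vapply(selected, function(v) {
    w <- which(rn == v | rn == paste0("`", v, "`"))
    w[1L]
  }, integer(1))
  beta <- cf[rows, 1L]
  se <- cf[rows, 2L]
  pvals <- cf[rows, 4L]
  msel <- meta[match(selected, meta$id), ]
  # exposure allele lowers LDL-C: alt if beta < 0, otherwise ref (dosage
  # flipped to 2 - d); weights are the positive conditional-effect magnitudes
  flip <- beta > 0
  structure(list(
    gene = gene,
    selected_variants = selected,
    exposure_alleles = ifelse(flip, msel$ref, msel$alt),
    weights = stats::setNames(abs(beta), selected),
    weight_ses = stats::setNames(unname(se), selected),
    conditional_p = stats::setNames(unname(pvals), selected),
    flip = stats::setNames(unname(flip), selected)
  ), class = "genetic_score")
}

#' Build the weighted, standardized genetic score
#'
#' Multiplies each participant's exposure-allele dosage at each selected
#' variant by the variant's weight and sums; the raw score is then
#' inverse-normal transformed with the shared routine (so reported effects
#' are per SD of the score).
#'
#' @param dosages Dosage matrix containing every selected variant.
#' @param score_def A `genetic_score` from [conditional_select_variants()]
#'   (or assembled externally for re-weighting a fixed variant list).
#' @return List with `raw` and `standardized` per-participant scores.
#' @export
build_score <- function(dosages, score_def) {
  stopifnot(inherits(score_def, "genetic_score"))
  if (length(score_def$selected_variants) == 0L) {
    stop("build_score: score has no variants", call. = FALSE)
  }
  missing <- setdiff(score_def$selected_variants, colnames(dosages))
  if (length(missing) > 0L) {
    stop("build_score: variant(s) missing from genotypes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  D <- dosages[, score_def$selected_variants, drop = FALSE]
  D <- sweep(D, 2L, as.numeric(score_def$flip) * 2, function(d, f) abs(f - d))
  raw <- as.numeric(D %*% score_def$weights)
  list(raw = raw, standardized = inverse_normal_transform(raw))
}

#' Association of a genetic score with a transformed metabolite
#'
#' Linear regression of the metabolite on the standardized score, adjusted
#' for age, sex, study area, and the top 10 genotype principal components;
#' the reported estimate is for a 2-SD increase in the score (twice the
#' per-1-SD coefficient).
#'
#' @param data Data frame with the metabolite and covariate columns.
#' @param marker Metabolite column name.
#' @param score Standardized score vector aligned to `data`.
#' @param covariates Covariate column names in `data`.
#' @param ancestry_pcs Matrix of genotype PCs aligned to `data` (optional if
#'   already included as columns).
#' @param scale_sd Report per this many SDs (default 2).
#' @return One association row (`contrast = "per 2-SD score"`).
#' @export
score_association <- function(data, marker, score,
                              covariates = c("age", "sex", "area"),
                              ancestry_pcs = NULL, scale_sd = 2) {
  .require_columns(data, c(marker, covariates), "score_association")
  stopifnot(length(score) == nrow(data))
  df <- data
  df$.score <- score
  terms <- c(".score", covariates)
  if (!is.null(ancestry_pcs)) {
    pcs <- as.matrix(ancestry_pcs)
    colnames(pcs) <- paste0("gPC", seq_len(ncol(pcs)))
    df <- cbind(df, pcs)
    terms <- c(terms, colnames(pcs))
  }
  fit <- stats::lm(.build_formula(marker, terms), data = df)
  .check_aliased(fit, "score_association")
  cf <- summary(fit)$coefficients
  .assoc_result(marker, sprintf("per %g-SD score", scale_sd),
                scale_sd * cf[".score", 1L], scale_sd * cf[".score", 2L],
                cf[".score", 4L])
}

#' Sum of two genetic scores
#'
#' Element-wise sum of the raw scores, re-standardized with the shared
#' inverse-normal routine.
#'
#' @param score_a,score_b Lists from [build_score()] (same participants).
#' @return List with `raw` and `standardized`.
#' @export
sum_scores <- function(score_a, score_b) {
  if (length(score_a$raw) != length(score_b$raw)) {
    stop("sum_scores: participant sets differ", call. = FALSE)
  }
  raw <- score_a$raw + score_b$raw
  list(raw = raw, standardized = inverse_normal_transform(raw))
}

#' HLF-metabolite association stratified by genetic score
#'
#' Dichotomizes the standardized score at its median, fits the linear
#' HLF-count model for the metabolite within each stratum, and tests for
#' effect modification with the pooled likelihood-ratio test of the
#' count-by-stratum product term.
#'
#' @param data Data frame with the metabolite, `hlf_count`, and covariates.
#' @param marker Metabolite column name.
#' @param score Standardized score aligned to `data`.
#' @param covariates Covariate column names.
#' @return List with `strata` (two association rows: below/at-or-above the
#'   median score) and `p_interaction`.
#' @export
stratified_hlf_analysis <- function(data, marker, score,
                                    covariates = c("age", "sex", "area",
                                                   "education")) {
  .require_columns(data, c(marker, "hlf_count", covariates),
                   "stratified_hlf_analysis")
  stopifnot(length(score) == nrow(data))
  med <- stats::median(score)
  stratum <- ifelse(score < med, "below_median", "at_or_above_median")
  if (length(unique(stratum)) < 2L) {
    stop("stratified_hlf_analysis: empty stratum", call. = FALSE)
  }
  rows <- lapply(c("below_median", "at_or_above_median"), function(s) {
    sub <- data[stratum == s, , drop = FALSE]
    fit <- stats::lm(.build_formula(marker, c("hlf_count", covariates)),
                     data = sub)
    cf <- summary(fit)$coefficients
    .assoc_result(marker, paste0("per +1 HLF | score ", s),
                  cf["hlf_count", 1L], cf["hlf_count", 2L], cf["hlf_count", 4L])
  })
  df <- data
  df$.stratum <- stratum
  lrt <- interaction_lrt(df, marker, "hlf_count", ".stratum", covariates,
                         family = "gaussian")
  list(strata = do.call(rbind, rows), p_interaction = lrt$p_value)
}

#' Serialize / read a genetic-score definition as JSON
#'
#' @param score_def A `genetic_score`.
#' @param path File path.
#' @return `read_score_definition` returns a `genetic_score`.
#' @export
write_score_definition <- function(score_def, path) {
  jsonlite::write_json(
    list(gene = score_def$gene,
         selected_variants = score_def$selected_variants,
         exposure_alleles = score_def$exposure_alleles,
         weights = as.list(score_def$weights),
         flip = as.list(score_def$flip)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_definition
#' @export
read_score_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    gene = x$gene,
    selected_variants = x$selected_variants,
    exposure_alleles = x$exposure_alleles,
    weights = unlist(x$weights),
    weight_ses = rep(NA_real_, length(x$weights)),
    conditional_p = rep(NA_real_, length(x$weights)),
    flip = unlist(x$flip)
  ), class = "genetic_score")
}
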