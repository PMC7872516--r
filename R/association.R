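# Association layers: lifestyle -> metabolites (linear), metabolites -> CHD
# (logistic), joint lifestyle x genetic-score groups, and interaction LRTs.
# Fits go through stats::lm / stats::glm; this module owns the contrast
# extraction, tidy output, and contracts.

.default_hlf_covariates <- c("age", "sex", "fasting_ge_8h", "area",
                             "education", "status_cc")
.default_chd_covariates <- c("age", "sex", "fasting_ge_8h", "area",
                             "education", "smoking_status")

.assoc_result <- function(marker, contrast, estimate, se, p, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(marker = marker, contrast = contrast, estimate = estimate,
             se = se, ci_low = estimate - z * se, ci_high = estimate + z * se,
             p = p, row.names = NULL)
}

.check_aliased <- function(fit, where) {
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    stop(sprintf("%s: rank-deficient design; aliased column(s): %s", where,
                 paste(names(aliased)[aliased], collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Backtick-quote non-syntactic names (marker names contain '-' and '/');
# ':' interaction terms are quoted component-wise.
.bt <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  parts <- vapply(parts, function(p) {
    if (grepl("^[a-zA-Z.][a-zA-Z0-9._]*$", p)) p else paste0("`", p, "`")
  }, character(1))
  paste(parts, collapse = ":")
}

.build_formula <- function(lhs, rhs_terms) {
  rhs <- vapply(rhs_terms, .bt, character(1))
  stats::as.formula(paste(.bt(lhs), "~", paste(rhs, collapse = " + ")),
                    env = parent.frame())
}

#' Association of combined HLFs with a transformed metabolite
#'
#' Ordinary least squares of an inverse-normal transformed metabolite on the
#' HLF exposure, adjusted for the standard covariate set (age, sex, fasting
#' time, study area, education, case/control status). The categorical
#' exposure uses participants with 0-1 HLFs as the reference group; the
#' continuous exposure reports the SD difference per one additional HLF.
#'
#' @param data Data frame containing the transformed metabolite column, the
#'   HLF columns (`hlf_group`, `hlf_count`) and the covariates.
#' @param marker Name of the metabolite column.
#' @param exposure "group" (three categories, reference "0-1") or "count"
#'   (per +1 HLF).
#' @param covariates Character vector of covariate column names.
#' @return Data frame of association rows (one per non-reference contrast):
#'   `marker`, `contrast`, `estimate` (SD difference), `se`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
fit_hlf_metabolite <- function(data, marker, exposure = c("group", "count"),
                               covariates = .default_hlf_covariates) {
  exposure <- match.arg(exposure)
  exp_col <- if (exposure == "group") "hlf_group" else "hlf_count"
  .require_columns(data, c(marker, exp_col, covariates), "fit_hlf_metabolite")
  df <- data
  if (exposure == "group") {
    # unordered factor so the model uses treatment contrasts vs "0-1"
    df$.exposure <- factor(as.character(df$hlf_group),
                           levels = c("0-1", "2-3", "4-5"))
  } else {
    df$.exposure <- df$hlf_count
  }
  fit <- stats::lm(.build_formula(marker, c(".exposure", covariates)), data = df)
  .check_aliased(fit, "fit_hlf_metabolite")
  cf <- summary(fit)$coefficients
  if (exposure == "group") {
    rows <- paste0(".exposure", c("2-3", "4-5"))
    contrasts <- c("2-3 vs 0-1 HLFs", "4-5 vs 0-1 HLFs")
  } else {
    rows <- ".exposure"
    contrasts <- "per +1 HLF"
  }
  .assoc_result(marker, contrasts, cf[rows, 1L], cf[rows, 2L], cf[rows, 4L])
}

#' Association of a transformed metabolite with CHD
#'
#' Maximum-likelihood logistic regression of CHD case status on a transformed
#' metabolite, adjusted for age, sex, fasting time, study area, education and
#' smoking status. Only CHD cases and controls may be present (stroke cases
#' are analysed elsewhere and must be excluded first).
#'
#' @param data Data frame restricted to `status` in control / chd_case.
#' @param marker Name of the transformed metabolite column.
#' @param covariates Covariate column names.
#' @return One association row; `estimate` is the log odds ratio per 1-SD
#'   higher metabolite, with `or`, `or_low`, `or_high` columns appended.
#' @export
fit_metabolite_chd <- function(data, marker,
                               covariates = .default_chd_covariates) {
  .require_columns(data, c(marker, "status", covariates), "fit_metabolite_chd")
  extra <- setdiff(unique(data$status), c("control", "chd_case"))
  if (length(extra) > 0L) {
    stop("fit_metabolite_chd: data must contain only CHD cases and controls; ",
         "found status: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  df <- data
  df$.y <- as.integer(df$status == "chd_case")
  df$.m <- df[[marker]]
  fit <- stats::glm(.build_formula(".y", c(".m", covariates)),
                    family = stats::binomial(), data = df)
  .check_aliased(fit, "fit_metabolite_chd")
  if (!fit$converged) {
    stop("fit_metabolite_chd: logistic fit did not converge", call. = FALSE)
  }
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10 | mu > 1 - 1e-10)) {
    stop("fit_metabolite_chd: fitted probabilities of 0 or 1 ",
         "(perfect or quasi-perfect separation)", call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  out <- .assoc_result(marker, "per 1-SD marker", cf[".m", 1L],
                       cf[".m", 2L], cf[".m", 4L])
  out$or <- exp(out$estimate)
  out$or_low <- exp(out$ci_low)
  out$or_high <- exp(out$ci_high)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, for testing across
#' the metabolite panel; significance is declared at FDR < 0.05.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Numeric vector of adjusted p-values (same order as the input).
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Joint lifestyle x genetic-score group analysis
#'
#' Cross-classifies participants into four groups by the median-dichotomized
#' genetic score and the two-level HLF count ("0-2" vs "3-5") and fits a
#' linear model for the metabolite with the four-level grouping plus
#' covariates. Because the score counts LDL-C-lowering (exposure) alleles, a
#' score below the median marks the higher-genetic-risk stratum; the
#' reference group is higher genetic risk with 0-2 HLFs.
#'
#' @param data Data frame with the metabolite, `hlf_group2` and covariates.
#' @param marker Metabolite column name.
#' @param score Numeric per-participant standardized genetic score, aligned
#'   to `data` rows.
#' @param covariates Covariate column names.
#' @return Four association rows (reference row has estimate 0, se/p NA).
#' @export
joint_group_analysis <- function(data, marker, score,
                                 covariates = c("age", "sex", "area",
                                                "education")) {
  .require_columns(data, c(marker, "hlf_group2", covariates),
                   "joint_group_analysis")
  stopifnot(length(score) == nrow(data))
  risk <- ifelse(score < stats::median(score), "higher_risk", "lower_risk")
  grp <- interaction(risk, data$hlf_group2, sep = " & ", lex.order = FALSE)
  lev <- c("higher_risk & 0-2", "lower_risk & 0-2",
           "higher_risk & 3-5", "lower_risk & 3-5")
  grp <- factor(as.character(grp), levels = lev)
  empty <- lev[!(lev %in% grp)]
  if (length(empty) > 0L || any(table(grp) == 0L)) {
    bad <- unique(c(empty, names(table(grp))[table(grp) == 0L]))
    stop("joint_group_analysis: empty cell(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  df <- data
  df$.grp <- grp
  fit <- stats::lm(.build_formula(marker, c(".grp", covariates)), data = df)
  .check_aliased(fit, "joint_group_analysis")
  cf <- summary(fit)$coefficients
  rows <- paste0(".grp", lev[-1L])
  out <- rbind(
    .assoc_result(marker, paste(lev[1L], "(reference)"), 0, 0, NA_real_),
    .assoc_result(marker, lev[-1L], cf[rows, 1L], cf[rows, 2L], cf[rows, 4L])
  )
  out$se[1L] <- NA_real_
  out$ci_low[1L] <- NA_real_
  out$ci_high[1L] <- NA_real_
  out
}

#' Likelihood-ratio test for effect modification
#'
#' Compares nested models with and without the exposure-by-modifier
#' cross-product term(s); the statistic is twice the log-likelihood
#' difference, referred to a chi-square distribution with degrees of freedom
#' equal to the number of cross-product terms.
#'
#' @param data Data frame with all model columns.
#' @param response Response column name (for the binomial family a 0/1 or
#'   logical column).
#' @param exposure,modifier Column names of the two interacting terms.
#' @param covariates Additional adjustment column names.
#' @param family "gaussian" or "binomial".
#' @return List with `statistic`, `df`, `p_value`.
#' @export
interaction_lrt <- function(data, response, exposure, modifier,
                            covariates = character(0),
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  .require_columns(data, c(response, exposure, modifier, covariates),
                   "interaction_lrt")
  base_terms <- c(exposure, modifier, covariates)
  full_terms <- c(base_terms, paste0(exposure, ":", modifier))
  if (family == "gaussian") {
    reduced <- stats::lm(.build_formula(response, base_terms), data = data)
    full <- stats::lm(.build_formula(response, full_terms), data = data)
  } else {
    reduced <- stats::glm(.build_formula(response, base_terms),
                          family = stats::binomial(), data = data)
    full <- stats::glm(.build_formula(response, full_terms),
                       family = stats::binomial(), data = data)
  }
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  if (df < 0L) {
    stop("interaction_lrt: models are not nested", call. = FALSE)
  }
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(reduced))))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Fit one association layer across a metabolite panel
#'
#' Loops [fit_hlf_metabolite()] or [fit_metabolite_chd()] over markers and
#' appends BH-FDR adjusted p-values within each contrast.
#'
#' @param data Data frame containing all transformed marker columns and
#'   covariates (for the CHD layer, restricted to CHD cases and controls).
#' @param markers Character vector of marker column names.
#' @param layer "hlf-metabolite" or "metabolite-chd".
#' @param ... Passed to the per-marker fit function.
#' @return Tidy data frame with a `p_fdr` column.
#' @export
associate_panel <- function(data, markers,
                            layer = c("hlf-metabolite", "metabolite-chd"),
                            ...) {
  layer <- match.arg(layer)
  fun <- if (layer == "hlf-metabolite") fit_hlf_metabolite else fit_metabolite_chd
  res <- do.call(rbind, lapply(markers, function(mk) fun(data, mk, ...)))
  res$p_fdr <- NA_real_
  for (ct in unique(res$contrast)) {
    idx <- res$contrast == ct
    res$p_fdr[idx] <- bh_fdr(res$p[idx])
  }
  res
}
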